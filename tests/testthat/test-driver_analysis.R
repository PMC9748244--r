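# A minimal survey with known per-year presence counts and abundances.
counts_survey <- function() {
  years <- c(rep(2009L, 241), rep(2010L, 150))
  sv <- data.frame(station_id = seq_along(years), year = years,
                   lon = 0, lat = 0, depth = 50, sst = 24, sss = 33)
  sv$spA <- c(rep(c(1L, 0L), c(199, 42)),   # 199 of 241 stations in 2009
              rep(0L, 150))                  # absent all of 2010
  sv$n_spA <- sv$spA * 3L
  attr(sv, "species") <- "spA"
  sv
}

metric_stub <- function() {
  data.frame(species = "spA", year = c(2009L, 2010L), algorithm = "glm",
             centroid_distance = c(0.2, 0.4),
             volume_change = c(0.1, 0.3),
             sorensen_dissimilarity = c(0.05, 0.2),
             inverse_intersection = c(1.2, Inf))
}

test_that("driver table derives occurrence, effort and abundance exactly", {
  drv <- data.frame(year = c(2009L, 2010L), sst = c(24, 25),
                    sss = c(33, 32), red_tide = c(0.1, 2))
  tab <- assemble_driver_table(metric_stub(), counts_survey(), drv)
  expect_equal(tab$occurrence[tab$year == 2009], 100 * 199 / 241)
  expect_equal(tab$occurrence[tab$year == 2010], 0)
  expect_equal(tab$effort, c(241L, 150L))
  expect_equal(tab$abundance[tab$year == 2009], 3 * 199 / 241)
  expect_equal(tab$sst, c(24, 25))
  bad_drv <- drv[drv$year == 2009, ]
  expect_error(assemble_driver_table(metric_stub(), counts_survey(),
                                     bad_drv), "2010")
})

test_that("the mixed model recovers an injected driver slope and AR(1)", {
  scen <- default_driver_scenario(2009:2020, slopes = c(effort = 0.5),
                                  seed = 91, ar1_rho = 0.6,
                                  residual_sd = 0.3)
  g <- generate_driver_table(scen, n_species = 10, n_algorithms = 4,
                             seed = 92)
  fit <- fit_lmm(g$table, "response", "effort")
  est <- fit$fixed$estimate[fit$fixed$term == "effort"]
  expect_lt(abs(est - 0.5), 0.1)
  expect_lt(abs(fit$ar1 - 0.6), 0.25)
  expect_gt(fit$var_random, 0)
})

test_that("likelihood-ratio machinery is exact on nested ML fits", {
  scen <- default_driver_scenario(2009:2020, seed = 93)
  g <- generate_driver_table(scen, n_species = 8, n_algorithms = 2,
                             seed = 94)
  null_fit <- fit_lmm(g$table, "response", "null")
  expect_equal(marginal_r2(null_fit), 0)
  self <- lrt(null_fit, null_fit)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  # nesting: any fixed effect can only raise the ML log-likelihood
  for (fe in c("effort", "sst", "red_tide")) {
    m <- fit_lmm(g$table, "response", fe)
    expect_gte(m$logLik, null_fit$logLik - 1e-6)
    expect_gte(marginal_r2(m), 0)
    expect_lte(marginal_r2(m), 1)
  }
  # LRT demands ML fits
  fake <- null_fit
  fake$method <- "REML"
  expect_error(lrt(fake, null_fit), "ML")
})

test_that("marginal R2 tracks a constructed variance split", {
  # fixed effects built to generate half the total variance:
  # slope 1 on a unit-sd driver; random 0.5^2 + AR(1) marginal 0.75 = 1
  scen <- default_driver_scenario(
    2009:2020, slopes = c(effort = 1), seed = 95,
    random_intercept_sd = 0.5, ar1_rho = 0,
    residual_sd = sqrt(0.75))
  g <- generate_driver_table(scen, n_species = 12, n_algorithms = 4,
                             seed = 96)
  fit <- fit_lmm(g$table, "response", "effort")
  expect_lt(abs(marginal_r2(fit) - 0.5), 0.08)
})

test_that("injected effect signs are recovered reliably", {
  hits <- matrix(0, 10, 4,
                 dimnames = list(NULL, c("red_tide", "effort",
                                         "occurrence", "sss")))
  truth <- c(red_tide = 0.3, effort = -0.3, occurrence = -0.25,
             sss = -0.25)
  for (r in 1:10) {
    scen <- default_driver_scenario(2009:2020, slopes = truth,
                                    seed = 500 + r)
    g <- generate_driver_table(scen, n_species = 10, n_algorithms = 4,
                               seed = 600 + r)
    for (fe in colnames(hits)) {
      m <- fit_lmm(g$table, "response", fe)
      est <- m$fixed$estimate[m$fixed$term == fe]
      hits[r, fe] <- sign(est) == sign(truth[[fe]])
    }
  }
  expect_gte(min(colMeans(hits)), 0.9)
})

test_that("non-finite responses are excluded listwise with a count", {
  scen <- default_driver_scenario(2009:2020, seed = 97)
  g <- generate_driver_table(scen, n_species = 5, n_algorithms = 2,
                             seed = 98)
  g$table$response[c(3, 17)] <- Inf
  fit <- fit_lmm(g$table, "response", "sst")
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n_used, nrow(g$table) - 2)
  expect_true(is.finite(fit$logLik))
})

test_that("the driver-model grid reports one row per response and effect", {
  scen <- default_driver_scenario(2009:2020,
                                  slopes = c(red_tide = 0.4), seed = 99)
  g <- generate_driver_table(scen, n_species = 8, n_algorithms = 4,
                             seed = 100)
  g$table$centroid_distance <- g$table$response
  dm <- fit_driver_models(g$table, responses = "centroid_distance",
                          fixed_effects = c("effort", "red_tide"))
  expect_equal(nrow(dm$results), 2)
  rt <- dm$results[dm$results$fixed_effect == "red_tide", ]
  expect_equal(rt$sign, 1)
  expect_lt(rt$lrt_p, 0.05)
  expect_gt(rt$marginal_r2,
            dm$results$marginal_r2[dm$results$fixed_effect == "effort"])
})
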