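test_that("survey has one row per station and honours the effort vector", {
  des <- default_survey_design(seed = 3)
  sv <- generate_survey(des, default_species_pool(2))
  expect_equal(nrow(sv), 2698)
  expect_equal(as.integer(table(sv$year)),
               c(241L, 243L, 151L, 237L, 209L, 297L, 261L, 215L, 257L,
                 260L, 237L, 90L))
  # seed determinism
  sv2 <- generate_survey(des, default_species_pool(2))
  expect_identical(sv, sv2)
  des_b <- default_survey_design(seed = 4)
  expect_false(identical(generate_survey(des_b, default_species_pool(2)),
                         sv))
})

test_that("occupancy follows the Gaussian niche response surface", {
  sp <- niche_spec("v", optimum = c(depth = 100, sst = 24, sss = 32),
                   breadth = c(depth = 40, sst = 4, sss = 3),
                   max_occupancy = 1)
  at_opt <- data.frame(depth = 100, sst = 24, sss = 32)
  expect_equal(true_suitability(sp, at_opt), 1)
  # one breadth away in a single dimension: exp(-1/2)
  expect_equal(true_suitability(sp, data.frame(depth = 140, sst = 24,
                                               sss = 32)),
               exp(-0.5))
  set.seed(9)
  grid <- data.frame(depth = runif(500, 0, 300), sst = runif(500, 10, 40),
                     sss = runif(500, 20, 40))
  p <- true_suitability(sp, grid)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("empirical prevalence converges to the spatial mean occupancy", {
  des <- survey_design(years = 2009L, effort = 12000L,
                       covariate_ranges = list(depth = c(10, 200),
                                               sst = c(17, 30),
                                               sss = c(25, 36)),
                       seed = 21)
  sp <- default_species_pool(1)[[1]]
  sv <- generate_survey(des, list(sp))
  p_true <- true_suitability(sp, sv)
  se <- sqrt(var(p_true) / nrow(sv) + mean(p_true * (1 - p_true)) / nrow(sv))
  expect_lt(abs(mean(sv[[sp$species_id]]) - mean(p_true)), 4 * se + 1e-6)
})

test_that("invalid designs, niches and scenarios are rejected", {
  rng <- list(depth = c(10, 200), sst = c(17, 30), sss = c(25, 36))
  expect_error(survey_design(integer(0), integer(0), rng), "non-empty")
  expect_error(survey_design(2009L, 0L, rng), "positive")
  expect_error(survey_design(2009L, 10L,
                             list(depth = c(5, 5), sst = c(17, 30),
                                  sss = c(25, 36))),
               "min < max")
  expect_error(niche_spec("x", c(depth = 1, sst = 1, sss = 1),
                          c(depth = 0, sst = 1, sss = 1)), "breadth")
  expect_error(niche_spec("x", c(depth = 1, sst = 1, sss = 1),
                          c(depth = 1, sst = 1, sss = 1),
                          max_occupancy = 1.2), "max_occupancy")
  drv <- data.frame(year = 1:3, effort = 1:3)
  expect_error(driver_scenario(drv, ar1_rho = 1), "ar1_rho")
  expect_error(driver_scenario(drv, residual_sd = 0), "residual_sd")
  expect_error(driver_scenario(drv, slopes = c(bogus = 1)), "unknown")
  des <- default_survey_design()
  expect_error(generate_survey(des, list()), "at least one")
  expect_error(generate_environment_grids(des, grid_shape = c(0, 5)),
               "positive")
})

test_that("species filter enforces the per-year presence floor", {
  set.seed(5)
  years <- rep(2009:2011, each = 100)
  sv <- data.frame(station_id = seq_along(years), year = years,
                   lon = 0, lat = 0, depth = 1, sst = 1, sss = 1)
  # spA dips to 19 in one year, spB sits exactly at 20, spC is common
  sv$spA <- ifelse(years == 2010, rep(c(1, 0), c(19, 81)),
                   rep(c(1, 0), c(60, 40)))
  sv$spB <- ifelse(years == 2011, rep(c(1, 0), c(20, 80)),
                   rep(c(1, 0), c(50, 50)))
  sv$spC <- rep(c(1, 0), c(70, 30))
  attr(sv, "species") <- c("spA", "spB", "spC")
  suppressMessages(out <- filter_species(sv, 20))
  expect_setequal(survey_species(out), c("spB", "spC"))
  expect_equal(unname(attr(out, "dropped_species")["spA"]), 19)
  # threshold 0 is the identity
  out0 <- filter_species(sv, 0)
  expect_setequal(survey_species(out0), c("spA", "spB", "spC"))
})

test_that("driver generator injects the stated mixed-model structure", {
  # no effects, no intercepts: pure stationary AR(1) noise around zero
  scen <- default_driver_scenario(2009:2020, seed = 2, ar1_rho = 0.5,
                                  random_intercept_sd = 1e-9,
                                  residual_sd = 0.4)
  g <- generate_driver_table(scen, n_species = 40, n_algorithms = 2,
                             seed = 3)
  expect_equal(nrow(g$table), 40 * 2 * 12)
  expect_lt(abs(mean(g$table$response)), 0.05)
  marg_sd <- 0.4 / sqrt(1 - 0.5^2)
  expect_lt(abs(sd(g$table$response) - marg_sd), 0.05)
  # determinism
  g2 <- generate_driver_table(scen, 40, 2, seed = 3)
  expect_identical(g$table, g2$table)
})

test_that("residual lag-1 autocorrelation matches the generating AR(1)", {
  pooled_lag1 <- function(rho, seed0) {
    xs <- ys <- numeric(0)
    for (r in 1:200) {
      scen <- default_driver_scenario(2009:2020, seed = seed0 + r,
                                      ar1_rho = rho,
                                      random_intercept_sd = 1e-9,
                                      residual_sd = 0.3)
      g <- generate_driver_table(scen, n_species = 1, n_algorithms = 1,
                                 seed = seed0 + 1000 + r)
      y <- g$table$response
      xs <- c(xs, y[-length(y)])
      ys <- c(ys, y[-1])
    }
    cor(xs, ys)
  }
  expect_lt(abs(pooled_lag1(0, 100)), 0.06)
  expect_lt(abs(pooled_lag1(0.6, 200) - 0.6), 0.06)
})

test_that("environment grids average monthly layers into annual means", {
  des <- survey_design(years = 2009:2010, effort = c(50L, 50L),
                       covariate_ranges = list(depth = c(10, 200),
                                               sst = c(17, 30),
                                               sss = c(25, 36)),
                       seed = 6)
  g <- generate_environment_grids(des, grid_shape = c(6L, 5L),
                                  monthly = TRUE, resolution = 0.041)
  expect_equal(attr(g, "resolution"), 0.041)
  expect_equal(attr(g, "grid_shape"), c(6L, 5L))
  # depth is one static layer, not per-year
  expect_equal(sum(g$covariate == "depth"), 30)
  # the emitted annual layer equals the mean of its 12 monthly layers
  for (yr in 2009:2010) {
    m <- g[g$covariate == "sst" & !is.na(g$year) & g$year == yr, ]
    monthly <- m[!is.na(m$month), ]
    annual <- m[is.na(m$month), ]
    by_cell <- tapply(monthly$value, paste(monthly$row, monthly$col), mean)
    expect_equal(as.numeric(by_cell[paste(annual$row, annual$col)]),
                 annual$value, tolerance = 1e-12)
  }
  # all values stay within physically sensible limits
  sst <- g$value[g$covariate == "sst"]
  expect_true(all(sst > 10 & sst < 36))
})
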