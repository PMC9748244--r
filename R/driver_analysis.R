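#' Assemble the driver table for mixed-model analysis
#'
#' Joins the annual-vs-pooled metric table with candidate drivers: per
#' (species, year) the survey-derived intrinsic and sampling drivers
#' (abundance = mean individuals per station, occurrence = percentage of
#' stations with at least one individual, effort = stations sampled) and
#' per year the environmental drivers (`sst`, `sss`, `red_tide`) supplied
#' in `annual_drivers`.
#'
#' @param metrics a metric table from [compare_annual_to_pooled()].
#' @param survey the (unscaled or scaled) survey table the metrics came
#'   from; count columns `n_<species>` are used for abundance when present,
#'   otherwise abundance is `NA`.
#' @param annual_drivers data frame with column `year` plus `sst`, `sss`,
#'   `red_tide` (annual values).
#' @return A data frame, one row per (species, year, algorithm), with the
#'   response metrics and all drivers. Years present in `metrics` but not
#'   in `survey` or `annual_drivers` are an error naming the offending
#'   keys.
#' @export
assemble_driver_table <- function(metrics, survey, annual_drivers) {
  need_years <- sort(unique(metrics$year))
  bad <- setdiff(need_years, unique(survey$year))
  if (length(bad)) stop("years missing from survey: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(need_years, annual_drivers$year)
  if (length(bad)) stop("years missing from annual_drivers: ",
                        paste(bad, collapse = ", "))
  effort_by_year <- table(survey$year)
  out <- metrics
  out$effort <- as.integer(effort_by_year[as.character(out$year)])
  key <- paste(out$species, out$year)
  occ <- vapply(seq_len(nrow(out)), function(i) {
    pres <- survey[[out$species[i]]][survey$year == out$year[i]]
    100 * sum(pres == 1) / length(pres)
  }, numeric(1))
  out$occurrence <- occ
  out$abundance <- vapply(seq_len(nrow(out)), function(i) {
    cn <- paste0("n_", out$species[i])
    if (!cn %in% names(survey)) return(NA_real_)
    mean(survey[[cn]][survey$year == out$year[i]])
  }, numeric(1))
  idx <- match(out$year, annual_drivers$year)
  for (d in c("sst", "sss", "red_tide"))
    out[[d]] <- annual_drivers[[d]][idx]
  out$species <- factor(out$species)
  out$algorithm <- factor(out$algorithm)
  out
}

#' The candidate fixed effects of the driver analysis
#' @export
driver_fixed_effects <- function()
  c("abundance", "occurrence", "effort", "sst", "sss", "red_tide",
    "algorithm")

#' Fit one linear mixed-effects driver model
#'
#' A linear mixed model with a species random intercept and an AR(1)
#' residual correlation within each species x algorithm annual series,
#' fitted by maximum likelihood (so likelihood-ratio tests on fixed
#' effects are valid). `fixed_effect = "null"` fits the random-effects-only
#' null model. Rows with non-finite response values (e.g. infinite inverse
#' intersection or gap rows) are excluded listwise with a recorded count.
#'
#' @param table a driver table (from [assemble_driver_table()] or
#'   [generate_driver_table()]).
#' @param response name of the response column (e.g. `centroid_distance`,
#'   `volume_change`, `sorensen_dissimilarity`).
#' @param fixed_effect one of [driver_fixed_effects()] or `"null"`.
#' @return An object of class `lmm_result`: fixed-effect table (estimate,
#'   se, sign), variance components (random intercept, residual), AR(1)
#'   coefficient, log-likelihood, marginal R-squared, convergence flag,
#'   number of rows used/excluded, and the underlying `nlme::lme` fit.
#' @export
fit_lmm <- function(table, response, fixed_effect = "null") {
  stopifnot(response %in% names(table))
  if (!fixed_effect %in% c("null", driver_fixed_effects()))
    stop("unknown fixed effect: ", fixed_effect)
  dat <- table
  dat$.y <- dat[[response]]
  keep <- is.finite(dat$.y)
  if (fixed_effect != "null") {
    if (!fixed_effect %in% names(dat))
      stop("driver column absent: ", fixed_effect)
    keep <- keep & !is.na(dat[[fixed_effect]])
  }
  n_excluded <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  dat$species <- factor(dat$species)
  dat$algorithm <- factor(dat$algorithm)
  f <- if (fixed_effect == "null") .y ~ 1 else
    as.formula(paste(".y ~", fixed_effect))
  fit <- try(nlme::lme(
    fixed = f, random = ~ 1 | species,
    correlation = nlme::corAR1(form = ~ year | species / algorithm),
    data = dat, method = "ML",
    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                               opt = "optim", returnObject = TRUE)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("lme failed for response ", response, " ~ ", fixed_effect, ": ",
         attr(fit, "condition")$message)
  vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  var_random <- vc[1]
  var_resid <- vc[2]
  phi <- tryCatch(
    coef(fit$modelStruct$corStruct, unconstrained = FALSE)[["Phi"]],
    error = function(e) NA_real_)
  fe <- nlme::fixef(fit)
  se <- sqrt(diag(fit$varFix))
  fixed_tab <- data.frame(term = names(fe), estimate = as.numeric(fe),
                          se = as.numeric(se),
                          sign = sign(as.numeric(fe)))
  # marginal R2: variance of the fixed-effect predictor over total
  X <- stats::model.matrix(f, dat)
  var_fixed <- if (ncol(X) > 1) var(as.numeric(X %*% fe)) else 0
  marg_r2 <- var_fixed / (var_fixed + var_random + var_resid)
  structure(list(response = response, fixed_effect = fixed_effect,
                 fixed = fixed_tab, var_random = var_random,
                 var_resid = var_resid, ar1 = phi,
                 logLik = as.numeric(logLik(fit)),
                 df = attr(logLik(fit), "df"),
                 marginal_r2 = marg_r2,
                 converged = TRUE, method = "ML",
                 n_used = nrow(dat), n_excluded = n_excluded,
                 fit = fit),
            class = "lmm_result")
}

#' Likelihood-ratio test of a driver model against the null
#'
#' @param fit,null_fit `lmm_result` objects for the same response and data,
#'   both fitted by maximum likelihood, with `null_fit` nested in `fit`.
#' @return List with `statistic` (`2 * (logLik_fit - logLik_null)`,
#'   truncated at 0 against numerical noise), `df` (parameter difference)
#'   and `p` (upper chi-squared tail).
#' @export
lrt <- function(fit, null_fit) {
  stopifnot(inherits(fit, "lmm_result"), inherits(null_fit, "lmm_result"))
  if (fit$method != "ML" || null_fit$method != "ML")
    stop("LRT on fixed effects requires ML fits")
  if (!identical(fit$response, null_fit$response))
    stop("fits compare different responses")
  stat <- max(0, 2 * (fit$logLik - null_fit$logLik))
  df <- fit$df - null_fit$df
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Marginal R-squared of a driver model
#'
#' The proportion of total variance explained by the fixed effects:
#' `var(fixed predictor) / (var fixed + random-intercept var + residual
#' var)`; 0 for the null model.
#'
#' @param fit an `lmm_result`.
#' @return Scalar in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_result"))
  fit$marginal_r2
}

#' Fit the full driver-model grid
#'
#' For each response, fits the null model plus one single-fixed-effect
#' model per candidate driver, and summarizes estimate, sign,
#' likelihood-ratio p-value against the null, and marginal R-squared.
#' For the multi-level `algorithm` factor no single sign exists and `NA`
#' is reported. No multiple-testing correction is applied; p-values are
#' raw likelihood-ratio tests.
#'
#' @param table a driver table.
#' @param responses response column names.
#' @param fixed_effects candidate drivers (default all seven).
#' @return List with `results` (one row per response x fixed effect) and
#'   `fits` (the `lmm_result` objects, keyed `response/fixed_effect`).
#' @export
fit_driver_models <- function(table,
                              responses = c("centroid_distance",
                                            "volume_change",
                                            "sorensen_dissimilarity"),
                              fixed_effects = driver_fixed_effects()) {
  rows <- list()
  fits <- list()
  for (resp in responses) {
    null_fit <- fit_lmm(table, resp, "null")
    fits[[paste(resp, "null", sep = "/")]] <- null_fit
    for (fe in fixed_effects) {
      m <- tryCatch(fit_lmm(table, resp, fe), error = function(e) e)
      if (inherits(m, "error")) {
        warning("driver model ", resp, " ~ ", fe, " failed: ",
                conditionMessage(m))
        rows[[paste(resp, fe)]] <- data.frame(
          response = resp, fixed_effect = fe, estimate = NA_real_,
          sign = NA_real_, lrt_stat = NA_real_, lrt_df = NA_integer_,
          lrt_p = NA_real_, marginal_r2 = NA_real_, ar1 = NA_real_,
          n_used = NA_integer_, n_excluded = NA_integer_)
        next
      }
      fits[[paste(resp, fe, sep = "/")]] <- m
      test <- lrt(m, null_fit)
      est <- m$fixed[m$fixed$term != "(Intercept)", , drop = FALSE]
      single <- nrow(est) == 1
      rows[[paste(resp, fe)]] <- data.frame(
        response = resp, fixed_effect = fe,
        estimate = if (single) est$estimate else NA_real_,
        sign = if (single) est$sign else NA_real_,
        lrt_stat = test$statistic, lrt_df = test$df, lrt_p = test$p,
        marginal_r2 = m$marginal_r2, ar1 = m$ar1,
        n_used = m$n_used, n_excluded = m$n_excluded)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, fits = fits)
}
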