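#' Area under the ROC curve
#'
#' The probability that a randomly chosen presence receives a higher score
#' than a randomly chosen absence, ties counted one half (the normalized
#' Mann-Whitney statistic).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' Sensitivity + specificity - 1 after binarizing the scores. The default
#' rule picks the threshold maximizing TSS on the evaluation data (the
#' common choice when no threshold is prescribed); `"fixed"` uses
#' `threshold` as given.
#'
#' @inheritParams auc
#' @param threshold_rule `"max_tss"` (default) or `"fixed"`.
#' @param threshold cutoff for `"fixed"` (default 0.5); prediction is
#'   presence when `score >= threshold`.
#' @return TSS in \[-1, 1\]; the threshold used is attached as attribute
#'   `threshold`.
#' @export
tss <- function(labels, scores, threshold_rule = c("max_tss", "fixed"),
                threshold = 0.5) {
  threshold_rule <- match.arg(threshold_rule)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  tss_at <- function(th) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred == 1 & labels == 1) / n1
    spec <- sum(pred == 0 & labels == 0) / n0
    sens + spec - 1
  }
  if (threshold_rule == "fixed") {
    out <- tss_at(threshold)
    attr(out, "threshold") <- threshold
    return(out)
  }
  cand <- sort(unique(scores))
  vals <- vapply(cand, tss_at, numeric(1))
  best <- which.max(vals)
  out <- vals[best]
  attr(out, "threshold") <- cand[best]
  out
}

#' Root-mean-squared error of probabilistic predictions
#' @inheritParams auc
#' @return `sqrt(mean((labels - scores)^2))`.
#' @export
rmse <- function(labels, scores) {
  if (length(labels) == 0) stop("empty input")
  stopifnot(length(labels) == length(scores))
  sqrt(mean((labels - scores)^2))
}

#' Adequacy cutoffs for fitted niche models
#'
#' @param auc_min minimum acceptable AUC (default 0.7).
#' @param tss_min minimum acceptable TSS (default 0.4).
#' @param rmse_max maximum acceptable RMSE (default 0.5).
#' @return An object of class `eval_thresholds`.
#' @export
eval_thresholds <- function(auc_min = 0.7, tss_min = 0.4, rmse_max = 0.5) {
  stopifnot(auc_min > 0, auc_min < 1, tss_min > 0, tss_min < 1,
            rmse_max > 0)
  structure(list(auc_min = auc_min, tss_min = tss_min,
                 rmse_max = rmse_max), class = "eval_thresholds")
}

#' Bootstrap evaluation of one model cell
#'
#' For each of `n_boot` replicates the model is refitted on a
#' with-replacement resample of the stations and scored on the stations not
#' drawn into the resample (out-of-bag; `eval_on = "full"` scores on the
#' original data instead). Replicates whose resample is single-class are
#' redrawn (up to 10 tries) and counted as skipped if still degenerate.
#'
#' @param data scaled survey slice (one species, one dataset).
#' @param species_id presence column name.
#' @param settings an [enm_settings()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @param eval_on `"oob"` (default) or `"full"`.
#' @param threshold_rule TSS binarization rule, see [tss()].
#' @return An object of class `eval_result`: point estimates (model fitted
#'   to all data, scored on all data), bootstrap mean/sd per metric,
#'   `n_boot`, skip count, and the settings used.
#' @export
bootstrap_evaluate <- function(data, species_id, settings, n_boot = 1000,
                               seed = 1L, eval_on = c("oob", "full"),
                               threshold_rule = "max_tss") {
  eval_on <- match.arg(eval_on)
  if (n_boot < 1) stop("n_boot must be >= 1")
  full_fit <- fit_enm(data, species_id, settings)
  sc <- predict(full_fit, data)
  y <- data[[species_id]]
  point <- c(auc = auc(y, sc),
             tss = as.numeric(tss(y, sc, threshold_rule)),
             rmse = rmse(y, sc))
  set.seed(seed)
  n <- nrow(data)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("auc", "tss", "rmse")))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      test_idx <- if (eval_on == "oob") setdiff(seq_len(n), idx)
                  else seq_len(n)
      if (length(unique(data[[species_id]][idx])) == 2 &&
          length(test_idx) > 0 &&
          length(unique(data[[species_id]][test_idx])) == 2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    fit_b <- tryCatch(fit_enm(data[idx, , drop = FALSE], species_id,
                              settings),
                      error = function(e) NULL)
    if (is.null(fit_b)) {
      skipped <- skipped + 1L
      next
    }
    test <- data[test_idx, , drop = FALSE]
    sc_b <- predict(fit_b, test)
    y_b <- test[[species_id]]
    reps[b, ] <- c(auc(y_b, sc_b),
                   as.numeric(tss(y_b, sc_b, threshold_rule)),
                   rmse(y_b, sc_b))
  }
  structure(list(point = point,
                 boot_mean = colMeans(reps, na.rm = TRUE),
                 boot_sd = apply(reps, 2, sd, na.rm = TRUE),
                 n_boot = n_boot, skipped = skipped, eval_on = eval_on,
                 threshold_rule = threshold_rule, settings = settings),
            class = "eval_result")
}

#' Classify a model cell as adequate or not
#'
#' Default convention `"not_inaccurate"`: a cell is adequate unless it is
#' inaccurate under the strict inaccuracy definition (AUC < 0.7 or
#' TSS < 0.4 or RMSE > 0.5), i.e. values exactly at a cutoff are adequate.
#' Convention `"strict_adequate"` requires strict inequalities on the
#' adequate side instead (AUC > 0.7 and TSS > 0.4 and RMSE < 0.5), so a
#' value exactly at a cutoff is inadequate.
#'
#' @param result an [bootstrap_evaluate()] result (the bootstrap means are
#'   used, falling back to point estimates if absent).
#' @param thresholds an [eval_thresholds()].
#' @param convention `"not_inaccurate"` (default) or `"strict_adequate"`.
#' @return Logical: adequate or not.
#' @export
classify_adequacy <- function(result, thresholds = eval_thresholds(),
                              convention = c("not_inaccurate",
                                             "strict_adequate")) {
  convention <- match.arg(convention)
  m <- if (!is.null(result$boot_mean) &&
           all(is.finite(result$boot_mean))) result$boot_mean
       else result$point
  if (convention == "strict_adequate")
    m[["auc"]] > thresholds$auc_min && m[["tss"]] > thresholds$tss_min &&
      m[["rmse"]] < thresholds$rmse_max
  else
    !(m[["auc"]] < thresholds$auc_min || m[["tss"]] < thresholds$tss_min ||
        m[["rmse"]] > thresholds$rmse_max)
}
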