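#' Settings for one niche-modelling algorithm
#'
#' The four presence-absence algorithms are fitted in a deliberately simple,
#' fixed structure so that fitted response surfaces are comparable across
#' species, years and algorithms (no per-cell model selection):
#'
#' * `glm_quadratic` — logistic regression with a linear plus squared term
#'   per covariate, so unimodal responses are representable.
#' * `gam_smooth` — binomial additive model with a penalized smooth per
#'   covariate, basis dimension `k = 4`, smoothness chosen by generalized
#'   cross-validation with the GCV score inflated by `gamma = 1.4` to guard
#'   against overfitting.
#' * `random_forest` — 500 probability trees; with three covariates and
#'   three candidate variables per split every variable is a candidate at
#'   every node.
#' * `boosted_trees` — gradient boosting on the binomial deviance, 100
#'   trees of depth 2, learning rate 0.1.
#'
#' @param algorithm one of `glm_quadratic`, `gam_smooth`, `random_forest`,
#'   `boosted_trees`.
#' @param n_trees trees for the two tree ensembles (default 500 for RF,
#'   100 for BRT).
#' @param basis_dimension GAM smooth basis dimension (default 4).
#' @param smoothness_inflation GAM GCV inflation factor (default 1.4).
#' @param candidate_vars_per_split RF mtry (default 3).
#' @param learning_rate BRT shrinkage, in (0, 1] (default 0.1).
#' @param tree_depth BRT tree depth (default 2).
#' @param seed integer seed for the stochastic learners.
#' @return An object of class `enm_settings`.
#' @export
enm_settings <- function(algorithm = c("glm_quadratic", "gam_smooth",
                                       "random_forest", "boosted_trees"),
                         n_trees = NULL, basis_dimension = 4,
                         smoothness_inflation = 1.4,
                         candidate_vars_per_split = 3,
                         learning_rate = 0.1, tree_depth = 2, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(n_trees))
    n_trees <- if (algorithm == "boosted_trees") 100L else 500L
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (basis_dimension < 3) stop("basis_dimension must be >= 3")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  structure(list(algorithm = algorithm, n_trees = as.integer(n_trees),
                 basis_dimension = basis_dimension,
                 smoothness_inflation = smoothness_inflation,
                 candidate_vars_per_split = candidate_vars_per_split,
                 learning_rate = learning_rate, tree_depth = tree_depth,
                 seed = as.integer(seed)),
            class = "enm_settings")
}

#' The four supported algorithm names
#' @export
enm_algorithms <- function() c("glm_quadratic", "gam_smooth",
                               "random_forest", "boosted_trees")

#' Fit one presence-absence niche model
#'
#' @param data data frame with scaled covariate columns (`depth`, `sst`,
#'   `sss`) and a 0/1 presence column named `species_id`.
#' @param species_id name of the presence column.
#' @param settings an [enm_settings()].
#' @param dataset_id label for the data slice (a year, or `"pooled"`).
#' @param covariates covariate names.
#' @return An object of class `enm_fit` with a [predict()] method mapping
#'   covariate points to suitabilities in \[0, 1\].
#' @export
fit_enm <- function(data, species_id, settings,
                    dataset_id = "pooled", covariates = ENV_COVARIATES) {
  stopifnot(inherits(settings, "enm_settings"))
  miss <- setdiff(c(covariates, species_id), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[, c(covariates, species_id)]))
    stop("covariates and response must be complete (no NA)")
  y <- data[[species_id]]
  if (length(unique(y)) < 2)
    stop("single-class response for ", species_id, " / ", dataset_id,
         ": cannot fit a presence-absence model")
  df <- data[, covariates, drop = FALSE]
  df$.y <- y
  converged <- TRUE
  set.seed(settings$seed)
  fit <- switch(
    settings$algorithm,
    glm_quadratic = {
      terms <- paste(vapply(covariates, function(d)
        sprintf("%s + I(%s^2)", d, d), character(1)), collapse = " + ")
      f <- as.formula(paste(".y ~", terms))
      m <- withCallingHandlers(
        glm(f, data = df, family = binomial()),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        })
      if (!m$converged) converged <- FALSE
      # fitted probabilities at machine 0/1 indicate (quasi-)separation
      if (any(m$fitted.values < 1e-10 | m$fitted.values > 1 - 1e-10))
        converged <- FALSE
      m
    },
    gam_smooth = {
      terms <- paste(sprintf("s(%s, k = %d)", covariates,
                             settings$basis_dimension), collapse = " + ")
      f <- as.formula(paste(".y ~", terms))
      m <- withCallingHandlers(
        mgcv::gam(f, data = df, family = binomial(), method = "GCV.Cp",
                  gamma = settings$smoothness_inflation),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        })
      if (!m$converged) converged <- FALSE
      m
    },
    random_forest = randomForest::randomForest(
      x = df[, covariates, drop = FALSE], y = factor(df$.y, levels = 0:1),
      ntree = settings$n_trees,
      mtry = min(settings$candidate_vars_per_split, length(covariates))),
    boosted_trees = {
      dm <- xgboost::xgb.DMatrix(as.matrix(df[, covariates, drop = FALSE]),
                                 label = df$.y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = settings$tree_depth,
                      eta = settings$learning_rate,
                      nthread = 1),
        data = dm, nrounds = settings$n_trees, verbose = 0)
    })
  structure(list(settings = settings, species_id = species_id,
                 dataset_id = as.character(dataset_id),
                 covariates = covariates, fit = fit,
                 converged = converged,
                 n_presence = sum(y == 1), n_absence = sum(y == 0)),
            class = "enm_fit")
}

#' Predict suitability from a fitted niche model
#'
#' @param object an `enm_fit`.
#' @param newdata data frame with the model's covariate columns (scaled
#'   units).
#' @param ... unused.
#' @return Numeric vector of suitabilities in \[0, 1\], one per row.
#' @export
predict.enm_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) stop("newdata lacks covariates: ",
                         paste(miss, collapse = ", "))
  nd <- newdata[, object$covariates, drop = FALSE]
  p <- switch(
    object$settings$algorithm,
    glm_quadratic = predict(object$fit, newdata = nd, type = "response"),
    gam_smooth = as.numeric(
      predict(object$fit, newdata = nd, type = "response")),
    random_forest = predict(object$fit, newdata = nd,
                            type = "prob")[, "1"],
    boosted_trees = predict(object$fit,
                            newdata = xgboost::xgb.DMatrix(as.matrix(nd))))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.enm_fit <- function(x, ...) {
  cat("<enm_fit>", x$settings$algorithm, "|", x$species_id, "|",
      x$dataset_id, "\n  presences:", x$n_presence, " absences:",
      x$n_absence, " converged:", x$converged, "\n")
  invisible(x)
}

#' Fit the full model grid: species x (years + pooled) x algorithms
#'
#' One model per cell. Cells whose fit fails (e.g. a single-class annual
#' response) are recorded in the returned manifest with their error message
#' rather than dropped silently.
#'
#' @param survey scaled survey table (see [apply_scaling()]).
#' @param species character vector of species columns (default: all).
#' @param years years to fit annually (default: all in the survey).
#' @param algorithms algorithm names (default: all four).
#' @param master_seed master seed; each cell gets a [child_seed()].
#' @return List with `models` (named list of `enm_fit`, keys
#'   `species/dataset/algorithm`) and `manifest` (data frame with one row
#'   per cell: species, dataset, algorithm, status, message, n_presence,
#'   converged).
#' @export
fit_model_grid <- function(survey, species = NULL, years = NULL,
                           algorithms = enm_algorithms(),
                           master_seed = 1L) {
  species <- species %||% survey_species(survey)
  years <- years %||% sort(unique(survey$year))
  bad <- setdiff(algorithms, enm_algorithms())
  if (length(bad)) stop("unknown algorithms: ", paste(bad, collapse = ", "))
  datasets <- c(as.character(years), "pooled")
  models <- list()
  rows <- list()
  for (sp in species) for (ds in datasets) for (alg in algorithms) {
    dat <- if (ds == "pooled") survey else survey[survey$year == ds, ]
    key <- paste(sp, ds, alg, sep = "/")
    st <- enm_settings(alg, seed = child_seed(master_seed,
                                              paste0("fit/", key)))
    res <- tryCatch(fit_enm(dat, sp, st, dataset_id = ds),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[key]] <- data.frame(species = sp, dataset = ds, algorithm = alg,
                                status = "failed",
                                message = conditionMessage(res),
                                n_presence = sum(dat[[sp]] == 1),
                                converged = NA)
    } else {
      models[[key]] <- res
      rows[[key]] <- data.frame(species = sp, dataset = ds, algorithm = alg,
                                status = "ok", message = "",
                                n_presence = res$n_presence,
                                converged = res$converged)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(models = models, manifest = manifest)
}
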