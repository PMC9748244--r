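#' Pooled z-score scaling parameters for the environmental covariates
#'
#' All niche hypervolumes are built and compared in one shared, scaled
#' coordinate system: the mean and sd of each covariate are computed once
#' from the pooled (all-years) data and reused for every annual subset.
#'
#' @param data data frame holding the covariate columns (raw units).
#' @param covariates covariate names (default depth, sst, sss).
#' @param provenance free-text note on which dataset the parameters came
#'   from.
#' @return An object of class `scaling_params` with `mean` and `sd` per
#'   covariate.
#' @export
fit_scaling <- function(data, covariates = ENV_COVARIATES,
                        provenance = "pooled survey") {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  m <- vapply(covariates, function(d) mean(data[[d]]), numeric(1))
  s <- vapply(covariates, function(d) sd(data[[d]]), numeric(1))
  if (any(!is.finite(s)) || any(s == 0))
    stop("constant covariate (sd = 0): ",
         paste(covariates[!is.finite(s) | s == 0], collapse = ", "))
  structure(list(mean = m, sd = s, covariates = covariates,
                 provenance = provenance),
            class = "scaling_params")
}

#' Apply (or invert) z-score scaling to a table
#'
#' @param table data frame containing the covariate columns.
#' @param params a [fit_scaling()] result.
#' @return The table with covariate columns replaced by `(x - mean) / sd`
#'   (or the exact inverse for [invert_scaling()]).
#' @export
apply_scaling <- function(table, params) {
  stopifnot(inherits(params, "scaling_params"))
  miss <- setdiff(params$covariates, names(table))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  for (d in params$covariates)
    table[[d]] <- (table[[d]] - params$mean[[d]]) / params$sd[[d]]
  table
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(table, params) {
  stopifnot(inherits(params, "scaling_params"))
  for (d in params$covariates)
    table[[d]] <- table[[d]] * params$sd[[d]] + params$mean[[d]]
  table
}

#' Axis-aligned range box of the (scaled) data
#'
#' The box over which uniform rejection-sampling proposals are drawn:
#' per-dimension `[min, max]` of the pooled scaled data, each side widened
#' by `expansion_fraction * (max - min)`.
#'
#' @param data data frame of scaled covariates.
#' @param covariates covariate names.
#' @param expansion_fraction non-negative widening fraction (default 0: the
#'   box is the data hull).
#' @return An object of class `range_box`: a 2 x d matrix with rows
#'   `lower`, `upper`.
#' @export
range_box_from <- function(data, covariates = ENV_COVARIATES,
                           expansion_fraction = 0) {
  if (nrow(data) == 0) stop("data must be non-empty")
  if (expansion_fraction < 0) stop("expansion_fraction must be >= 0")
  lo <- vapply(covariates, function(d) min(data[[d]]), numeric(1))
  hi <- vapply(covariates, function(d) max(data[[d]]), numeric(1))
  if (any(hi <= lo))
    stop("degenerate dimension (min = max): ",
         paste(covariates[hi <= lo], collapse = ", "))
  w <- expansion_fraction * (hi - lo)
  box <- rbind(lower = lo - w, upper = hi + w)
  colnames(box) <- covariates
  class(box) <- c("range_box", class(box))
  box
}

#' Volume of a range box
#' @param box a [range_box_from()] result.
#' @return Product of the edge lengths.
#' @export
box_volume <- function(box) prod(box["upper", ] - box["lower", ])

#' Serialize scaling parameters to a small structured text file
#' @param params a `scaling_params`.
#' @param path file path (YAML).
#' @export
write_scaling <- function(params, path) {
  yaml::write_yaml(list(mean = as.list(params$mean),
                        sd = as.list(params$sd),
                        covariates = params$covariates,
                        provenance = params$provenance), path)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean = unlist(x$mean)[x$covariates],
                 sd = unlist(x$sd)[x$covariates],
                 covariates = x$covariates, provenance = x$provenance),
            class = "scaling_params")
}
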