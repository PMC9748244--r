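#' Rejection-sample a fitted suitability surface
#'
#' Proposals are drawn uniformly within the range box; proposal `x` is
#' accepted when `u < p(x)` with `u ~ Uniform(0, 1)`, so accepted points
#' are distributed proportionally to predicted occupancy.
#'
#' @param model any object with a [predict()] method returning
#'   suitabilities in \[0, 1\] for a data frame of covariates (typically an
#'   `enm_fit`).
#' @param box a [range_box_from()] result (scaled units).
#' @param n_proposals number of uniform proposals (default 100000).
#' @param seed integer seed.
#' @return List with `points` (data frame of accepted points) and
#'   `acceptance_rate`.
#' @export
rejection_sample <- function(model, box, n_proposals = 1e5, seed = 1L) {
  if (n_proposals < 1) stop("n_proposals must be >= 1")
  dims <- colnames(box)
  set.seed(seed)
  prop <- as.data.frame(lapply(dims, function(d)
    runif(n_proposals, box["lower", d], box["upper", d])))
  names(prop) <- dims
  p <- predict(model, prop)
  keep <- runif(n_proposals) < p
  if (!any(keep)) {
    cell <- if (inherits(model, "enm_fit"))
      paste(model$species_id, model$dataset_id,
            model$settings$algorithm, sep = "/") else "model"
    stop("rejection_sample: zero acceptances for ", cell,
         " (suitability may be ~0 over the whole box)")
  }
  list(points = prop[keep, , drop = FALSE],
       acceptance_rate = mean(keep))
}

silverman_bandwidths <- function(points) {
  n <- nrow(points); d <- ncol(points)
  f <- (4 / ((d + 2) * n))^(1 / (d + 4))
  vapply(points, sd, numeric(1)) * f
}

#' Build a niche hypervolume from a set of sample points
#'
#' A Gaussian product kernel density estimate with per-dimension Silverman
#' bandwidths is fitted to the points; the hypervolume boundary is the
#' density level set enclosing `quantile` of the points' own estimated
#' densities. The hypervolume is represented by a cloud of `cloud_size`
#' uniform random points inside the boundary, obtained by sampling the
#' bandwidth-padded bounding box (padding 3 bandwidths per side) and
#' keeping points whose density reaches the threshold; the enclosed volume
#' is the kept fraction times the padded-box volume.
#'
#' @param points data frame or matrix of sample points (e.g. accepted
#'   rejection-sampling draws), scaled units.
#' @param quantile fraction of the points' own densities enclosed by the
#'   boundary (default 0.95).
#' @param cloud_size number of uniform cloud points (default 10000).
#' @param seed integer seed.
#' @param bandwidth optional fixed per-dimension bandwidths overriding
#'   Silverman's rule.
#' @param min_points minimum number of input points (default 100).
#' @param max_proposal_factor give up (with an error) after
#'   `max_proposal_factor * cloud_size` box proposals (default 500).
#' @param provenance optional named list recorded on the object
#'   (species, dataset, algorithm, ...).
#' @return An object of class `niche_hypervolume`: `points`, `bandwidth`,
#'   `threshold`, `cloud`, `volume`, `dims`, `provenance`.
#' @export
build_hypervolume <- function(points, quantile = 0.95, cloud_size = 1e4,
                              seed = 1L, bandwidth = NULL,
                              min_points = 100, max_proposal_factor = 500,
                              provenance = list()) {
  pts <- as.data.frame(points)
  if (nrow(pts) < min_points)
    stop("too few points (", nrow(pts), " < ", min_points,
         ") to estimate a hypervolume boundary")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  dims <- names(pts)
  h <- bandwidth %||% silverman_bandwidths(pts)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("degenerate point set: a dimension has ~zero spread (",
         paste(dims[!is.finite(h) | h <= 0], collapse = ", "), ")")
  m <- as.matrix(pts)
  dens_self <- kde_gauss_eval(m, h, m)
  # level enclosing `quantile` of the points' own densities
  threshold <- stats::quantile(dens_self, 1 - quantile, names = FALSE)
  lo <- apply(m, 2, min) - 3 * h
  hi <- apply(m, 2, max) + 3 * h
  pad_vol <- prod(hi - lo)
  set.seed(seed)
  cloud <- matrix(numeric(0), 0, length(dims))
  proposed <- 0L
  kept <- 0L
  batch <- max(cloud_size, 5000L)
  while (kept < cloud_size) {
    if (proposed >= max_proposal_factor * cloud_size)
      stop("cloud sampling acceptance rate too low (",
           signif(kept / proposed, 3), "); boundary may be degenerate")
    q <- vapply(seq_along(dims), function(k) runif(batch, lo[k], hi[k]),
                numeric(batch))
    d <- kde_gauss_eval(m, h, q)
    inside <- d >= threshold
    proposed <- proposed + batch
    kept <- kept + sum(inside)
    cloud <- rbind(cloud, q[inside, , drop = FALSE])
  }
  volume <- (kept / proposed) * pad_vol
  cloud <- cloud[seq_len(cloud_size), , drop = FALSE]
  colnames(cloud) <- dims
  structure(list(dims = dims, points = m, bandwidth = h,
                 threshold = threshold, cloud = cloud, volume = volume,
                 padded_box = rbind(lower = lo, upper = hi),
                 quantile = quantile, seed = seed,
                 provenance = provenance),
            class = "niche_hypervolume")
}

#' Build a hypervolume directly from a fitted niche model
#'
#' Convenience wrapper: [rejection_sample()] then [build_hypervolume()],
#' with provenance recorded from the model.
#'
#' @inheritParams rejection_sample
#' @inheritParams build_hypervolume
#' @export
hypervolume_from_enm <- function(model, box, n_proposals = 1e5,
                                 quantile = 0.95, cloud_size = 1e4,
                                 seed = 1L) {
  rs <- rejection_sample(model, box, n_proposals, seed = seed)
  prov <- if (inherits(model, "enm_fit"))
    list(species = model$species_id, dataset = model$dataset_id,
         algorithm = model$settings$algorithm, seed = seed,
         n_proposals = n_proposals,
         acceptance_rate = rs$acceptance_rate) else
    list(seed = seed, n_proposals = n_proposals,
         acceptance_rate = rs$acceptance_rate)
  build_hypervolume(rs$points, quantile = quantile,
                    cloud_size = cloud_size, seed = seed + 1L,
                    provenance = prov)
}

#' Test which points fall inside a hypervolume
#'
#' @param hv a `niche_hypervolume`.
#' @param points data frame or matrix with the hypervolume's dimensions.
#' @return Logical vector: kernel density at the point reaches the
#'   hypervolume's threshold.
#' @export
hv_contains <- function(hv, points) {
  stopifnot(inherits(hv, "niche_hypervolume"))
  pts <- as.matrix(as.data.frame(points)[, hv$dims, drop = FALSE])
  if (ncol(pts) != length(hv$dims)) stop("dimension mismatch")
  kde_gauss_eval(hv$points, hv$bandwidth, pts) >= hv$threshold
}

#' Centroid of a hypervolume
#'
#' Per-dimension mean of the uniform cloud.
#'
#' @param hv a `niche_hypervolume`.
#' @return Named numeric vector.
#' @export
hv_centroid <- function(hv) {
  stopifnot(inherits(hv, "niche_hypervolume"))
  if (nrow(hv$cloud) == 0) stop("empty cloud")
  colMeans(hv$cloud)
}

#' Serialize a hypervolume to disk with a plain-text provenance sidecar
#'
#' The object is written as an RDS archive; a YAML sidecar
#' (`<path>.provenance.yml`) carries the provenance, seed, quantile,
#' threshold and volume so runs remain auditable without loading R
#' objects.
#'
#' @param hv a `niche_hypervolume`.
#' @param path file path for the archive.
#' @return `path`, invisibly.
#' @export
write_hypervolume <- function(hv, path) {
  stopifnot(inherits(hv, "niche_hypervolume"))
  saveRDS(hv, path)
  yaml::write_yaml(
    c(hv$provenance,
      list(quantile = hv$quantile, seed = hv$seed,
           threshold = unname(hv$threshold), volume = hv$volume,
           n_support_points = nrow(hv$points),
           cloud_size = nrow(hv$cloud))),
    paste0(path, ".provenance.yml"))
  invisible(path)
}

#' @rdname write_hypervolume
#' @export
read_hypervolume <- function(path) {
  hv <- readRDS(path)
  stopifnot(inherits(hv, "niche_hypervolume"))
  hv
}

#' @export
print.niche_hypervolume <- function(x, ...) {
  cat("<niche_hypervolume>", paste(x$dims, collapse = " x "),
      "\n  volume:", signif(x$volume, 4),
      " cloud:", nrow(x$cloud), " support points:", nrow(x$points),
      "\n  quantile:", x$quantile, " threshold:", signif(x$threshold, 4),
      "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               unlist(x$provenance), sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}
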