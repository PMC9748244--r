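#' Euclidean distance between two hypervolume centroids
#' @param a,b `niche_hypervolume` objects with the same dimensions.
#' @return Non-negative scalar; symmetric in its arguments.
#' @export
centroid_distance <- function(a, b) {
  check_same_dims(a, b)
  sqrt(sum((hv_centroid(a) - hv_centroid(b))^2))
}

#' Minimum Euclidean distance between two hypervolume clouds
#'
#' The smallest distance over all cross-pairs of the two uniform clouds;
#' approximately zero for overlapping hypervolumes.
#'
#' @inheritParams centroid_distance
#' @export
minimum_distance <- function(a, b) {
  check_same_dims(a, b)
  if (nrow(a$cloud) == 0 || nrow(b$cloud) == 0) stop("empty cloud")
  min_cross_distance(a$cloud, b$cloud)
}

#' Monte-Carlo intersection volume of two hypervolumes
#'
#' Symmetric mutual-inclusion estimator
#' \deqn{V_\cap \approx \tfrac12\,(f_b(a) V_a + f_a(b) V_b),}
#' where `f_b(a)` is the fraction of `a`'s cloud inside `b`'s boundary.
#' Monte-Carlo noise can push the estimate above `min(V_a, V_b)`; it is
#' then clipped with a warning.
#'
#' @inheritParams centroid_distance
#' @export
intersection_volume <- function(a, b) {
  check_same_dims(a, b)
  f_ab <- mean(hv_contains(b, a$cloud))  # fraction of a inside b
  f_ba <- mean(hv_contains(a, b$cloud))
  v <- 0.5 * (f_ab * a$volume + f_ba * b$volume)
  cap <- min(a$volume, b$volume)
  if (v > cap) {
    warning("intersection volume ", signif(v, 4),
            " exceeds min(Va, Vb); clipped to ", signif(cap, 4))
    v <- cap
  }
  max(v, 0)
}

#' Inverse intersection of two hypervolumes
#'
#' The reciprocal of the fraction of the combined clouds falling inside
#' both hypervolumes; 1 for identical hypervolumes, infinite when no point
#' is shared (a legal value, excluded from driver models downstream).
#'
#' @inheritParams centroid_distance
#' @export
inverse_intersection <- function(a, b) {
  check_same_dims(a, b)
  n_ab <- sum(hv_contains(b, a$cloud))
  n_ba <- sum(hv_contains(a, b$cloud))
  frac <- (n_ab + n_ba) / (nrow(a$cloud) + nrow(b$cloud))
  if (frac == 0) Inf else 1 / frac
}

#' Absolute volume difference between two hypervolumes
#' @inheritParams centroid_distance
#' @export
volume_change <- function(a, b) abs(a$volume - b$volume)

#' Sorensen-Dice and Jaccard dissimilarity between two hypervolumes
#'
#' Both range from 0 (fully overlapped) to 1 (fully disjunct):
#' Sorensen-Dice dissimilarity is `1 - 2 * V_int / (V_a + V_b)`; Jaccard
#' dissimilarity is `1 - V_int / (V_a + V_b - V_int)`. Jaccard
#' dissimilarity is always at least the Sorensen-Dice dissimilarity.
#'
#' @inheritParams centroid_distance
#' @param v_int optional precomputed [intersection_volume()].
#' @export
sorensen_dissimilarity <- function(a, b, v_int = NULL) {
  check_positive_volumes(a, b)
  v_int <- v_int %||% intersection_volume(a, b)
  clamp01(1 - 2 * v_int / (a$volume + b$volume))
}

#' @rdname sorensen_dissimilarity
#' @export
jaccard_dissimilarity <- function(a, b, v_int = NULL) {
  check_positive_volumes(a, b)
  v_int <- v_int %||% intersection_volume(a, b)
  clamp01(1 - v_int / (a$volume + b$volume - v_int))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

check_same_dims <- function(a, b) {
  stopifnot(inherits(a, "niche_hypervolume"),
            inherits(b, "niche_hypervolume"))
  if (!identical(a$dims, b$dims))
    stop("hypervolume dimension mismatch: ",
         paste(a$dims, collapse = ","), " vs ",
         paste(b$dims, collapse = ","))
}

check_positive_volumes <- function(a, b) {
  check_same_dims(a, b)
  if (a$volume <= 0 || b$volume <= 0)
    stop("hypervolume volumes must be positive")
}

#' All six comparison metrics for one hypervolume pair
#'
#' @inheritParams centroid_distance
#' @return Named numeric vector: `centroid_distance`, `minimum_distance`,
#'   `inverse_intersection`, `volume_change`, `sorensen_dissimilarity`,
#'   `jaccard_dissimilarity`, plus the two volumes.
#' @export
hv_metrics <- function(a, b) {
  v_int <- intersection_volume(a, b)
  c(centroid_distance = centroid_distance(a, b),
    minimum_distance = minimum_distance(a, b),
    inverse_intersection = inverse_intersection(a, b),
    volume_change = volume_change(a, b),
    sorensen_dissimilarity = sorensen_dissimilarity(a, b, v_int),
    jaccard_dissimilarity = jaccard_dissimilarity(a, b, v_int),
    annual_volume = a$volume, pooled_volume = b$volume)
}

#' Compare every annual hypervolume to its pooled reference
#'
#' @param hypervolumes named list of `niche_hypervolume` objects keyed
#'   `species/dataset/algorithm`, where `dataset` is a year or `"pooled"`;
#'   (as produced by the pipeline's hypervolume stage).
#' @return A data frame (`metric_table`), one row per
#'   (species, year, algorithm). Cells whose annual hypervolume is missing
#'   appear as explicit gap rows (metrics `NA`, `gap = TRUE`); a missing
#'   pooled hypervolume for a (species, algorithm) pair is an error.
#' @export
compare_annual_to_pooled <- function(hypervolumes) {
  keys <- strsplit(names(hypervolumes), "/", fixed = TRUE)
  stopifnot(all(lengths(keys) == 3))
  info <- data.frame(species = vapply(keys, `[`, "", 1),
                     dataset = vapply(keys, `[`, "", 2),
                     algorithm = vapply(keys, `[`, "", 3))
  years <- sort(unique(info$dataset[info$dataset != "pooled"]))
  combos <- unique(info[info$dataset != "pooled",
                        c("species", "algorithm")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sp <- combos$species[i]; alg <- combos$algorithm[i]
    pooled_key <- paste(sp, "pooled", alg, sep = "/")
    pooled <- hypervolumes[[pooled_key]]
    if (is.null(pooled))
      stop("missing pooled hypervolume for ", sp, "/", alg)
    for (yr in years) {
      key <- paste(sp, yr, alg, sep = "/")
      hv <- hypervolumes[[key]]
      if (is.null(hv)) {
        m <- setNames(rep(NA_real_, 8),
                      c("centroid_distance", "minimum_distance",
                        "inverse_intersection", "volume_change",
                        "sorensen_dissimilarity", "jaccard_dissimilarity",
                        "annual_volume", "pooled_volume"))
        gap <- TRUE
      } else {
        m <- hv_metrics(hv, pooled)
        gap <- FALSE
      }
      rows[[key]] <- data.frame(species = sp, year = as.integer(yr),
                                algorithm = alg, t(m), gap = gap)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}
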