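# Hypervolume fixtures shared across metric tests (built once per file).
hv_a <- make_cube_hv(c(0, 0, 0), n = 8000, cloud = 3000, seed = 61)
hv_half <- make_cube_hv(c(0.5, 0, 0), n = 8000, cloud = 3000, seed = 62)
hv_far <- make_cube_hv(c(100, 0, 0), n = 8000, cloud = 3000, seed = 63)

test_that("self-comparison is the zero of every metric", {
  expect_equal(centroid_distance(hv_a, hv_a), 0)
  expect_equal(minimum_distance(hv_a, hv_a), 0)
  expect_equal(inverse_intersection(hv_a, hv_a), 1)
  expect_equal(volume_change(hv_a, hv_a), 0)
  expect_equal(sorensen_dissimilarity(hv_a, hv_a), 0)
  expect_equal(jaccard_dissimilarity(hv_a, hv_a), 0)
})

test_that("disjoint hypervolumes are fully dissimilar", {
  expect_equal(sorensen_dissimilarity(hv_a, hv_far), 1)
  expect_equal(jaccard_dissimilarity(hv_a, hv_far), 1)
  expect_identical(inverse_intersection(hv_a, hv_far), Inf)
  expect_equal(intersection_volume(hv_a, hv_far), 0)
  # unit cubes centred 100 apart leave a gap of 99 between faces
  md <- minimum_distance(hv_a, hv_far)
  expect_gt(md, 98.5)
  expect_lt(md, 99.3)
})

test_that("translation moves the centroid distance by the shift", {
  # same point seed and build seed: the translated cloud is an exact copy
  pts <- cube_points(8000, c(0, 0, 0), seed = 61)
  pts3 <- pts
  pts3$depth <- pts3$depth + 3
  hv3 <- build_hypervolume(pts3, cloud_size = 3000, seed = 61 + 1000)
  expect_equal(centroid_distance(hv_a, hv3), 3, tolerance = 1e-10)
  # cubes at the origin and (1,1,1): centroid distance sqrt(3)
  hv111 <- make_cube_hv(c(1, 1, 1), n = 8000, cloud = 3000, seed = 64)
  expect_equal(centroid_distance(hv_a, hv111), sqrt(3), tolerance = 0.05)
})

test_that("half-offset unit cubes match the closed-form overlap", {
  v_int <- intersection_volume(hv_a, hv_half)
  # the 0.95-quantile boundary erodes ~(1-q) of each support, biasing the
  # raw intersection volume low; the ratio metrics largely cancel it
  expect_lt(abs(v_int - 0.5), 0.06)
  expect_equal(sorensen_dissimilarity(hv_a, hv_half), 0.5,
               tolerance = 0.05)
  expect_equal(jaccard_dissimilarity(hv_a, hv_half), 2 / 3,
               tolerance = 0.05)
  expect_equal(inverse_intersection(hv_a, hv_half), 2, tolerance = 0.05)
  expect_lt(minimum_distance(hv_a, hv_half), 0.05)
  # symmetry
  expect_equal(sorensen_dissimilarity(hv_half, hv_a),
               sorensen_dissimilarity(hv_a, hv_half))
  expect_equal(volume_change(hv_a, hv_half), volume_change(hv_half, hv_a))
})

test_that("volume change is the absolute volume difference", {
  a <- hv_a; b <- hv_a
  a$volume <- 1; b$volume <- 1.5
  expect_equal(volume_change(a, b), 0.5)
  expect_equal(volume_change(b, a), 0.5)
})

test_that("metric identities hold across a ladder of separations", {
  offsets <- c(0, 0.4, 0.8, 1.4)
  hvs <- lapply(seq_along(offsets), function(i)
    make_cube_hv(c(offsets[i], 0, 0), n = 5000, cloud = 2000,
                 seed = 70, point_seed = 70))
  cd <- sor <- jac <- numeric(length(offsets))
  for (i in seq_along(offsets)) {
    v_int <- intersection_volume(hv_a, hvs[[i]])
    cd[i] <- centroid_distance(hv_a, hvs[[i]])
    sor[i] <- sorensen_dissimilarity(hv_a, hvs[[i]], v_int)
    jac[i] <- jaccard_dissimilarity(hv_a, hvs[[i]], v_int)
  }
  # monotone response to increasing translation
  expect_true(all(diff(cd) > 0))
  expect_true(all(diff(sor) >= -1e-9))
  expect_true(all(diff(jac) >= -1e-9))
  # Jaccard dissimilarity dominates Sorensen-Dice, both within [0, 1]
  expect_true(all(jac >= sor - 1e-12))
  expect_true(all(sor >= 0 & sor <= 1 & jac >= 0 & jac <= 1))
})

test_that("dimension mismatches and bad volumes are rejected", {
  hv2d <- hv_a
  hv2d$dims <- c("depth", "sst")
  expect_error(centroid_distance(hv_a, hv2d), "dimension mismatch")
  bad <- hv_a
  bad$volume <- 0
  expect_error(sorensen_dissimilarity(hv_a, bad), "positive")
})

test_that("annual-vs-pooled comparison enumerates and flags gaps", {
  small <- function(center, seed) make_cube_hv(center, n = 2000,
                                               cloud = 700, seed = seed)
  hvs <- list(
    "sp1/2009/glm" = small(c(0, 0, 0), 81),
    "sp1/2010/glm" = small(c(0.3, 0, 0), 82),
    "sp1/pooled/glm" = small(c(0, 0, 0), 83),
    "sp2/2009/glm" = small(c(0, 0.2, 0), 84),
    "sp2/2010/glm" = small(c(0, 0.4, 0), 85),
    "sp2/pooled/glm" = small(c(0, 0.3, 0), 86))
  tab <- compare_annual_to_pooled(hvs)
  expect_equal(nrow(tab), 4)  # 2 species x 2 years x 1 algorithm
  expect_true(all(!tab$gap))
  expect_true(all(tab$jaccard_dissimilarity >=
                    tab$sorensen_dissimilarity - 1e-12))
  # a year identical to the pooled reference scores zero dissimilarity
  hvs2 <- list("sp1/2009/glm" = hvs[["sp1/pooled/glm"]],
               "sp1/pooled/glm" = hvs[["sp1/pooled/glm"]])
  tab2 <- compare_annual_to_pooled(hvs2)
  expect_equal(tab2$sorensen_dissimilarity, 0)
  expect_equal(tab2$centroid_distance, 0)
  # a missing annual cell becomes an explicit gap row
  hvs3 <- hvs
  hvs3[["sp2/2010/glm"]] <- NULL
  tab3 <- compare_annual_to_pooled(hvs3)
  expect_equal(nrow(tab3), 4)
  gap_row <- tab3[tab3$species == "sp2" & tab3$year == 2010, ]
  expect_true(gap_row$gap)
  expect_true(is.na(gap_row$sorensen_dissimilarity))
  # a missing pooled reference is an error
  hvs4 <- hvs
  hvs4[["sp1/pooled/glm"]] <- NULL
  expect_error(compare_annual_to_pooled(hvs4), "missing pooled")
})
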