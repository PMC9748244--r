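# Shared fixtures, all generated in code.

# A constant-suitability "model" for exercising rejection sampling and
# hypervolume construction without a fitted ENM.
const_model <- function(p) structure(list(p = p), class = "const_suit")
predict.const_suit <- function(object, newdata, ...)
  rep(object$p, nrow(newdata))
registerS3method("predict", "const_suit", predict.const_suit)

# Uniform points in an axis-aligned cube of edge 1 centred at `center`.
cube_points <- function(n, center = c(0, 0, 0), seed = 1, edge = c(1, 1, 1)) {
  set.seed(seed)
  data.frame(depth = runif(n, center[1] - edge[1] / 2, center[1] + edge[1] / 2),
             sst = runif(n, center[2] - edge[2] / 2, center[2] + edge[2] / 2),
             sss = runif(n, center[3] - edge[3] / 2, center[3] + edge[3] / 2))
}

make_cube_hv <- function(center = c(0, 0, 0), n = 8000, cloud = 3000,
                         seed = 1, edge = c(1, 1, 1), point_seed = seed) {
  build_hypervolume(cube_points(n, center, seed = point_seed, edge = edge),
                    cloud_size = cloud, seed = seed + 1000)
}

# A small scaled survey with a sharply unimodal species at the origin of
# scaled covariate space, for ENM fitting tests.
unimodal_survey <- function(n = 1500, seed = 1, breadth = 0.7,
                            pmax = 0.95) {
  set.seed(seed)
  d <- data.frame(depth = runif(n, -2, 2), sst = runif(n, -2, 2),
                  sss = runif(n, -2, 2), year = 2009L)
  p <- pmax * exp(-(d$depth^2 + d$sst^2 + d$sss^2) / (2 * breadth^2))
  d$spx <- rbinom(n, 1, p)
  d
}

# A tiny raw-unit multi-species survey for grid / pipeline tests.
tiny_survey <- function(n_species = 2, years = 2009:2011,
                        effort = c(150, 160, 170), seed = 1) {
  des <- survey_design(years = years, effort = effort[seq_along(years)],
                       covariate_ranges = list(depth = c(10, 200),
                                               sst = c(17, 30),
                                               sss = c(25, 36)),
                       seed = seed)
  generate_survey(des, default_species_pool(n_species))
}
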