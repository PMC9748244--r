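#' Virtual species niche specification
#'
#' Describes a virtual species whose probability of occupancy is a product of
#' Gaussian response curves over the three environmental covariates,
#' \deqn{p(x) = p_{max} \prod_d \exp\{-(x_d - \mu_d)^2 / (2 \sigma_d^2)\},}
#' where \eqn{\mu_d} is the niche optimum and \eqn{\sigma_d} the niche
#' breadth on covariate \eqn{d}. The optimum and breadth are expressed in
#' raw covariate units (m, deg C, psu).
#'
#' @param species_id character label, used as the survey column name.
#' @param optimum named numeric vector of niche optima for `depth`, `sst`,
#'   `sss`.
#' @param breadth named numeric vector of positive niche breadths (sd of the
#'   Gaussian response), same names.
#' @param max_occupancy occupancy probability at the optimum, in (0, 1].
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, optimum, breadth, max_occupancy = 0.9) {
  stopifnot(is.character(species_id), length(species_id) == 1)
  optimum <- optimum[ENV_COVARIATES]
  breadth <- breadth[ENV_COVARIATES]
  if (anyNA(optimum) || anyNA(breadth))
    stop("optimum and breadth must be named over: ",
         paste(ENV_COVARIATES, collapse = ", "))
  if (any(breadth <= 0)) stop("niche breadth must be > 0 for every covariate")
  if (max_occupancy <= 0 || max_occupancy > 1)
    stop("max_occupancy must be in (0, 1]")
  structure(list(species_id = species_id, optimum = optimum,
                 breadth = breadth, max_occupancy = max_occupancy),
            class = "niche_spec")
}

#' True occupancy probability of a virtual species
#'
#' @param spec a [niche_spec()].
#' @param newdata data frame with `depth`, `sst`, `sss` in raw units.
#' @return Numeric vector of occupancy probabilities in \[0, 1\].
#' @export
true_suitability <- function(spec, newdata) {
  stopifnot(inherits(spec, "niche_spec"))
  p <- rep(spec$max_occupancy, nrow(newdata))
  for (d in ENV_COVARIATES) {
    z <- (newdata[[d]] - spec$optimum[[d]]) / spec$breadth[[d]]
    p <- p * exp(-0.5 * z^2)
  }
  p
}

#' Multi-year survey design
#'
#' @param years ordered integer vector of survey years.
#' @param effort positive integer vector, one station count per year.
#' @param covariate_ranges named list of `c(min, max)` per covariate, raw
#'   units.
#' @param seed integer seed controlling all survey randomness.
#' @param year_shift optional named list of per-covariate numeric vectors
#'   (one value per year) added to the covariate draws, emulating interannual
#'   environmental shifts; default none.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(years, effort, covariate_ranges, seed = 1L,
                          year_shift = NULL) {
  if (length(years) == 0) stop("years must be non-empty")
  if (length(effort) != length(years) || any(effort < 1))
    stop("effort must give a positive station count for every year")
  for (d in ENV_COVARIATES) {
    r <- covariate_ranges[[d]]
    if (is.null(r) || length(r) != 2 || r[1] >= r[2])
      stop("covariate_ranges$", d, " must be c(min, max) with min < max")
  }
  if (!is.null(year_shift)) {
    for (d in names(year_shift))
      stopifnot(length(year_shift[[d]]) == length(years))
  }
  structure(list(years = as.integer(years), effort = as.integer(effort),
                 covariate_ranges = covariate_ranges[ENV_COVARIATES],
                 seed = as.integer(seed), year_shift = year_shift),
            class = "survey_design")
}

#' Survey design emulating a 12-year shelf bottom-trawl programme
#'
#' Twelve annual surveys (2009-2020) with the observed per-year station
#' counts of a Gulf-of-Mexico shelf trawl programme
#' (241, 243, 151, 237, 209, 297, 261, 215, 257, 260, 237, 90; 2,698
#' stations in total). Covariate ranges follow the shelf setting: depth
#' 10-200 m, SST 17-30 deg C, SSS 25-36 psu.
#'
#' @param seed integer seed.
#' @param year_shift optional, see [survey_design()].
#' @return A `survey_design`.
#' @export
default_survey_design <- function(seed = 1L, year_shift = NULL) {
  survey_design(
    years = 2009:2020,
    effort = c(241L, 243L, 151L, 237L, 209L, 297L, 261L, 215L, 257L, 260L,
               237L, 90L),
    covariate_ranges = list(depth = c(10, 200), sst = c(17, 30),
                            sss = c(25, 36)),
    seed = seed, year_shift = year_shift)
}

#' A pool of virtual demersal species spanning common to rare
#'
#' Ten species with niche optima spread over the covariate ranges of
#' [default_survey_design()] and occupancy ceilings graded from high to
#' moderate, so that mean prevalence spans roughly 0.8 down to 0.4 — the
#' occupancy gradient of a dominant demersal assemblage, in which even the
#' least common species clears 20 presences in the smallest annual survey.
#'
#' @param n number of species (up to 10).
#' @return List of [niche_spec()] objects.
#' @export
default_species_pool <- function(n = 10) {
  stopifnot(n >= 1, n <= 10)
  opt_depth <- c(70, 90, 55, 105, 75, 45, 95, 65, 110, 60)
  opt_sst   <- c(24, 23, 25.5, 22.5, 24.5, 26, 23.5, 24, 22, 25)
  opt_sss   <- c(32, 31.5, 33, 31, 32.5, 33.5, 30.5, 32, 34, 31)
  br_depth  <- c(130, 120, 115, 110, 105, 100, 95, 90, 85, 80)
  br_sst    <- c(11, 10.5, 10, 9.5, 9, 8.5, 8.5, 8, 7.5, 7.5)
  br_sss    <- c(10, 9.5, 9, 9, 8.5, 8, 8, 7.5, 7, 7)
  pmax      <- c(1.0, 0.98, 0.95, 0.92, 0.88, 0.85, 0.82, 0.78, 0.75, 0.72)
  lapply(seq_len(n), function(i)
    niche_spec(sprintf("sp%02d", i),
               optimum = c(depth = opt_depth[i], sst = opt_sst[i],
                           sss = opt_sss[i]),
               breadth = c(depth = br_depth[i], sst = br_sst[i],
                           sss = br_sss[i]),
               max_occupancy = pmax[i]))
}

#' Generate a synthetic multi-year presence-absence survey
#'
#' One row per sampling station. Covariates are drawn uniformly within the
#' design ranges (plus any per-year shift); presence of each species is a
#' Bernoulli draw from its Gaussian niche response evaluated at the station.
#' Identical seeds give identical tables.
#'
#' @param design a [survey_design()].
#' @param niches list of [niche_spec()] objects (at least one).
#' @param abundance if `TRUE`, also emit a count column `n_<species>` per
#'   species: zero where absent, `1 + Poisson(abundance_scale * p(x))` where
#'   present, supporting the abundance driver.
#' @param abundance_scale Poisson mean multiplier (default 20).
#' @return A data frame (`survey_table`) with columns `station_id`, `year`,
#'   `lon`, `lat`, `depth`, `sst`, `sss`, then one 0/1 column per species
#'   (and optional count columns).
#' @export
generate_survey <- function(design, niches, abundance = FALSE,
                            abundance_scale = 20) {
  stopifnot(inherits(design, "survey_design"))
  if (length(niches) == 0) stop("at least one niche_spec is required")
  stopifnot(all(vapply(niches, inherits, logical(1), "niche_spec")))
  set.seed(design$seed)
  n <- sum(design$effort)
  year <- rep(design$years, design$effort)
  tab <- data.frame(
    station_id = sprintf("st%05d", seq_len(n)),
    year = year,
    lon = runif(n, -87.5, -81.0),
    lat = runif(n, 24.5, 30.5))
  for (d in ENV_COVARIATES) {
    r <- design$covariate_ranges[[d]]
    x <- runif(n, r[1], r[2])
    if (!is.null(design$year_shift[[d]])) {
      shift <- design$year_shift[[d]][match(year, design$years)]
      x <- x + shift
    }
    tab[[d]] <- x
  }
  for (sp in niches) {
    p <- true_suitability(sp, tab)
    pres <- rbinom(n, 1L, p)
    tab[[sp$species_id]] <- pres
    if (abundance) {
      cnt <- integer(n)
      cnt[pres == 1L] <- 1L + rpois(sum(pres), abundance_scale * p[pres == 1L])
      tab[[paste0("n_", sp$species_id)]] <- cnt
    }
  }
  class(tab) <- c("survey_table", "data.frame")
  attr(tab, "species") <- vapply(niches, `[[`, character(1), "species_id")
  tab
}

#' Species columns of a survey table
#' @param survey a survey table.
#' @return Character vector of presence/absence column names.
#' @export
survey_species <- function(survey) {
  sp <- attr(survey, "species")
  if (!is.null(sp)) return(sp)
  reserved <- c("station_id", "year", "lon", "lat", ENV_COVARIATES)
  nm <- setdiff(names(survey), reserved)
  nm[!startsWith(nm, "n_")]
}

#' Generate annual (and optionally monthly) environmental grids
#'
#' Emulates the preparation of annual environmental raster layers: monthly
#' SST and SSS fields are averaged within each year to produce the annual
#' layer, while depth is a static field shared by all years. Fields are
#' smooth gradients over the grid plus year effects and monthly seasonal
#' variation; values stay within the design covariate ranges.
#'
#' @param design a [survey_design()].
#' @param grid_shape integer `c(nrow, ncol)` of the grid, both positive.
#' @param monthly if `TRUE` (default) emit the 12 monthly layers per year
#'   per dynamic covariate in addition to their annual mean.
#' @param resolution grid cell size in degrees, recorded as metadata
#'   (default 0.041).
#' @return A long-format data frame (`env_grid`) with columns `covariate`,
#'   `year`, `month` (`NA` for annual means and for depth), `row`, `col`,
#'   `value`; attributes `resolution` and `grid_shape`.
#' @export
generate_environment_grids <- function(design, grid_shape = c(20L, 20L),
                                       monthly = TRUE, resolution = 0.041) {
  stopifnot(inherits(design, "survey_design"))
  if (any(grid_shape < 1)) stop("grid_shape must be positive in both axes")
  set.seed(design$seed + 1L)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cell <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  out <- list()
  # static depth field: a shore-to-shelf gradient
  r <- design$covariate_ranges$depth
  depth_field <- r[1] + (r[2] - r[1]) *
    ((cell$row - 1) / max(1, nr - 1) * 0.7 +
       (cell$col - 1) / max(1, nc - 1) * 0.3)
  out[[length(out) + 1L]] <- data.frame(
    covariate = "depth", year = NA_integer_, month = NA_integer_,
    row = cell$row, col = cell$col, value = depth_field)
  for (d in c("sst", "sss")) {
    r <- design$covariate_ranges[[d]]
    base <- r[1] + (r[2] - r[1]) *
      ((cell$col - 1) / max(1, nc - 1) * 0.6 +
         (cell$row - 1) / max(1, nr - 1) * 0.2 + 0.1)
    amp <- 0.08 * (r[2] - r[1])
    for (i in seq_along(design$years)) {
      yr <- design$years[i]
      yr_eff <- rnorm(1, 0, 0.05 * (r[2] - r[1]))
      monthly_vals <- vapply(1:12, function(m)
        base + yr_eff + amp * sin(2 * pi * (m - 3) / 12) +
          rnorm(nrow(cell), 0, 0.02 * (r[2] - r[1])),
        numeric(nrow(cell)))
      if (monthly) {
        for (m in 1:12)
          out[[length(out) + 1L]] <- data.frame(
            covariate = d, year = yr, month = m,
            row = cell$row, col = cell$col, value = monthly_vals[, m])
      }
      out[[length(out) + 1L]] <- data.frame(
        covariate = d, year = yr, month = NA_integer_,
        row = cell$row, col = cell$col, value = rowMeans(monthly_vals))
    }
  }
  grids <- do.call(rbind, out)
  attr(grids, "resolution") <- resolution
  attr(grids, "grid_shape") <- as.integer(grid_shape)
  class(grids) <- c("env_grid", "data.frame")
  grids
}

#' Driver scenario for synthetic niche-metric responses
#'
#' Defines year-indexed candidate driver series and the true (injected)
#' effect of each driver on a niche-metric response, plus the variance
#' components of the generating mixed model.
#'
#' @param drivers data frame with column `year` and one column per driver
#'   (any of `abundance`, `occurrence`, `effort`, `sst`, `sss`, `red_tide`).
#' @param slopes named numeric vector of injected slopes per driver
#'   (drivers not named get slope 0).
#' @param random_intercept_sd sd of the species random intercept.
#' @param ar1_rho AR(1) coefficient of the residual series, in (-1, 1).
#' @param residual_sd innovation sd of the AR(1) residuals, > 0.
#' @return An object of class `driver_scenario`.
#' @export
driver_scenario <- function(drivers, slopes = numeric(),
                            random_intercept_sd = 0.2, ar1_rho = 0.3,
                            residual_sd = 0.3) {
  stopifnot(is.data.frame(drivers), "year" %in% names(drivers))
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie strictly inside (-1, 1)")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  bad <- setdiff(names(slopes), setdiff(names(drivers), "year"))
  if (length(bad)) stop("slopes name unknown drivers: ",
                        paste(bad, collapse = ", "))
  structure(list(drivers = drivers, slopes = slopes,
                 random_intercept_sd = random_intercept_sd,
                 ar1_rho = ar1_rho, residual_sd = residual_sd),
            class = "driver_scenario")
}

#' Default driver scenario over a set of years
#'
#' Standardized (mean 0, sd 1) driver series: smooth trends plus noise for
#' abundance, occurrence, effort, SST and SSS, and a non-negative skewed
#' red-tide severity index (standardized after generation).
#'
#' @param years integer years.
#' @param seed integer seed.
#' @inheritParams driver_scenario
#' @return A `driver_scenario`.
#' @export
default_driver_scenario <- function(years, slopes = numeric(), seed = 1L,
                                    random_intercept_sd = 0.2,
                                    ar1_rho = 0.3, residual_sd = 0.3) {
  set.seed(seed)
  ny <- length(years)
  t <- seq_len(ny)
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  drv <- data.frame(
    year = years,
    abundance = std(10 + 2 * sin(2 * pi * t / 6) + rnorm(ny)),
    occurrence = std(60 + 5 * cos(2 * pi * t / 5) + rnorm(ny, 0, 3)),
    effort = std(200 + 30 * rnorm(ny)),
    sst = std(24 + 0.05 * t + rnorm(ny, 0, 0.5)),
    sss = std(33 + rnorm(ny, 0, 0.8)),
    red_tide = std(rexp(ny, 1)))
  driver_scenario(drv, slopes = slopes,
                  random_intercept_sd = random_intercept_sd,
                  ar1_rho = ar1_rho, residual_sd = residual_sd)
}

#' Generate a synthetic niche-metric response table with known ground truth
#'
#' Builds a (species x year x algorithm) response table from
#' \deqn{y_{sat} = \sum_k \beta_k\, driver_k(t) + b_s + \varepsilon_{sat},}
#' with species intercepts \eqn{b_s \sim N(0, \sigma_b^2)} and, within each
#' species x algorithm series, AR(1) residuals with coefficient `ar1_rho`
#' and innovation sd `residual_sd`. The stationary marginal sd of the
#' residuals is `residual_sd / sqrt(1 - ar1_rho^2)`.
#'
#' @param scenario a [driver_scenario()].
#' @param n_species number of species (random-intercept groups).
#' @param n_algorithms number of replicate series per species (default 4,
#'   one per niche-modelling algorithm).
#' @param seed integer seed.
#' @return List with `table` (data frame: `species`, `year`, `algorithm`,
#'   drivers, `response`) and `truth` (the generating parameters, including
#'   the drawn species intercepts).
#' @export
generate_driver_table <- function(scenario, n_species = 10,
                                  n_algorithms = 4, seed = 1L) {
  stopifnot(inherits(scenario, "driver_scenario"))
  set.seed(seed)
  drv <- scenario$drivers
  ny <- nrow(drv)
  species <- sprintf("sp%02d", seq_len(n_species))
  algos <- paste0("alg", seq_len(n_algorithms))
  b <- rnorm(n_species, 0, scenario$random_intercept_sd)
  names(b) <- species
  fixed <- rep(0, ny)
  for (k in names(scenario$slopes))
    fixed <- fixed + scenario$slopes[[k]] * drv[[k]]
  rows <- vector("list", n_species * n_algorithms)
  i <- 0L
  for (s in seq_len(n_species)) for (a in algos) {
    eps <- numeric(ny)
    # stationary AR(1) start so the marginal variance is constant in t
    eps[1] <- rnorm(1, 0, scenario$residual_sd /
                      sqrt(1 - scenario$ar1_rho^2))
    if (ny > 1) for (t in 2:ny)
      eps[t] <- scenario$ar1_rho * eps[t - 1] +
        rnorm(1, 0, scenario$residual_sd)
    i <- i + 1L
    rows[[i]] <- data.frame(species = species[s], year = drv$year,
                            algorithm = a, drv[setdiff(names(drv), "year")],
                            response = fixed + b[s] + eps)
  }
  tab <- do.call(rbind, rows)
  tab$species <- factor(tab$species)
  tab$algorithm <- factor(tab$algorithm)
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(slopes = scenario$slopes,
                    random_intercept_sd = scenario$random_intercept_sd,
                    ar1_rho = scenario$ar1_rho,
                    residual_sd = scenario$residual_sd,
                    species_intercepts = b))
}

#' Drop species with too few presences in any year
#'
#' Retains only species observed at least `min_presence_per_year` times in
#' every survey year, mirroring the common practice of excluding sparse
#' species whose annual models would be unreliable.
#'
#' @param survey a survey table from [generate_survey()].
#' @param min_presence_per_year non-negative presence threshold (default 20).
#' @return The filtered survey table; attribute `dropped_species` lists the
#'   removed species with their worst-year presence count.
#' @export
filter_species <- function(survey, min_presence_per_year = 20) {
  stopifnot(min_presence_per_year >= 0)
  species <- survey_species(survey)
  worst <- vapply(species, function(sp)
    min(tapply(survey[[sp]], survey$year, sum)), numeric(1))
  keep <- names(worst)[worst >= min_presence_per_year]
  drop <- setdiff(species, keep)
  if (length(drop))
    message("filter_species: dropped ", length(drop), " species (",
            paste0(drop, " [min ", worst[drop], "]", collapse = ", "), ")")
  out <- survey[, setdiff(names(survey),
                          c(drop, paste0("n_", drop))), drop = FALSE]
  class(out) <- class(survey)
  attr(out, "species") <- keep
  attr(out, "dropped_species") <- worst[drop]
  out
}

#' Write / read a survey table as delimited text
#' @param survey a survey table.
#' @param path file path.
#' @export
write_survey <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("survey_table", "data.frame")
  tab
}
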