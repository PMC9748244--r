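#' Configuration for a full synthetic niche-dynamics run
#'
#' One object controls every stage; all randomness descends from
#' `master_seed` via [child_seed()], so runs are reproducible end to end
#' and adding a species does not shift other cells' random streams.
#'
#' @param out_dir output directory (created if needed).
#' @param design a [survey_design()] (default [default_survey_design()]
#'   seeded from `master_seed`).
#' @param niches list of [niche_spec()] (default
#'   [default_species_pool()]).
#' @param min_presence_per_year species filter threshold (default 20).
#' @param algorithms algorithms to fit (default all four; must be a
#'   non-empty subset).
#' @param n_proposals,cloud_size,quantile hypervolume settings.
#' @param n_boot bootstrap replicates for evaluation; 0 skips the
#'   evaluation stage.
#' @param thresholds an [eval_thresholds()].
#' @param responses,fixed_effects driver-model settings.
#' @param abundance include survey count columns (default TRUE, so the
#'   abundance driver is available).
#' @param master_seed integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            design = NULL, niches = NULL,
                            min_presence_per_year = 20,
                            algorithms = enm_algorithms(),
                            n_proposals = 1e5, cloud_size = 1e4,
                            quantile = 0.95,
                            n_boot = 0, thresholds = eval_thresholds(),
                            responses = c("centroid_distance",
                                          "volume_change",
                                          "sorensen_dissimilarity"),
                            fixed_effects = driver_fixed_effects(),
                            abundance = TRUE,
                            master_seed = 1L) {
  if (length(algorithms) == 0) stop("algorithms must be non-empty")
  bad <- setdiff(algorithms, enm_algorithms())
  if (length(bad)) stop("unsupported algorithms: ",
                        paste(bad, collapse = ", "))
  if (is.null(master_seed)) stop("master_seed must be set")
  design <- design %||% default_survey_design(
    seed = child_seed(master_seed, "survey"))
  niches <- niches %||% default_species_pool()
  structure(list(out_dir = out_dir, design = design, niches = niches,
                 min_presence_per_year = min_presence_per_year,
                 algorithms = algorithms, n_proposals = n_proposals,
                 cloud_size = cloud_size, quantile = quantile,
                 n_boot = n_boot, thresholds = thresholds,
                 responses = responses, fixed_effects = fixed_effects,
                 abundance = abundance,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Enumerate the model grid of a configuration without fitting
#'
#' @param config a [pipeline_config()].
#' @return Data frame of (species, dataset, algorithm) cells.
#' @export
enumerate_model_grid <- function(config) {
  species <- vapply(config$niches, `[[`, character(1), "species_id")
  datasets <- c(as.character(config$design$years), "pooled")
  expand.grid(species = species, dataset = datasets,
              algorithm = config$algorithms, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Simulate stage: survey, species filter, annual drivers
#' @param config a [pipeline_config()].
#' @param state pipeline state list (created if missing).
#' @return Updated state with `survey` (filtered, raw units) and
#'   `annual_drivers`; writes `survey.csv` and `annual_drivers.csv`.
#' @export
stage_simulate <- function(config, state = list()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  survey <- generate_survey(config$design, config$niches,
                            abundance = config$abundance)
  survey <- filter_species(survey, config$min_presence_per_year)
  scen <- default_driver_scenario(
    config$design$years, seed = child_seed(config$master_seed, "drivers"))
  state$survey <- survey
  state$annual_drivers <- scen$drivers[, c("year", "sst", "sss",
                                           "red_tide")]
  write_survey(survey, file.path(config$out_dir, "survey.csv"))
  write.csv(state$annual_drivers,
            file.path(config$out_dir, "annual_drivers.csv"),
            row.names = FALSE)
  state
}

#' Fit stage: pooled scaling and the full model grid
#' @inheritParams stage_simulate
#' @return State with `scaling`, `scaled_survey`, `box`, `models`,
#'   `fit_manifest`; writes `scaling.yml` and `fit_manifest.csv`.
#' @export
stage_fit <- function(config, state) {
  if (is.null(state$survey)) stop("missing upstream output: survey ",
                                  "(run stage_simulate first)")
  scaling <- fit_scaling(state$survey)
  scaled <- apply_scaling(state$survey, scaling)
  state$scaling <- scaling
  state$scaled_survey <- scaled
  state$box <- range_box_from(scaled)
  grid <- fit_model_grid(scaled, algorithms = config$algorithms,
                         master_seed = config$master_seed)
  state$models <- grid$models
  state$fit_manifest <- grid$manifest
  write_scaling(scaling, file.path(config$out_dir, "scaling.yml"))
  write.csv(grid$manifest, file.path(config$out_dir, "fit_manifest.csv"),
            row.names = FALSE)
  state
}

#' Evaluation stage: bootstrap metrics and adequacy per cell
#' @inheritParams stage_simulate
#' @return State with `evaluation`; writes `evaluation.csv`.
#' @export
stage_evaluate <- function(config, state) {
  if (is.null(state$models)) stop("missing upstream output: models ",
                                  "(run stage_fit first)")
  if (config$n_boot < 1) {
    state$evaluation <- NULL
    return(state)
  }
  rows <- lapply(names(state$models), function(key) {
    m <- state$models[[key]]
    dat <- if (m$dataset_id == "pooled") state$scaled_survey else
      state$scaled_survey[state$scaled_survey$year == m$dataset_id, ]
    ev <- bootstrap_evaluate(dat, m$species_id, m$settings,
                             n_boot = config$n_boot,
                             seed = child_seed(config$master_seed,
                                               paste0("eval/", key)))
    data.frame(species = m$species_id, dataset = m$dataset_id,
               algorithm = m$settings$algorithm,
               auc = ev$boot_mean[["auc"]], tss = ev$boot_mean[["tss"]],
               rmse = ev$boot_mean[["rmse"]],
               auc_sd = ev$boot_sd[["auc"]], n_boot = ev$n_boot,
               skipped = ev$skipped,
               adequate = classify_adequacy(ev, config$thresholds))
  })
  state$evaluation <- do.call(rbind, rows)
  write.csv(state$evaluation, file.path(config$out_dir, "evaluation.csv"),
            row.names = FALSE)
  state
}

#' Hypervolume stage: one hypervolume per successfully fitted cell
#' @inheritParams stage_simulate
#' @return State with `hypervolumes` (named list) and
#'   `hypervolume_manifest`; writes `hypervolume_manifest.csv`.
#' @export
stage_hypervolumes <- function(config, state) {
  if (is.null(state$models)) stop("missing upstream output: models ",
                                  "(run stage_fit first)")
  hvs <- list()
  rows <- list()
  for (key in names(state$models)) {
    hv <- tryCatch(
      hypervolume_from_enm(state$models[[key]], state$box,
                           n_proposals = config$n_proposals,
                           quantile = config$quantile,
                           cloud_size = config$cloud_size,
                           seed = child_seed(config$master_seed,
                                             paste0("hv/", key))),
      error = function(e) e)
    if (inherits(hv, "error")) {
      rows[[key]] <- data.frame(key = key, status = "failed",
                                volume = NA_real_,
                                message = conditionMessage(hv))
    } else {
      hvs[[key]] <- hv
      rows[[key]] <- data.frame(key = key, status = "ok",
                                volume = hv$volume, message = "")
    }
  }
  state$hypervolumes <- hvs
  state$hypervolume_manifest <- do.call(rbind, rows)
  rownames(state$hypervolume_manifest) <- NULL
  write.csv(state$hypervolume_manifest,
            file.path(config$out_dir, "hypervolume_manifest.csv"),
            row.names = FALSE)
  state
}

#' Metrics stage: annual-vs-pooled comparison table
#' @inheritParams stage_simulate
#' @return State with `metrics`; writes `metrics.csv`.
#' @export
stage_metrics <- function(config, state) {
  if (is.null(state$hypervolumes))
    stop("missing upstream output: hypervolumes ",
         "(run stage_hypervolumes first)")
  state$metrics <- compare_annual_to_pooled(state$hypervolumes)
  write.csv(state$metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  state
}

#' Driver stage: assemble driver table and fit the mixed-model grid
#' @inheritParams stage_simulate
#' @return State with `driver_table` and `driver_results`; writes
#'   `driver_table.csv` and `driver_results.csv`.
#' @export
stage_drivers <- function(config, state) {
  if (is.null(state$metrics)) stop("missing upstream output: metrics ",
                                   "(run stage_metrics first)")
  tab <- assemble_driver_table(state$metrics, state$survey,
                               state$annual_drivers)
  state$driver_table <- tab
  fe <- config$fixed_effects
  if (all(is.na(tab$abundance))) fe <- setdiff(fe, "abundance")
  if (length(unique(tab$algorithm)) < 2) fe <- setdiff(fe, "algorithm")
  # constant drivers (e.g. equal effort every year) carry no information
  const <- vapply(setdiff(fe, "algorithm"), function(d)
    sd(tab[[d]], na.rm = TRUE) == 0, logical(1))
  fe <- setdiff(fe, names(const)[const])
  dm <- fit_driver_models(tab, responses = config$responses,
                          fixed_effects = fe)
  state$driver_results <- dm$results
  state$driver_fits <- dm$fits
  write.csv(tab, file.path(config$out_dir, "driver_table.csv"),
            row.names = FALSE)
  write.csv(dm$results, file.path(config$out_dir, "driver_results.csv"),
            row.names = FALSE)
  state
}

#' Run the full pipeline end to end
#'
#' filter -> scale -> fit grid -> (evaluate) -> hypervolumes -> metrics ->
#' driver models, then writes `manifest.csv` listing every produced text
#' output with its MD5 checksum. Two runs with the same configuration and
#' master seed produce identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param dry_run if `TRUE`, return the enumerated model grid without
#'   fitting anything.
#' @return The final state list (invisibly), with a `manifest` element.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dry_run) return(enumerate_model_grid(config))
  state <- stage_simulate(config)
  state <- stage_fit(config, state)
  state <- stage_evaluate(config, state)
  state <- stage_hypervolumes(config, state)
  state <- stage_metrics(config, state)
  state <- stage_drivers(config, state)
  files <- sort(list.files(config$out_dir,
                           pattern = "\\.(csv|yml)$", full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  state$manifest <- manifest
  invisible(state)
}
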