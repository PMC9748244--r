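#!/usr/bin/env Rscript
# Stage 4 — one three-dimensional niche hypervolume per fitted cell:
# rejection-sample the suitability surface inside the pooled range box,
# then estimate the kernel-density boundary and Monte-Carlo volume.
#
# Sample sizes are reduced from the package defaults (100,000 proposals /
# 10,000 cloud points) to keep this desk run tractable on one CPU.

library(nichedyn)

out <- "results"
master_seed <- 2024L
n_proposals <- 2e4
cloud_size <- 2000

survey <- read_survey(file.path(out, "survey.csv"))
scaling <- read_scaling(file.path(out, "scaling.yml"))
scaled <- apply_scaling(survey, scaling)
box <- range_box_from(scaled)
models <- readRDS(file.path(out, "models.rds"))

hvs <- list()
rows <- list()
for (key in names(models)) {
  hv <- tryCatch(
    hypervolume_from_enm(models[[key]], box, n_proposals = n_proposals,
                         cloud_size = cloud_size,
                         seed = child_seed(master_seed,
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
manifest <- do.call(rbind, rows)
write.csv(manifest, file.path(out, "hypervolume_manifest.csv"),
          row.names = FALSE)
saveRDS(hvs, file.path(out, "hypervolumes.rds"))

cat("Hypervolumes built:", sum(manifest$status == "ok"), "of",
    nrow(manifest), "\n")
cat("Volume range (scaled units^3):",
    sprintf("%.2f-%.2f", min(manifest$volume, na.rm = TRUE),
            max(manifest$volume, na.rm = TRUE)), "\n")
cat("Wrote hypervolume_manifest.csv, hypervolumes.rds\n")
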