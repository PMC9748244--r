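# nichedyn

Temporal dynamics of estimated environmental niche hypervolumes.

## What this is for

Ecological niche models (ENMs) predict where a species can occur from
environmental covariates, and the Hutchinsonian *hypervolume* — here a
three-dimensional region over scaled depth, sea-surface temperature and
sea-surface salinity — summarizes the environmental space the fitted
model considers suitable. When a multi-year survey is modelled year by
year, the estimated niche fluctuates, and those fluctuations mix real
biology with artefacts of sampling effort, population state and the
modelling algorithm itself. `nichedyn` is for ecologists who want to
quantify that: it fits annual and pooled (all-years) presence–absence
ENMs per species with four algorithms (quadratic logistic regression,
penalized additive models with basis dimension 4 and GCV inflation 1.4,
500-tree random forests, 100-tree depth-2 boosted trees), turns each
fitted model into a hypervolume, compares annual against pooled niches,
and attributes the metric variation to candidate drivers.

The core constructions:

* **Rejection sampling**: proposals uniform in the range box of the
  pooled scaled data; proposal *x* is kept when *u* < *p̂(x)*, so
  accepted points follow predicted occupancy.
* **Hypervolume**: a Gaussian product-kernel density with per-dimension
  Silverman bandwidths on the accepted points; the boundary is the
  density level set enclosing 95% of the points' own densities; the
  region is represented by a uniform cloud and its Monte-Carlo volume.
* **Six comparison metrics** per (species, year, algorithm): centroid
  distance, minimum cloud distance, inverse intersection, volume change
  |V_a − V_b|, Sørensen-Dice dissimilarity 1 − 2V∩/(V_a+V_b) and
  Jaccard dissimilarity 1 − V∩/(V_a+V_b−V∩).
* **Driver models**: linear mixed models (maximum likelihood) with a
  species random intercept and AR(1) residuals within each
  species × algorithm series; one null model plus seven
  single-fixed-effect models (abundance, occurrence, effort, SST, SSS,
  red-tide severity, algorithm), compared by likelihood-ratio tests and
  marginal R².

Everything runs on synthetic surveys with known ground truth — virtual
species with Gaussian niche responses over a 12-year trawl-style design
(2,698 stations) — so the whole pipeline is testable without restricted
survey data.

## Worked example

```r
library(nichedyn)

design <- survey_design(years = 2009:2011, effort = c(130L, 150L, 170L),
                        covariate_ranges = list(depth = c(10, 200),
                                                sst = c(17, 30),
                                                sss = c(25, 36)),
                        seed = 11)
cfg <- pipeline_config(out_dir = "run", design = design,
                       niches = default_species_pool(2),
                       algorithms = c("glm_quadratic", "random_forest"),
                       n_proposals = 6000, cloud_size = 700,
                       master_seed = 11)
state <- run_pipeline(cfg)
nrow(state$fit_manifest)
#> [1] 16
head(state$metrics[, c("species", "year", "algorithm",
                       "centroid_distance", "sorensen_dissimilarity")], 3)
#>   species year     algorithm centroid_distance sorensen_dissimilarity
#> 1    sp01 2009 glm_quadratic        0.06152822             0.05945276
#> 2    sp01 2010 glm_quadratic        0.07856723             0.04499026
#> 3    sp01 2011 glm_quadratic        0.09801287             0.04415935
```

16 cells is 2 species × (3 years + pooled) × 2 algorithms. Each metric
row compares one annual hypervolume with its pooled reference; here the
environment is interannually stable, so centroid distances of ~0.06–0.1
scaled units and Sørensen-Dice dissimilarities of ~0.04–0.06 are pure
sampling-plus-algorithm noise — the baseline against which real niche
shifts would stand out. `state$driver_results` holds the mixed-model
summary (estimate, sign, LRT p, marginal R²) per response × driver.

The numbered scripts under `analysis/` run the same workflow at the
full study scale (10 species, 12 years + pooled, 4 algorithms = 520
model cells) and write tidy tables under `results/`: run them in order
from the repository root.

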