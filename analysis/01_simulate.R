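#!/usr/bin/env Rscript

# Simulate the default synthetic cohort: 1,653 right eyes with per-sex
# covariates and ground-truth fundus scenes, plus a handful of rendered
# example images.  Writes results/sim/.

suppressPackageStartupMessages(library(fundusindex))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config()          # defaults: n = 1653, seed 20050501
sim <- simulate_cohort(cfg)

write_cohort_csv(sim$subjects, file.path(out, "cohort.csv"))
write_features_csv(sim$features, file.path(out, "features.csv"))

by_sex <- split(sim$subjects, sim$subjects$sex)
fmt <- function(x) sprintf("%.2f +/- %.2f", mean(x), sd(x))
cat("Cohort summary (", nrow(sim$subjects), "right eyes )\n")
for (sx in c("male", "female")) {
  g <- by_sex[[sx]]
  cat(sprintf("  %-6s n=%4d  age %s  height %s cm  axial %s mm\n",
              sx, nrow(g), fmt(g$age), fmt(g$height_cm),
              fmt(g$axial_length_mm)))
}

# a few rendered examples with their landmark files
ex <- simulate_cohort(cohort_config(n_subjects = 4, seed = cfg$seed),
                      scenes = TRUE)
for (id in names(ex$scenes)[1:3]) {
  rr <- render_image(ex$scenes[[id]])
  write_image_png(rr$image, file.path(out, paste0(id, ".png")))
  write_landmarks(rr$landmarks, file.path(out, paste0(id, ".json")))
}
cat("wrote", out, "\n")
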