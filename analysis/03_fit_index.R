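#!/usr/bin/env Rscript

# Fit the ridge logistic model on the simulated cohort's 42 parameters
# and compute the leave-one-out cross-validated fundus sex index
# (one held-out fit per eye).  Requires 01_simulate.R.  Writes
# results/index.csv, results/model.json.

suppressPackageStartupMessages(library(fundusindex))

cohort <- read.csv("results/sim/cohort.csv")
features <- read_features_csv("results/sim/features.csv")
y <- as.integer(cohort$sex == "female")

set.seed(20050501)
lambda <- as.numeric(select_lambda(features, y))
cat(sprintf("lambda selected by 10-fold CV: %.4g\n", lambda))

res <- loocv_index(features, y, lambda, ids = cohort$subject_id)
write.csv(res$index, "results/index.csv", row.names = FALSE)
write_model_json(res$model, "results/model.json")

cat(sprintf("LOOCV: %d held-out fits, AROC = %.3f\n", res$n_fits, res$aroc))
idx <- res$index$fundus_sex_index
for (sx in c("male", "female"))
  cat(sprintf("  %-6s index %.2f +/- %.2f\n", sx,
              mean(idx[cohort$sex == sx]), sd(idx[cohort$sex == sx])))
cat(sprintf("  classified correctly at 0.5 threshold: %.1f%%\n",
            100 * mean((idx > 0.5) == (y == 1))))
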