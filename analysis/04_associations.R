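#!/usr/bin/env Rscript

# Association analyses of the fundus sex index: correlations with body
# height and axial length (all / men / women), sex-group comparisons,
# index ~ height + sex, and the stepwise regression of axial length on
# the index plus all 42 parameters.  Requires 01 and 03.  Writes
# results/report/.

suppressPackageStartupMessages(library(fundusindex))

cohort <- read.csv("results/sim/cohort.csv")
truth <- read.csv("results/sim/cohort_truth.csv")
cohort <- merge(cohort, truth, by = "subject_id")
features <- read_features_csv("results/sim/features.csv")
index <- read.csv("results/index.csv")

rep <- build_report(index, cohort, features = features)
write_report(rep, "results/report")

cat("Fundus sex index correlations (Pearson r / Spearman rho):\n")
with(rep$correlations,
     for (i in seq_along(variable))
       cat(sprintf("  %-13s %-7s r = %+.3f  rho = %+.3f  p = %.3g\n",
                   variable[i], subgroup[i], pearson_r[i], spearman_rho[i],
                   pearson_p[i])))

cat("\nSex comparisons (Mann-Whitney):\n")
with(rep$group_tests,
     for (i in seq_along(variable))
       cat(sprintf("  %-17s male %8.2f  female %8.2f  p = %.3g%s\n",
                   variable[i], mean_male[i], mean_female[i], p_value[i],
                   ifelse(significant[i], " *", ""))))

cat("\nIndex ~ height + sex, standardized coefficients:\n")
print(round(rep$index_on_height_sex$std_coefficients, 3))

sw <- rep$stepwise$all
cat(sprintf("\nStepwise for axial length (all): %d variables selected; index %s\n",
            length(sw$selected),
            if ("fundus_sex_index" %in% sw$selected)
              sprintf("selected (std coef %+.3f)",
                      sw$std_coefficients["fundus_sex_index"])
            else "not selected"))
cat("wrote results/report/\n")
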