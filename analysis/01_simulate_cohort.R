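#!/usr/bin/env Rscript
# Simulate the study-shaped cohorts every later stage consumes:
#  - a null cohort with the default design (28 controls / 11 cases, two
#    time points, paired subjects, log-normal depths)
#  - the same design with a 2x case-group depth confound
#  - an unpaired benchmarking cohort with an 8-fold signal implanted on
#    five mid-to-low-abundance features
# Outputs go to results/cohorts/<name>/ as TSV + truth JSON + manifest.

suppressPackageStartupMessages(library(condaba))
seed <- 20260921L

cohorts <- list(
  null_study = sim_config(seed = derive_seed(seed, "null")),
  depth_confound = sim_config(depth_group_shift = 2,
                              seed = derive_seed(seed, "depth")),
  implanted = sim_config(n_paired_control = 0, n_early_only_control = 50,
                         n_late_only_control = 0, n_paired_case = 0,
                         n_early_only_case = 50, n_late_only_case = 0,
                         n_diff = 5, log2_fold_changes = 3,
                         seed = derive_seed(seed, "signal")))

for (nm in names(cohorts)) {
  cfg <- cohorts[[nm]]
  co <- simulate_cohort(cfg)
  dir <- file.path("results", "cohorts", nm)
  write_cohort(co, dir, cfg = cfg, force = TRUE)
  m <- co$meta
  cat(sprintf(
    "%s: %d samples (%d control / %d case), %d features, %d truth features\n",
    nm, nrow(m), sum(m$group == "control"), sum(m$group == "case"),
    ncol(co$table$values), length(co$truth$feature_ids)))
}
cat("cohorts written under results/cohorts/\n")
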