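#!/usr/bin/env Rscript
# Tool-concordance metrics across a battery of benchmarking datasets:
# for every engine, the share of its calls that are consensus, the share
# of consensus features it finds, and its min-max-normalized call count,
# aggregated as median (IQR) across datasets with consensus features.

suppressPackageStartupMessages(library(condaba))
seed <- 20260921L
n_datasets <- 8

records <- NULL
for (i in seq_len(n_datasets)) {
  s <- derive_seed(seed, paste0("concord", i))
  co <- simulate_cohort(sim_config(
    n_features = 200, n_paired_control = 0, n_early_only_control = 40,
    n_late_only_control = 0, n_paired_case = 0, n_early_only_case = 40,
    n_late_only_case = 0, n_diff = 5, log2_fold_changes = c(3, -3),
    seed = s))
  cfg <- engine_config(mc_samples = 128, n_perm = 199, seed = s)
  outr <- run_all_engines(list(sgb = co$table), co$meta, da_design(),
                          "counts", cfg)
  cons <- consensus_across_levels(outr$results)
  records <- rbind(records,
                   tool_metrics(outr$results$sgb, cons,
                                dataset_id = paste0("sim", i)))
}

out <- file.path("results", "concordance")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.table(records, file.path(out, "tool_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
agg <- aggregate_metrics(records)
write.table(agg, file.path(out, "tool_metrics_aggregated.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (mt in unique(agg$metric)) {
  cat("\n", mt, ":\n", sep = "")
  sub <- agg[agg$metric == mt, ]
  sub <- sub[order(-sub$median), ]
  for (i in seq_len(nrow(sub)))
    cat(sprintf("  %-12s %.1f (%.1f-%.1f)\n", sub$engine[i],
                sub$median[i], sub$q1[i], sub$q3[i]))
}
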