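#!/usr/bin/env Rscript
# Diversity analyses of the null study cohort: rarefied alpha diversity by
# group, depth-richness correlation, Aitchison beta diversity with the
# dispersion-gated PERMANOVA, and the matched/unmatched stability
# comparison across time points. Reads results/cohorts/null_study.

suppressPackageStartupMessages(library(condaba))
seed <- 20260921L

dirc <- file.path("results", "cohorts", "null_study")
counts <- read_feature_table(file.path(dirc, "counts.tsv"), "count", "sgb")
meta <- read_sample_metadata(file.path(dirc, "metadata.tsv"))
out <- file.path("results", "diversity")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# alpha diversity on rarefied counts (rarefy to the shallowest sample)
depth <- min(rowSums(counts$values))
rare <- rarefy(counts, depth, seed = derive_seed(seed, "rarefaction"))
alpha <- alpha_diversity(rare)
alpha <- merge(alpha, meta[, c("sample_id", "group", "timepoint")],
               by = "sample_id")
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (tp in c("early", "late")) {
  a <- alpha[alpha$timepoint == tp, ]
  p <- rank_sum_test(a$shannon[a$group == "control"],
                     a$shannon[a$group == "case"], exact_max = 0)$p
  cat(sprintf("shannon control vs case (%s): medians %.2f / %.2f, p=%.3f\n",
              tp, median(a$shannon[a$group == "control"]),
              median(a$shannon[a$group == "case"]), p))
}

# depth sensitivity of richness before rarefaction
raw_rich <- data.frame(sample_id = ft_samples(counts),
                       richness = rowSums(counts$values > 0))
dr <- depth_richness_corr(meta, raw_rich)
cat(sprintf("depth-richness Spearman rho=%.3f (p=%.2g)\n", dr$rho, dr$p))

# beta diversity: Aitchison distances, dispersion gate, PERMANOVA
rel <- to_proportions(counts)
dm <- aitchison(rel, 1e-6)
meta_o <- meta[match(ft_samples(counts), meta$sample_id), ]
disp <- permdisp(dm, meta_o$group, n_perm = 999,
                 seed = derive_seed(seed, "permdisp"))
pmv <- permanova(dm, meta_o$group, n_perm = 9999,
                 seed = derive_seed(seed, "permanova"))
cat(sprintf("permdisp p=%.3f (gate %s); permanova F=%.2f R2=%.3f p=%.4f%s\n",
            disp$p, ifelse(disp$gate_pass, "passes", "fails"),
            pmv$pseudo_F, pmv$R2, pmv$p,
            ifelse(disp$gate_pass, "", " [not reported: dispersion gate]")))

# time-point contrast with permutations restricted within subject
pmv_tp <- permanova(dm, meta_o$timepoint, n_perm = 9999,
                    seed = derive_seed(seed, "permanova_tp"),
                    strata = meta_o$subject_id)
cat(sprintf("time-point permanova (within-subject perms) p=%.4f\n", pmv_tp$p))

# stability: matched vs unmatched distances, and per group
mu <- matched_unmatched(dm, meta)
mb <- matched_by_group(dm, meta)
cat(sprintf("matched median %.2f vs unmatched %.2f, p=%.3g\n",
            median(mu$matched), median(mu$unmatched), mu$p))
cat(sprintf("control vs case matched distances: p=%.3f (%s test)\n",
            mb$p, mb$test))
stab <- rbind(data.frame(set = "matched", distance = mu$matched),
              data.frame(set = "unmatched", distance = mu$unmatched))
write.table(stab, file.path(out, "stability_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
dmat <- as.matrix(dm)
write.table(data.frame(sample_id = rownames(dmat), dmat,
                       check.names = FALSE),
            file.path(out, "aitchison_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
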