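# Independent oracles: brute-force definitions kept deliberately separate
# from the package implementations they check.

# Benjamini-Hochberg straight from the definition: q(i) = min_{j>=i} p(j)*m/j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(ps[i:m] * m / (i:m), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# Holm step-down: adjusted p = max_{j<=i} (m-j+1)*p(j), clipped to 1
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- cummax((m - seq_len(m) + 1) * ps)
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# exact two-sided Wilcoxon rank-sum by complete enumeration of assignments
brute_wilcox_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  obs <- abs(sum(r[seq_len(nx)]) - nx * (length(r) + 1) / 2)
  combos <- combn(length(r), nx)
  devs <- abs(colSums(matrix(r[combos], nrow = nx)) -
                nx * (length(r) + 1) / 2)
  mean(devs >= obs - 1e-12)
}

# two-sided Fisher/hypergeometric p for a 2x2 table by full enumeration
brute_fisher_2x2 <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  probs <- dhyper(max(0, k - n):min(k, m), m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# simple labelled count table builders -----------------------------------

make_table <- function(values, unit = "count", level = "genus",
                       samples = NULL, features = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  rownames(values) <- samples %||% sprintf("S%02d", seq_len(nrow(values)))
  colnames(values) <- features %||% sprintf("F%02d", seq_len(ncol(values)))
  feature_table(values, unit, level, check_sums = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_meta <- function(table, group = NULL, timepoint = "early",
                      subject = NULL, depth = NULL, bmi = NULL) {
  ids <- rownames(table$values)
  n <- length(ids)
  data.frame(sample_id = ids,
             subject_id = subject %||% paste0("U", seq_len(n)),
             group = group %||% rep(c("control", "case"), length.out = n),
             timepoint = rep(timepoint, length.out = n),
             bmi = bmi %||% rep(25, n),
             library_size = depth %||% rowSums(table$values) + (rowSums(table$values) == 0),
             stringsAsFactors = FALSE)
}

# a small unpaired two-group cohort, one sample per subject
null_cohort <- function(seed, n_per_group = 20, n_features = 200, ...) {
  simulate_cohort(sim_config(
    n_features = n_features,
    n_paired_control = 0, n_early_only_control = n_per_group,
    n_late_only_control = 0,
    n_paired_case = 0, n_early_only_case = n_per_group,
    n_late_only_case = 0, seed = seed, ...))
}

write_taxonomy_fixture <- function(path) {
  lines <- c(
    "clade_name\tS1\tS2\tS3",
    "k__Bacteria\t100\t100\t100",
    "k__Bacteria|p__Proteobacteria\t60\t55\t70",
    "k__Bacteria|p__Firmicutes\t40\t45\t30",
    "k__Bacteria|p__Proteobacteria|c__Gammaproteobacteria\t30\t25\t50",
    "k__Bacteria|p__Firmicutes|c__Bacilli\t70\t75\t50")
  writeLines(lines, path)
  path
}

write_pathway_fixture <- function(path, with_unmapped = TRUE) {
  lines <- c("# Pathway\tS1\tS2",
             if (with_unmapped) "UNMAPPED\t500\t400",
             "PWY-1: one\t100\t110",
             "PWY-1: one|g__Escherichia.s__coli\t60\t70",
             "PWY-1: one|g__Bacteroides.s__dorei\t40\t40",
             "PWY-1: one|unclassified\t0\t0",
             "PWY-2: two\t30\t20",
             "PWY-2: two|g__Escherichia.s__coli\t10\t5",
             "PWY-2: two|g__Bacteroides.s__dorei\t20\t15",
             "PWY-2: two|unclassified\t0\t0")
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  path
}
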