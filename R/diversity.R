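#' Alpha diversity of a rarefied count table
#'
#' Shannon index in natural log units, richness as the number of observed
#' features, and Pielou's evenness (Shannon divided by log richness; 0 for
#' a single-feature sample). Requires an even-depth (rarefied) table, since
#' richness is strongly depth-sensitive.
#'
#' @param x rarefied count \code{feature_table} (equal row sums).
#' @return data.frame with \code{sample_id}, \code{shannon},
#'   \code{richness}, \code{evenness}.
#' @export
alpha_diversity <- function(x) {
  v <- x$values
  rs <- rowSums(v)
  if (max(rs) - min(rs) > 1e-9)
    stop("unequal sample depths; rarefy before alpha diversity")
  shannon <- apply(v, 1, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p))
  })
  richness <- rowSums(v > 0)
  evenness <- ifelse(richness > 1, shannon / log(richness), 0)
  data.frame(sample_id = rownames(v), shannon = shannon,
             richness = as.integer(richness), evenness = evenness,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aitchison distance matrix
#'
#' Euclidean distances between CLR-transformed samples; invariant to
#' per-sample scaling and feature order.
#'
#' @param x a \code{feature_table} (any non-negative unit).
#' @param pseudo pseudo-count on the table's native scale.
#' @return a \code{dist} object.
#' @export
aitchison <- function(x, pseudo) {
  if (nrow(x$values) < 2) stop("need at least 2 samples for distances")
  stats::dist(clr_transform(x, pseudo))
}

gower_center <- function(dm) {
  d <- as.matrix(dm)
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way location test on a distance matrix: pseudo-F from the
#' Gower-centred Gram matrix, with a permutation p-value using the add-one
#' convention. Permutations are free by default or restricted within
#' \code{strata} (e.g. within subject for time-point contrasts).
#'
#' @param dm a \code{dist} or symmetric matrix.
#' @param groups factor-like group labels, one per sample; every group must
#'   be non-empty with at least two groups.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param strata optional blocking factor restricting permutations.
#' @param exact enumerate all n! label permutations instead of sampling
#'   (small n only); p is then the exact permutation proportion.
#' @return list with \code{pseudo_F}, \code{R2}, \code{p}, \code{n_perm}.
#' @export
permanova <- function(dm, groups, n_perm = 9999, seed = 1, strata = NULL,
                      exact = FALSE) {
  d2 <- as.matrix(dm)^2
  groups <- as.factor(as.character(groups))
  n <- nrow(d2)
  if (length(groups) != n) stop("groups length must match distance matrix")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  g <- nlevels(groups)
  ss_total <- sum(d2) / (2 * n)
  stat <- function(idx) {
    gr <- groups[idx]
    ss_w <- 0
    for (lv in levels(gr)) {
      sel <- which(gr == lv)
      ss_w <- ss_w + sum(d2[sel, sel]) / (2 * length(sel))
    }
    ((ss_total - ss_w) / (g - 1)) / (ss_w / (n - g))
  }
  f_obs <- stat(seq_len(n))
  ss_within <- 0
  for (lv in levels(groups)) {
    sel <- which(groups == lv)
    ss_within <- ss_within + sum(d2[sel, sel]) / (2 * length(sel))
  }
  r2 <- (ss_total - ss_within) / ss_total
  if (exact) {
    if (!is.null(strata)) stop("exact enumeration does not support strata")
    perms <- all_perms(n)
    p <- mean(vapply(perms, function(idx) stat(idx) >= f_obs - 1e-12,
                     logical(1)))
    return(list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = length(perms)))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      idx <- permute_labels(n, strata)
      stat(idx) >= f_obs - 1e-12
    }, logical(1)))
  })
  list(pseudo_F = f_obs, R2 = r2, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm)
}

permute_labels <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lv in unique(strata)) {
    sel <- which(strata == lv)
    if (length(sel) > 1) idx[sel] <- sel[sample.int(length(sel))]
  }
  idx
}

permdisp_f <- function(dm, groups) {
  # distances to group centroids in principal-coordinate space (all axes,
  # negative eigenvalues truncated); ANOVA F on those distances
  d <- as.matrix(dm)
  n <- nrow(d)
  g_mat <- gower_center(d)
  e <- eigen(g_mat, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  pts <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                  sum(keep))
  zd <- numeric(n)
  for (lv in unique(groups)) {
    sel <- which(groups == lv)
    cen <- colMeans(pts[sel, , drop = FALSE])
    zd[sel] <- sqrt(rowSums((pts[sel, , drop = FALSE] -
                               matrix(cen, length(sel), ncol(pts),
                                      byrow = TRUE))^2))
  }
  gr <- as.factor(groups)
  k <- nlevels(gr)
  gm <- mean(zd)
  ss_b <- sum(tapply(zd, gr, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum((zd - stats::ave(zd, gr))^2)
  list(f = (ss_b / (k - 1)) / (ss_w / (n - k)), dist_to_centroid = zd)
}

#' Homogeneity of multivariate dispersions (permutation test)
#'
#' Distances to group centroids in principal-coordinate space, compared by
#' an F statistic under label permutation. PERMANOVA location results are
#' reported only when dispersions are homogeneous; the returned
#' \code{gate_pass} flag encodes that rule (\code{p >= alpha}).
#'
#' @inheritParams permanova
#' @param alpha significance level of the gate.
#' @param exact enumerate all n! label permutations (small n only).
#' @return list with \code{F}, \code{p}, \code{gate_pass},
#'   \code{dist_to_centroid}.
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1, alpha = 0.05,
                     exact = FALSE) {
  groups <- as.factor(as.character(groups))
  n <- nrow(as.matrix(dm))
  if (length(groups) != n) stop("groups length must match distance matrix")
  if (nlevels(groups) < 2 || any(table(groups) == 0))
    stop("need >= 2 non-empty groups")
  obs <- permdisp_f(dm, groups)
  if (exact) {
    p <- mean(vapply(all_perms(n), function(idx)
      permdisp_f(dm, groups[idx])$f >= obs$f - 1e-12, logical(1)))
    return(list(F = obs$f, p = p, gate_pass = p >= alpha,
                dist_to_centroid = obs$dist_to_centroid))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b)
      permdisp_f(dm, groups[sample.int(n)])$f >= obs$f - 1e-12, logical(1)))
  })
  p <- (1 + exceed) / (1 + n_perm)
  list(F = obs$f, p = p, gate_pass = p >= alpha,
       dist_to_centroid = obs$dist_to_centroid)
}

#' Matched vs unmatched cross-time-point distances
#'
#' Matched distances connect a subject's early and late samples; unmatched
#' distances connect early and late samples of different subjects. Greater
#' similarity (smaller distance) of matched pairs indicates within-subject
#' stability over time. Compared with a two-sided rank-sum test; if every
#' distance in both sets is identical the test is degenerate and p = 1.
#'
#' @param dm distance matrix over all samples.
#' @param meta validated metadata for those samples.
#' @return list with \code{matched}, \code{unmatched} (numeric vectors) and
#'   \code{p}.
#' @export
matched_unmatched <- function(dm, meta) {
  d <- as.matrix(dm)
  meta <- sample_metadata(meta)
  early <- meta[meta$timepoint == "early", ]
  late <- meta[meta$timepoint == "late", ]
  paired_subj <- intersect(early$subject_id, late$subject_id)
  if (length(paired_subj) == 0) stop("no subject has both time points")
  matched <- vapply(paired_subj, function(s)
    d[early$sample_id[early$subject_id == s],
      late$sample_id[late$subject_id == s]], numeric(1))
  unmatched <- as.vector(d[early$sample_id, late$sample_id, drop = FALSE])
  um_subj <- outer(early$subject_id, late$subject_id, "==")
  unmatched <- unmatched[!as.vector(um_subj)]
  if (length(unique(c(matched, unmatched))) <= 1) {
    p <- 1
  } else {
    p <- rank_sum_test(matched, unmatched,
                       exact_max = if (length(matched) + length(unmatched) <= 8) 8 else 0)$p
  }
  list(matched = unname(matched), unmatched = unmatched, p = p)
}

#' Compare within-subject stability between groups
#'
#' Matched early-late distances computed per group, then compared between
#' groups by an unpaired t-test when both groups pass a Shapiro normality
#' gate (alpha 0.05) or a rank-sum test otherwise; the auto-selected test
#' is reported.
#'
#' @inheritParams matched_unmatched
#' @return list with \code{control}, \code{case} (matched distances),
#'   \code{p}, \code{test}.
#' @export
matched_by_group <- function(dm, meta) {
  meta <- sample_metadata(meta)
  out <- list()
  for (g in c("control", "case")) {
    mg <- meta[meta$group == g, , drop = FALSE]
    sub <- matched_unmatched(ft_dist_subset(dm, mg$sample_id), mg)
    out[[g]] <- sub$matched
  }
  if (length(out$control) < 2 || length(out$case) < 2)
    stop("need at least 2 matched pairs per group to compare stability")
  normal <- tryCatch(
    stats::shapiro.test(out$control)$p.value >= 0.05 &&
      stats::shapiro.test(out$case)$p.value >= 0.05,
    error = function(e) FALSE)
  if (normal) {
    p <- stats::t.test(out$control, out$case)$p.value
    test <- "t"
  } else {
    p <- rank_sum_test(out$control, out$case,
                       exact_max = if (length(out$control) + length(out$case) <= 8) 8 else 0)$p
    test <- "rank_sum"
  }
  list(control = out$control, case = out$case, p = p, test = test)
}

ft_dist_subset <- function(dm, ids) {
  d <- as.matrix(dm)
  stats::as.dist(d[ids, ids, drop = FALSE])
}

#' Correlation between sequencing depth and richness
#'
#' Spearman correlation of per-sample library size with unrarefied observed
#' richness; a strong positive correlation signals that richness contrasts
#' must be made on rarefied data.
#'
#' @param meta validated metadata.
#' @param alpha data.frame with \code{sample_id} and \code{richness}
#'   computed before rarefaction.
#' @return list with \code{rho}, \code{p}, \code{defined} (FALSE when
#'   richness is constant).
#' @export
depth_richness_corr <- function(meta, alpha) {
  meta <- sample_metadata(meta)
  m <- merge(meta[, c("sample_id", "library_size")],
             alpha[, c("sample_id", "richness")], by = "sample_id")
  if (length(unique(m$richness)) < 2 || length(unique(m$library_size)) < 2)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(m$library_size, m$richness, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}
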