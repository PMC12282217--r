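test_that("alpha diversity matches hand computations and vegan", {
  tab <- make_table(rbind(c(50, 50, 0), c(100, 0, 0), c(10, 20, 70)))
  a <- alpha_diversity(tab)
  expect_equal(a$shannon[1], log(2))
  expect_equal(a$richness[1], 2L)
  expect_equal(a$evenness[1], 1)
  expect_equal(a$shannon[2], 0)   # single nonzero feature
  expect_equal(a$evenness[2], 0)
  expect_equal(a$shannon[3],
               -(0.1 * log(0.1) + 0.2 * log(0.2) + 0.7 * log(0.7)))
  expect_equal(a$shannon, unname(vegan::diversity(tab$values)))
  # evenness bounded, shannon <= ln(richness)
  expect_true(all(a$shannon <= log(pmax(a$richness, 2)) + 1e-12))
  uneq <- make_table(rbind(c(10, 0), c(20, 0)))
  expect_error(alpha_diversity(uneq), "rarefy")
})

test_that("Shannon is maximal at the uniform composition", {
  unif <- make_table(matrix(25, 1, 4))
  set.seed(5)
  for (i in 1:20) {
    x <- as.vector(rmultinom(1, 100, runif(4) + 0.05))
    if (any(x == 0)) next
    other <- make_table(matrix(x, 1, 4))
    skew <- alpha_diversity(other)$shannon
    expect_lte(skew, alpha_diversity(unif)$shannon + 1e-12)
  }
})

test_that("aitchison distance has CLR geometry", {
  m <- rbind(a = c(1, 2, 4), b = c(1, 1, 1), c = c(10, 20, 40))
  colnames(m) <- c("x", "y", "z")
  tab <- feature_table(m, "count", "genus", check_sums = FALSE)
  # pseudo tiny so the closed form applies
  d <- as.matrix(aitchison(tab, 1e-12))
  expect_equal(d["a", "b"], log(2) * sqrt(2), tolerance = 1e-6)
  # per-sample scaling collapses to zero distance
  expect_lt(d["a", "c"], 1e-6)
  # invariant to feature reordering
  tab2 <- ft_subset(tab, features = c("z", "x", "y"))
  expect_equal(as.matrix(aitchison(tab2, 1e-12))["a", "b"], d["a", "b"])
  one <- ft_subset(tab, samples = "a")
  expect_error(aitchison(one, 1e-6), "2 samples")
})

test_that("permanova matches adonis2 and exhaustive enumeration", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(9), 3, 3), matrix(rnorm(9, 2), 3, 3))
  rownames(pts) <- paste0("s", 1:6)
  dm <- dist(pts)
  grp <- rep(c("A", "B"), each = 3)
  mine <- permanova(dm, grp, n_perm = 499, seed = 2)
  ref <- vegan::adonis2(dm ~ g, data = data.frame(g = grp),
                        permutations = 499)
  expect_equal(mine$pseudo_F, ref$F[1])
  expect_equal(mine$R2, ref$R2[1])
  # exhaustive: compare against an independent enumeration over the 20
  # distinct balanced label assignments (F depends only on the partition)
  exact <- permanova(dm, grp, exact = TRUE)
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    vegan::adonis2(dm ~ g, data = data.frame(g = g), permutations = 2)$F[1]
  })
  p_enum <- mean(fs >= mine$pseudo_F - 1e-12)
  expect_equal(exact$p, p_enum)
  expect_error(permanova(dm, rep("A", 6)), "2 groups")
})

test_that("permanova p is calibrated under label exchange", {
  set.seed(3)
  ps <- vapply(1:40, function(s) {
    pts <- matrix(rnorm(8 * 4), 8, 4)
    rownames(pts) <- paste0("s", 1:8)
    permanova(dist(pts), rep(c("A", "B"), 4), n_perm = 199, seed = s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # strongly separated clouds: only relabelings reproducing the observed
  # partition can reach the observed F, so p is pinned near its floor
  far <- rbind(matrix(rnorm(12), 4, 3), matrix(rnorm(12, 50), 4, 3))
  rownames(far) <- paste0("s", 1:8)
  p_far <- permanova(dist(far), rep(c("A", "B"), each = 4),
                     n_perm = 199, seed = 1)$p
  expect_lte(p_far, 0.05)
  # exact enumeration gives the partition-recurrence probability 2/70
  expect_equal(permanova(dist(far), rep(c("A", "B"), each = 4),
                         exact = TRUE)$p, 2 / 70)
})

test_that("permanova restricted by strata only permutes within blocks", {
  set.seed(8)
  # block effect is huge; group is confounded with nothing within blocks
  blocks <- rep(1:4, each = 2)
  pts <- matrix(rnorm(8 * 3), 8, 3) + blocks * 10
  rownames(pts) <- paste0("s", 1:8)
  grp <- rep(c("A", "B"), 4)
  free <- permanova(dist(pts), grp, n_perm = 199, seed = 2)
  strat <- permanova(dist(pts), grp, n_perm = 199, seed = 2,
                     strata = blocks)
  # under free permutation the block noise drowns the test; both must be
  # valid p-values and the stratified one must be reproducible
  expect_true(strat$p >= 1 / 200 && strat$p <= 1)
  strat2 <- permanova(dist(pts), grp, n_perm = 199, seed = 2,
                      strata = blocks)
  expect_identical(strat$p, strat2$p)
})

test_that("permdisp matches betadisper's F and exhaustive enumeration", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(18, sd = 0.3), 6, 3),
               matrix(rnorm(18, sd = 3), 6, 3))
  rownames(pts) <- paste0("s", 1:12)
  dm <- dist(pts)
  grp <- rep(c("tight", "wide"), each = 6)
  mine <- permdisp(dm, grp, n_perm = 199, seed = 5)
  bd <- vegan::betadisper(dm, grp, type = "centroid")
  pt <- vegan::permutest(bd, permutations = 99)
  expect_equal(mine$F, unname(pt$statistic))
  expect_equal(unname(mine$dist_to_centroid),
               unname(bd$distances), tolerance = 1e-8)
  # inflated copy of a tight cluster: dispersion difference detected
  expect_lte(mine$p, 0.05)
  # exhaustive enumeration oracle via betadisper on relabelings
  dm6 <- dist(rbind(pts[1:3, ], pts[7:9, ]))
  g6 <- rep(c("a", "b"), each = 3)
  exact <- permdisp(dm6, g6, exact = TRUE)
  f_of <- function(g) {
    b <- vegan::betadisper(dm6, g, type = "centroid")
    anova(b)$`F value`[1]
  }
  fs <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"; f_of(g)
  })
  expect_equal(exact$p, mean(fs >= f_of(g6) - 1e-12))
})

test_that("mirror-image groups have homogeneous dispersions", {
  set.seed(2)
  a <- matrix(rnorm(15), 5, 3)
  pts <- rbind(a, -a)
  rownames(pts) <- paste0("s", 1:10)
  pd <- permdisp(dist(pts), rep(c("A", "B"), each = 5), n_perm = 199,
                 seed = 3)
  expect_gt(pd$p, 0.05)
  expect_true(pd$gate_pass)
})

test_that("matched/unmatched bookkeeping and degenerate ties", {
  # 2 paired subjects -> 2 matched, 2 unmatched cross-subject distances
  meta <- data.frame(sample_id = c("a_E", "a_L", "b_E", "b_L"),
                     subject_id = c("a", "a", "b", "b"),
                     group = "control",
                     timepoint = c("early", "late", "early", "late"),
                     library_size = 1000)
  pts <- matrix(rnorm(8), 4, 2,
                dimnames = list(meta$sample_id, NULL))
  mu <- matched_unmatched(dist(pts), meta)
  expect_length(mu$matched, 2)
  expect_length(mu$unmatched, 2)
  # identical samples: all distances zero, ties policy gives p = 1
  same <- matrix(1, 4, 2, dimnames = list(meta$sample_id, NULL))
  mu0 <- matched_unmatched(dist(same), meta)
  expect_equal(mu0$p, 1)
  solo <- meta[meta$timepoint == "early", ]
  expect_error(matched_unmatched(dist(pts[1:2, ]), solo), "both time points")
})

test_that("group stability comparison detects a noisier case group", {
  co <- simulate_cohort(sim_config(
    n_features = 100, n_paired_control = 12, n_early_only_control = 0,
    n_late_only_control = 0, n_paired_case = 12, n_early_only_case = 0,
    n_late_only_case = 0, subject_sd = 1, noise_sd = 0.3, seed = 31))
  # double the case group's within-subject noise by perturbing late samples
  v <- co$table$values
  late_case <- co$meta$sample_id[co$meta$group == "case" &
                                   co$meta$timepoint == "late"]
  set.seed(1)
  v[late_case, ] <- round(v[late_case, ] *
                            exp(matrix(rnorm(length(late_case) * ncol(v),
                                             0, 1.2),
                                       length(late_case))))
  tab <- feature_table(v, "count", "sgb", check_sums = FALSE)
  dm <- aitchison(to_proportions(tab), 1e-6)
  mb <- matched_by_group(dm, co$meta)
  expect_gt(median(mb$case), median(mb$control))
  expect_lt(mb$p, 0.05)
  expect_true(mb$test %in% c("t", "rank_sum"))
  # single pair per group is refused
  small <- simulate_cohort(sim_config(
    n_features = 30, n_paired_control = 1, n_early_only_control = 0,
    n_late_only_control = 0, n_paired_case = 1, n_early_only_case = 0,
    n_late_only_case = 0, seed = 2))
  dm_s <- aitchison(to_proportions(small$table), 1e-6)
  expect_error(matched_by_group(dm_s, small$meta), "2 matched pairs")
})

test_that("depth-richness correlation handles degenerate inputs", {
  meta <- data.frame(sample_id = paste0("s", 1:6), subject_id = paste0("u", 1:6),
                     group = "control", timepoint = "early",
                     library_size = c(10, 20, 30, 40, 50, 60) * 1000)
  const <- data.frame(sample_id = meta$sample_id, richness = 5L)
  expect_false(depth_richness_corr(meta, const)$defined)
  exact <- data.frame(sample_id = meta$sample_id,
                      richness = meta$library_size)
  dr <- depth_richness_corr(meta, exact)
  expect_equal(dr$rho, 1)
})
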