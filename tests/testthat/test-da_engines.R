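test_that("BH and Holm adjustments match their brute-force definitions", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(fdr_adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(fdr_adjust(0.03, "bh"), 0.03)
  expect_equal(fdr_adjust(0.03, "holm"), 0.03)
  expect_length(fdr_adjust(numeric(0), "bh"), 0)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(fdr_adjust(p, "bh"), brute_bh(p))
    expect_equal(fdr_adjust(p, "holm"), brute_holm(p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2), "bh"), "outside")
})

test_that("AST linear engine matches the closed-form two-sample t-test", {
  # proportions chosen so the AST-transformed values are exactly these
  target <- rbind(c(0.1), c(0.2), c(0.3), c(0.4), c(0.5), c(0.6))
  vals <- sin(target)^2
  tab <- make_table(cbind(vals, 0.5 - vals), unit = "proportion",
                    features = c("F1", "Fpad"))
  meta <- make_meta(tab, group = rep(c("control", "case"), each = 3))
  res <- engine_ast_lm(tab, meta)
  tt <- t.test(target[4:6], target[1:3], var.equal = TRUE)
  r1 <- res[res$feature_id == "F1", ]
  expect_equal(r1$effect, 0.3)
  expect_equal(r1$p, tt$p.value)
  expect_equal(r1$direction, 1L)
})

test_that("constant features get effect 0 and p 1", {
  tab <- make_table(cbind(rep(0.2, 6), runif(6, 0.1, 0.3)),
                    unit = "proportion")
  meta <- make_meta(tab, group = rep(c("control", "case"), 3))
  res <- engine_ast_lm(tab, meta)
  expect_equal(res$effect[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("engines reject rank-deficient designs naming the column", {
  tab <- make_table(matrix(runif(12, 0.1, 0.2), 6, 2), unit = "proportion")
  meta <- make_meta(tab, group = rep("control", 6))  # no case samples
  expect_error(engine_ast_lm(tab, meta), "group_case")
})

test_that("deterministic engines are equivariant to sample and feature order", {
  co <- null_cohort(17, n_per_group = 8, n_features = 40)
  filt <- prevalence_filter(co$table)
  perm_f <- sample(ft_features(filt))
  perm_s <- sample(ft_samples(filt))
  scrambled <- ft_subset(filt, samples = perm_s, features = perm_f)
  for (fn in list(engine_ast_lm, engine_clr_lm_bias, engine_loglinear_bias,
                  engine_negbin_wald)) {
    a <- fn(filt, co$meta)
    b <- fn(scrambled, co$meta)
    b <- b[match(a$feature_id, b$feature_id), ]
    expect_equal(a$effect, b$effect, tolerance = 1e-9)
    expect_equal(a$p, b$p, tolerance = 1e-9)
  }
})

test_that("bias-corrected CLR engine subtracts the median raw effect", {
  co <- null_cohort(23, n_per_group = 10, n_features = 30)
  filt <- prevalence_filter(co$table)
  prop <- ft_subset(to_proportions(co$table), features = ft_features(filt))
  res <- engine_clr_lm_bias(prop, co$meta)
  # independent raw effects: per-feature lm on CLR(prop + 1e-6)
  z <- clr_transform(prop$values, 1e-6)
  grp <- as.numeric(co$meta$group[match(ft_samples(prop),
                                        co$meta$sample_id)] == "case")
  raw <- vapply(seq_len(ncol(z)), function(j)
    unname(coef(lm(z[, j] ~ grp))[2]), numeric(1))
  expect_equal(res$effect, raw - median(raw), tolerance = 1e-8)
  # a single spiked feature barely moves the median: corrected ~ raw
  imp <- implant_signal(co$table, ft_features(filt)[5], 8, "case", co$meta)
  prop2 <- ft_subset(to_proportions(imp$table),
                     features = ft_features(filt))
  res2 <- engine_clr_lm_bias(prop2, imp$meta)
  z2 <- clr_transform(prop2$values, 1e-6)
  raw2 <- unname(coef(lm(z2[, 5] ~ grp))[2])
  expect_equal(res2$effect[5], raw2, tolerance = abs(raw2) * 0.2)
})

test_that("log-linear engine recovers implanted sample offsets", {
  set.seed(4)
  n <- 100; m <- 150
  lam <- rnorm(m, 3, 1.5)
  d_true <- rnorm(n, 0, 0.8)
  y <- outer(d_true, lam, "+") + matrix(rnorm(n * m, 0, 0.3), n, m)
  counts <- round(exp(y))
  tab <- make_table(counts, samples = sprintf("S%03d", 1:n),
                    features = sprintf("F%03d", 1:m))
  meta <- make_meta(tab, group = rep(c("control", "case"), length.out = n))
  res <- engine_loglinear_bias(tab, meta)
  d_hat <- attr(res, "offsets")
  expect_gt(cor(d_hat, d_true), 0.99)
  # zero implanted effects: no significant calls expected after Holm
  expect_lte(sum(res$significant), 1)
  one <- ft_subset(tab, features = 1)
  expect_error(engine_loglinear_bias(one, meta), "identifiable")
  prop <- make_table(matrix(0.5, 4, 2), unit = "proportion")
  expect_error(engine_loglinear_bias(prop, make_meta(prop)), "count input")
})

test_that("log-linear engine effects are invariant to a global scale shift", {
  co <- null_cohort(29, n_per_group = 10, n_features = 60)
  filt <- prevalence_filter(co$table)
  big <- ft_subset(filt, features = colSums(filt$values > 50) == nrow(filt$values))
  a <- engine_loglinear_bias(big, co$meta)
  shifted <- feature_table(big$values * 8, "count", big$level,
                           check_sums = FALSE)
  b <- engine_loglinear_bias(shifted, co$meta)
  # log(8c+1) ~ log(c+1) + log 8 at large counts: offsets absorb the shift
  expect_equal(a$effect, b$effect, tolerance = 0.02)
})

test_that("Dirichlet MC engine reproduces the exact Wilcoxon on separated data", {
  # one feature overwhelmingly abundant in cases; n = 4 vs 4 -> p = 2/70
  v <- cbind(c(rep(10, 4), rep(5000, 4)),
             c(rep(5000, 4), rep(10, 4)))
  tab <- make_table(v, features = c("low_then_high", "high_then_low"))
  meta <- make_meta(tab, group = rep(c("control", "case"), each = 4))
  cfg <- engine_config(mc_samples = 16, scale_noise_gamma = 0, seed = 5)
  res <- engine_dirichlet_mc(tab, meta, da_design(), cfg)
  expect_equal(res$p, rep(2 / 70, 2))
  expect_equal(res$direction, c(1L, -1L))
  expect_equal(attr(res, "test"), "wilcoxon")
  expect_error(engine_dirichlet_mc(tab, meta, da_design(),
                                   engine_config(mc_samples = 1)), ">= 2")
})

test_that("Dirichlet MC engine finds no signal between identical groups", {
  co <- null_cohort(37, n_per_group = 8, n_features = 40)
  filt <- prevalence_filter(co$table)
  # duplicate the control samples as a fake case group
  v <- filt$values[co$meta$group == "control", ]
  dup <- rbind(v, v)
  rownames(dup) <- c(paste0("c", seq_len(nrow(v))),
                     paste0("d", seq_len(nrow(v))))
  tab <- feature_table(dup, "count", "sgb", check_sums = FALSE)
  meta <- make_meta(tab, group = rep(c("control", "case"),
                                     each = nrow(v)))
  res <- engine_dirichlet_mc(tab, meta, da_design(),
                             engine_config(mc_samples = 32, seed = 2))
  expect_equal(sum(res$significant), 0)
  expect_gt(median(res$q), 0.5)
})

test_that("scale noise never increases Dirichlet MC call counts", {
  violations <- 0
  for (s in 1:20) {
    co <- null_cohort(100 + s, n_per_group = 10, n_features = 60,
                      n_diff = 3, log2_fold_changes = 3)
    filt <- prevalence_filter(co$table)
    meta <- co$meta
    n0 <- sum(engine_dirichlet_mc(
      filt, meta, da_design(),
      engine_config(mc_samples = 64, scale_noise_gamma = 0,
                    seed = s))$significant)
    n1 <- sum(engine_dirichlet_mc(
      filt, meta, da_design(),
      engine_config(mc_samples = 64, scale_noise_gamma = 0.5,
                    seed = s))$significant)
    if (n1 > n0) violations <- violations + 1
  }
  expect_lte(violations, 1)
})

test_that("negative-binomial engine size factors behave like median-of-ratios", {
  # identical samples: all size factors exactly 1
  v <- matrix(rep(c(100, 50, 10, 200), 5), 5, 4, byrow = TRUE)
  tab <- make_table(v)
  meta <- make_meta(tab, group = c("control", "control", "control",
                                   "case", "case"))
  res <- engine_negbin_wald(tab, meta)
  expect_equal(unname(attr(res, "size_factors")), rep(1, 5))
  # doubling one dense sample doubles its factor only, effects unchanged
  co <- null_cohort(41, n_per_group = 8, n_features = 30)
  dense <- ft_subset(co$table,
                     features = colSums(co$table$values > 0) ==
                       nrow(co$table$values))
  a <- engine_negbin_wald(dense, co$meta)
  v2 <- dense$values
  v2[3, ] <- v2[3, ] * 2
  b <- engine_negbin_wald(feature_table(v2, "count", "sgb",
                                        check_sums = FALSE), co$meta)
  sfa <- attr(a, "size_factors"); sfb <- attr(b, "size_factors")
  # relative to any other sample the doubled sample's factor is exactly x2
  # (the geometric-mean reference itself shifts by 2^(1/n), so the
  # absolute factor moves by 2^(1 - 1/n))
  expect_equal(unname(sfb[3] / sfb[1]), unname(2 * sfa[3] / sfa[1]),
               tolerance = 1e-9)
  expect_equal(unname(sfb[-3] / sfb[1]), unname(sfa[-3] / sfa[1]),
               tolerance = 1e-9)
  expect_equal(a$effect, b$effect, tolerance = 2e-2)
  zero <- make_table(rbind(c(0, 0), c(5, 5)))
  expect_error(engine_negbin_wald(zero, make_meta(zero)), "all-zero")
})

test_that("Poisson data drives estimated dispersions to the floor", {
  set.seed(6)
  mu <- runif(80, 60, 400)
  v <- t(replicate(30, rpois(80, mu)))
  tab <- make_table(v, samples = sprintf("S%02d", 1:30))
  meta <- make_meta(tab, group = rep(c("control", "case"), 15))
  res <- engine_negbin_wald(tab, meta)
  expect_lt(median(attr(res, "dispersion")), 0.05)
})

test_that("reference-ratio engine: null calibration, spike recovery, exact perms", {
  co <- null_cohort(53, n_per_group = 20, n_features = 80)
  filt <- prevalence_filter(co$table)
  cfg <- engine_config(n_perm = 199, seed = 11)
  res <- engine_reference_perm(filt, co$meta, da_design(), cfg)
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
  expect_true(all(res$q >= 0 & res$q <= 1))
  # monotone q in F: larger p never has smaller q among shared features
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))

  # implanted 8-fold feature attains the minimum q
  imp <- implant_signal(co$table, ft_features(filt)[10], 8, "case", co$meta)
  filt2 <- ft_subset(imp$table, features = ft_features(filt))
  res2 <- engine_reference_perm(filt2, imp$meta, da_design(), cfg)
  expect_equal(res2$feature_id[which.min(res2$q)], ft_features(filt)[10])

  # n = 6: engine switches to exhaustive enumeration; verify against an
  # independently coded Freedman-Lane enumeration on the ratio responses
  set.seed(3)
  v6 <- matrix(rpois(6 * 3, 400), 6, 3)
  tab6 <- make_table(v6)
  meta6 <- make_meta(tab6, group = rep(c("control", "case"), each = 3))
  cfg6 <- engine_config(n_perm = 720, seed = 1)
  res6 <- engine_reference_perm(tab6, meta6, da_design(), cfg6)
  pmat <- sweep(v6 + 0.5, 1, rowSums(v6 + 0.5), "/")
  refsum <- rowSums(pmat[, match(attr(res6, "reference_set"),
                                 ft_features(tab6)), drop = FALSE])
  ratio <- sqrt(sweep(pmat, 1, refsum, "/"))
  g <- rep(c(0, 1), each = 3)
  f_stat <- function(y, gg) {
    rss1 <- sum(resid(lm(y ~ gg))^2)
    rss0 <- sum(resid(lm(y ~ 1))^2)
    ((rss0 - rss1) / 1) / (rss1 / 4)
  }
  perms <- condaba:::all_perms(6)
  for (j in 1:3) {
    y <- ratio[, j]
    fobs <- f_stat(y, g)
    res_red <- resid(lm(y ~ 1)); fit_red <- fitted(lm(y ~ 1))
    fstar <- vapply(perms, function(ix)
      f_stat(fit_red + res_red[ix], g), numeric(1))
    expect_equal(res6$p[j], mean(fstar >= fobs - 1e-12))
  }
})

test_that("run_all_engines produces the full grid with a method audit", {
  co <- null_cohort(61, n_per_group = 6, n_features = 30)
  rel <- to_proportions(co$table)
  relpct <- feature_table(rel$values * 100, "relative_percent", "genus",
                          check_sums = FALSE)
  tables <- list(genus = relpct,
                 species = feature_table(rel$values * 100,
                                         "relative_percent", "species",
                                         check_sums = FALSE),
                 sgb = feature_table(rel$values * 100, "relative_percent",
                                     "sgb", check_sums = FALSE))
  cfg <- engine_config(mc_samples = 8, n_perm = 49, seed = 2)
  m1 <- run_all_engines(tables, co$meta, da_design(), "proportions", cfg)
  m2 <- run_all_engines(tables, co$meta, da_design(), "counts", cfg)
  expect_equal(sum(vapply(m1$results, length, integer(1))), 18L)
  expect_equal(nrow(m1$audit), 18L)
  # method 1: proportion-capable engines get proportions, others counts
  a1 <- m1$audit
  expect_true(all(a1$input_unit[a1$engine %in%
                                  c("lm_ast", "lm_clr_bias", "ref_perm")] ==
                    "proportion"))
  expect_true(all(a1$input_unit[a1$engine %in%
                                  c("loglin_bias", "dirichlet_mc",
                                    "negbin_wald")] == "count"))
  expect_true(all(m2$audit$input_unit == "count"))
  # engine outputs cover exactly the shared filtered feature set
  feats <- lapply(m1$results$genus, function(r) sort(r$feature_id))
  expect_true(all(vapply(feats, identical, logical(1), feats[[1]])))
})

test_that("one engine's failure is audited without aborting the run", {
  # a single-feature level makes the log-linear engine unidentifiable
  co <- null_cohort(67, n_per_group = 6, n_features = 25)
  rel <- to_proportions(co$table)
  one <- feature_table(rel$values[, 1, drop = FALSE] /
                         rowSums(rel$values[, 1, drop = FALSE]),
                       "proportion", "kingdom", check_sums = FALSE)
  cfg <- engine_config(mc_samples = 8, n_perm = 49, seed = 3)
  out <- run_all_engines(list(kingdom = one), co$meta, da_design(),
                         "counts", cfg,
                         params = transform_params(min_prevalence = 0.01))
  expect_true(any(grepl("error", out$audit$status)))
  expect_true(any(out$audit$status == "ok"))
  expect_false("loglin_bias" %in% names(out$results$kingdom))
})
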