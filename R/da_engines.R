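#' Multiple-testing adjustment used by the DA engines
#'
#' Benjamini-Hochberg step-up FDR or Holm-Bonferroni step-down FWER
#' adjustment (via \code{stats::p.adjust}). Empty input yields empty
#' output.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"bh"} or \code{"holm"}.
#' @return adjusted q-values, same length as \code{p}.
#' @export
fdr_adjust <- function(p, method = c("bh", "holm")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

#' Design for a differential-abundance contrast
#'
#' The response contrast is always case vs control. Covariates (e.g.
#' \code{"bmi"}) enter as fixed effects; \code{pairing = TRUE} adds subject
#' fixed effects, the uniform tractable stand-in for subject random
#' effects across all engine families.
#'
#' @param covariates character vector of metadata columns.
#' @param pairing include subject fixed effects.
#' @param alpha significance level for the \code{significant} flag.
#' @return a list of class \code{da_design}.
#' @export
da_design <- function(covariates = character(0), pairing = FALSE,
                      alpha = 0.05) {
  structure(list(covariates = covariates, pairing = pairing, alpha = alpha),
            class = "da_design")
}

#' Engine tuning parameters
#'
#' Defaults mirror standard practice for these engine families: 1000
#' Dirichlet Monte-Carlo instances with log-scale noise SD 0.25, and 999
#' permutations for the reference-ratio engine.
#'
#' @param mc_samples number of Dirichlet Monte-Carlo instances (>= 2).
#' @param scale_noise_gamma SD of per-sample log-scale noise added to each
#'   Monte-Carlo instance (>= 0).
#' @param n_perm permutations for the reference-ratio engine.
#' @param seed root seed; engines derive named substreams from it.
#' @return a list of class \code{engine_config}.
#' @export
engine_config <- function(mc_samples = 1000, scale_noise_gamma = 0.25,
                          n_perm = 999, seed = 1) {
  if (mc_samples < 2) stop("mc_samples must be >= 2")
  if (scale_noise_gamma < 0) stop("scale_noise_gamma must be >= 0")
  structure(list(mc_samples = mc_samples,
                 scale_noise_gamma = scale_noise_gamma,
                 n_perm = n_perm, seed = seed),
            class = "engine_config")
}

build_design_matrix <- function(meta, design, drop_group = FALSE) {
  n <- nrow(meta)
  x <- matrix(1, n, 1, dimnames = list(meta$sample_id, "intercept"))
  if (!drop_group)
    x <- cbind(x, group_case = as.numeric(meta$group == "case"))
  for (cv in design$covariates) {
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv)
    x <- cbind(x, stats::setNames(as.numeric(meta[[cv]]), NULL))
    colnames(x)[ncol(x)] <- cv
  }
  if (isTRUE(design$pairing)) {
    subj <- factor(meta$subject_id)
    tab <- table(meta$subject_id, meta$timepoint)
    if (any(tab > 1))
      stop("pairing requires at most one sample per subject and time point")
    if (nlevels(subj) > 1) {
      dm <- stats::model.matrix(~ subj)[, -1, drop = FALSE]
      colnames(dm) <- paste0("subject_", levels(subj)[-1])
      x <- cbind(x, dm)
    }
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  x
}

# OLS of every column of y on x; t-test on the named coefficient.
# Zero-variance features get effect 0, p 1 (flagged in the result).
ols_columns <- function(y, x, coef_name = "group_case") {
  qrx <- qr(x)
  cf <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  df <- nrow(x) - ncol(x)
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  gg <- solve(crossprod(x))[coef_name, coef_name]
  se <- sqrt(pmax(sigma2 * gg, 0))
  eff <- cf[coef_name, ]
  degenerate <- se < 1e-12
  tt <- ifelse(degenerate, 0, eff / ifelse(degenerate, 1, se))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tt), df))
  eff[degenerate & abs(eff) < 1e-12] <- 0
  list(effect = unname(eff), se = unname(se), t = unname(tt),
       p = unname(p), df = df, degenerate = unname(degenerate))
}

finish_da_result <- function(features, effect, p, engine, alpha,
                             fdr_method = "bh", q = NULL) {
  if (is.null(q)) q <- fdr_adjust(p, fdr_method)
  data.frame(feature_id = features,
             effect = effect,
             p = p, q = q,
             significant = q < alpha,
             direction = as.integer(sign(effect)),
             engine = engine,
             row.names = NULL, stringsAsFactors = FALSE)
}

engine_proportions <- function(x) {
  switch(x$unit,
         proportion = x$values,
         relative_percent = x$values / 100,
         stop("expected a proportion-scale table, got unit=", x$unit))
}

#' Linear-model engine on AST proportions or CLR counts
#'
#' The MaAsLin2-style family: ordinary least squares per feature on an
#' arcsine-square-root transform when the input is proportions, or on a
#' CLR transform (pseudo-count 0.5) when the input is counts; two-sided
#' t-test on the group coefficient; BH adjustment.
#'
#' @param x \code{feature_table} (proportion-scale or count).
#' @param meta validated metadata.
#' @param design a \code{\link{da_design}}.
#' @param cfg an \code{\link{engine_config}} (unused here; kept for the
#'   shared engine signature).
#' @return data.frame of per-feature results.
#' @export
engine_ast_lm <- function(x, meta, design = da_design(),
                          cfg = engine_config()) {
  meta <- meta_align(meta, x)
  y <- if (x$unit == "count") clr_transform(x$values, 0.5)
       else ast_transform(engine_proportions(x))
  xm <- build_design_matrix(meta, design)
  fit <- ols_columns(y, xm)
  finish_da_result(ft_features(x), fit$effect, fit$p, "lm_ast",
                   design$alpha, "bh")
}

#' Bias-corrected CLR linear-model engine
#'
#' The LinDA-style family: CLR transform (pseudo-count on the proportion
#' scale for proportion input; library-size-scaled half-minimum imputation
#' of zeros for count input), per-feature OLS, then subtraction of the
#' median of all raw group effects as the compositional-bias estimate. The
#' t-test uses the corrected effect with the unchanged standard error; BH.
#'
#' @inheritParams engine_ast_lm
#' @param pseudo proportion-scale pseudo-count for proportion input.
#' @return data.frame of per-feature results.
#' @export
engine_clr_lm_bias <- function(x, meta, design = da_design(),
                               cfg = engine_config(), pseudo = 1e-6) {
  meta <- meta_align(meta, x)
  if (x$unit == "count") {
    v <- x$values
    prop <- sweep(v, 1, pmax(rowSums(v), 1), "/")
    for (j in seq_len(ncol(prop))) {
      nz <- prop[, j] > 0
      if (!any(nz)) { prop[, j] <- pseudo; next }
      imput <- 0.5 * min(prop[nz, j])
      prop[!nz, j] <- imput
    }
    y <- log(prop) - rowMeans(log(prop))
  } else {
    y <- clr_transform(engine_proportions(x), pseudo)
  }
  xm <- build_design_matrix(meta, design)
  fit <- ols_columns(y, xm)
  bias <- stats::median(fit$effect)
  eff <- fit$effect - bias
  degen <- fit$se < 1e-12
  tt <- ifelse(degen, 0, eff / ifelse(degen, 1, fit$se))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(tt), fit$df))
  finish_da_result(ft_features(x), eff, p, "lm_clr_bias", design$alpha, "bh")
}

#' Iterative log-linear engine with sample-specific offsets
#'
#' The ANCOM-BC2-style family: models log(count + 1) with per-sample
#' sequencing-bias offsets estimated by alternating (a) per-feature
#' regression of the offset-corrected response on the design with (b)
#' offset = mean residual across features, until convergence (1e-8, max
#' 100 iterations; offsets centred each step to fix the gauge). Wald test
#' on the group coefficient; Holm-Bonferroni adjustment.
#'
#' @inheritParams engine_ast_lm
#' @return data.frame of per-feature results.
#' @export
engine_loglinear_bias <- function(x, meta, design = da_design(),
                                  cfg = engine_config()) {
  if (x$unit != "count") stop("log-linear engine requires count input")
  if (ncol(x$values) < 2)
    stop("offsets are not identifiable from a single feature")
  meta <- meta_align(meta, x)
  y <- log(x$values + 1)
  xm <- build_design_matrix(meta, design)
  qrx <- qr(xm)
  d <- numeric(nrow(y))
  for (it in seq_len(100)) {
    cf <- qr.coef(qrx, y - d)
    # gauge: offsets and coefficients are jointly identified only up to
    # X %*% gamma; pin the across-feature mean of every coefficient to 0
    # (the taxa-specific bias correction), letting offsets absorb the rest
    cf <- cf - rowMeans(cf)
    fitted <- xm %*% cf
    d_new <- rowMeans(y - fitted)
    if (max(abs(d_new - d)) < 1e-8) { d <- d_new; break }
    d <- d_new
  }
  fit <- ols_columns(y - d, xm)
  # Wald statistic against a t reference: the residual variance is
  # estimated with n - p df, and the normal reference is visibly
  # anti-conservative at cohort-scale n
  z <- ifelse(fit$degenerate, 0, fit$effect / ifelse(fit$degenerate, 1, fit$se))
  p <- ifelse(fit$degenerate, 1, 2 * stats::pt(-abs(z), fit$df))
  res <- finish_da_result(ft_features(x), fit$effect, p, "loglin_bias",
                          design$alpha, "holm")
  attr(res, "offsets") <- stats::setNames(d, ft_samples(x))
  res
}

#' Dirichlet Monte-Carlo instance engine
#'
#' The ALDEx2-style family: per instance, sample proportions from a
#' Dirichlet posterior (counts + 0.5 prior), CLR-transform, add per-sample
#' log-scale noise (SD \code{scale_noise_gamma}) to model scale
#' uncertainty, then a two-sided Wilcoxon rank-sum test per feature (exact
#' for total n <= 8, midrank normal approximation otherwise); BH within the
#' instance. Reported p and q are means over instances; the effect is the
#' median over instances of the between-group mean difference divided by
#' the larger within-group SD. Designs with covariates or pairing fall
#' back to per-instance OLS on the CLR values (noted in the result
#' attribute \code{test}).
#'
#' @inheritParams engine_ast_lm
#' @return data.frame of per-feature results.
#' @export
engine_dirichlet_mc <- function(x, meta, design = da_design(),
                                cfg = engine_config()) {
  if (x$unit != "count") stop("Dirichlet MC engine requires count input")
  if (cfg$mc_samples < 2) stop("mc_samples must be >= 2")
  meta <- meta_align(meta, x)
  shape <- x$values + 0.5
  n <- nrow(shape); m <- ncol(shape)
  use_lm <- length(design$covariates) > 0 || isTRUE(design$pairing)
  xm <- if (use_lm) build_design_matrix(meta, design) else NULL
  in_case <- meta$group == "case"
  if (!any(in_case) || all(in_case)) stop("both groups must be present")
  p_sum <- q_sum <- numeric(m)
  eff_mat <- matrix(NA_real_, cfg$mc_samples, m)
  with_seed(derive_seed(cfg$seed, "dirichlet_mc"), {
    for (b in seq_len(cfg$mc_samples)) {
      g <- matrix(stats::rgamma(n * m, shape = shape), n, m)
      z <- log(g)
      z <- z - rowMeans(z)
      if (cfg$scale_noise_gamma > 0)
        z <- z + stats::rnorm(n, 0, cfg$scale_noise_gamma)
      if (use_lm) {
        fit <- ols_columns(z, xm)
        p_b <- fit$p
        eff_mat[b, ] <- fit$effect
      } else {
        p_b <- rank_sum_columns(z, in_case)
        mu1 <- colMeans(z[in_case, , drop = FALSE])
        mu0 <- colMeans(z[!in_case, , drop = FALSE])
        s1 <- apply(z[in_case, , drop = FALSE], 2, stats::sd)
        s0 <- apply(z[!in_case, , drop = FALSE], 2, stats::sd)
        eff_mat[b, ] <- (mu1 - mu0) / pmax(s1, s0, 1e-12)
      }
      p_sum <- p_sum + p_b
      q_sum <- q_sum + fdr_adjust(p_b, "bh")
    }
  })
  p_bar <- p_sum / cfg$mc_samples
  q_bar <- q_sum / cfg$mc_samples
  eff <- apply(eff_mat, 2, stats::median)
  res <- finish_da_result(ft_features(x), eff, p_bar, "dirichlet_mc",
                          design$alpha, q = q_bar)
  attr(res, "test") <- if (use_lm) "ols_clr" else "wilcoxon"
  res
}

#' Negative-binomial Wald engine
#'
#' The DESeq2-style family: counts are modelled as negative binomial with a
#' log link. Size factors use the positive-counts variant of
#' median-of-ratios (geometric means over non-zero cells, sample factors
#' normalized to geometric mean one) and enter as offsets. Per-feature
#' dispersions come from method-of-moments (floored at 1e-8), shrunk
#' half-weight toward a log-mean trend; the group coefficient is tested by
#' a Wald z. BH adjustment.
#'
#' @inheritParams engine_ast_lm
#' @return data.frame of per-feature results, with the size factors in
#'   attribute \code{size_factors}.
#' @export
engine_negbin_wald <- function(x, meta, design = da_design(),
                               cfg = engine_config()) {
  if (x$unit != "count") stop("negative-binomial engine requires count input")
  v <- x$values
  if (any(rowSums(v) == 0)) stop("sample with all-zero counts")
  meta <- meta_align(meta, x)
  # poscounts size factors
  logv <- log(v)
  logv[!is.finite(logv)] <- NA
  loggeo <- colMeans(logv, na.rm = TRUE)
  sf <- apply(v, 1, function(row) {
    ok <- row > 0 & is.finite(loggeo)
    stats::median(row[ok] / exp(loggeo[ok]))
  })
  sf <- sf / exp(mean(log(sf)))
  k <- sweep(v, 1, sf, "/")
  base_mean <- colMeans(k)
  # method-of-moments dispersion, pooled within groups
  grp <- meta$group
  alpha_mom <- vapply(seq_len(ncol(k)), function(j) {
    num <- 0; den <- 0
    for (g in levels(grp)) {
      kg <- k[grp == g, j]
      if (length(kg) > 1) {
        num <- num + (length(kg) - 1) * (stats::var(kg) - mean(kg))
        den <- den + (length(kg) - 1) * mean(kg)^2
      }
    }
    if (den <= 0) return(1e-8)
    max(num / den, 1e-8)
  }, numeric(1))
  la <- log(alpha_mom)
  lb <- log(pmax(base_mean, 1e-8))
  disp <- alpha_mom
  if (length(unique(lb)) > 2 && stats::sd(la) > 0) {
    tr <- stats::lm(la ~ lb)
    disp <- exp(0.5 * la + 0.5 * unname(stats::predict(tr)))
  }
  disp <- pmax(disp, 1e-8)
  xm <- build_design_matrix(meta, design)
  off <- log(sf)
  gcol <- match("group_case", colnames(xm))
  eff <- p <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(xm, v[, j], offset = off,
                                      family = MASS::negative.binomial(1 / disp[j]))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        any(!is.finite(fit$coefficients))) {
      eff[j] <- 0; p[j] <- 1; next
    }
    w <- fit$weights
    xtwx <- crossprod(xm, xm * w)
    covb <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(covb)) { eff[j] <- 0; p[j] <- 1; next }
    se <- sqrt(pmax(covb[gcol, gcol], 0))
    eff[j] <- fit$coefficients[gcol]
    p[j] <- if (se < 1e-12) 1 else 2 * stats::pnorm(-abs(eff[j] / se))
  }
  res <- finish_da_result(ft_features(x), eff, p, "negbin_wald",
                          design$alpha, "bh")
  attr(res, "size_factors") <- stats::setNames(sf, ft_samples(x))
  attr(res, "dispersion") <- stats::setNames(disp, ft_features(x))
  res
}

rss_f_stats <- function(y, qr_full, qr_red, d1, d2) {
  rss_full <- colSums(qr.resid(qr_full, y)^2)
  rss_red <- colSums(qr.resid(qr_red, y)^2)
  ((rss_red - rss_full) / d1) / pmax(rss_full / d2, 1e-300)
}

#' Reference-ratio permutation engine
#'
#' The ZicoSeq-style family. Count input is converted to posterior-mean
#' proportions under a Dirichlet(+0.5) prior; proportions are square-root
#' transformed. Stage 1 ranks features by a residual-permutation F-test of
#' the group term and takes the lower half of evidence (largest p) as the
#' reference set. Stage 2 tests sqrt(feature proportion / reference-set
#' total) by the same F statistic under Freedman-Lane permutation of
#' reduced-model residuals, with a permutation-based FDR: for each
#' feature, the mean permuted exceedance count of its observed F divided by
#' the observed exceedance count, clipped to [0, 1] and monotonized in F.
#'
#' @inheritParams engine_ast_lm
#' @return data.frame of per-feature results, with the reference feature
#'   ids in attribute \code{reference_set}.
#' @export
engine_reference_perm <- function(x, meta, design = da_design(),
                                  cfg = engine_config()) {
  meta <- meta_align(meta, x)
  pmat <- if (x$unit == "count") {
    sweep(x$values + 0.5, 1, rowSums(x$values + 0.5), "/")
  } else engine_proportions(x)
  n <- nrow(pmat); m <- ncol(pmat)
  x_full <- build_design_matrix(meta, design)
  x_red <- build_design_matrix(meta, design, drop_group = TRUE)
  d1 <- ncol(x_full) - ncol(x_red)
  d2 <- n - ncol(x_full)
  if (d2 <= 0) stop("no residual degrees of freedom")
  qr_full <- qr(x_full); qr_red <- qr(x_red)

  run_stage <- function(y, perms) {
    f_obs <- rss_f_stats(y, qr_full, qr_red, d1, d2)
    fitted_red <- y - qr.resid(qr_red, y)
    res_red <- qr.resid(qr_red, y)
    f_perm <- matrix(NA_real_, length(perms), m)
    for (b in seq_along(perms)) {
      ystar <- fitted_red + res_red[perms[[b]], , drop = FALSE]
      f_perm[b, ] <- rss_f_stats(ystar, qr_full, qr_red, d1, d2)
    }
    list(f_obs = f_obs, f_perm = f_perm)
  }

  # with a tiny sample the full permutation group fits in the budget:
  # enumerate it and report exact permutation proportions (no add-one)
  exhaustive <- n <= 9 && factorial(n) <= cfg$n_perm + 1
  with_seed(derive_seed(cfg$seed, "ref_perm"), {
    perms <- if (exhaustive) all_perms(n)
             else lapply(seq_len(cfg$n_perm), function(b) sample.int(n))
    n_eff <- length(perms)
    # p is the unbiased permutation exceedance fraction (the exhaustive
    # enumeration contains the identity, so it is then strictly positive);
    # significance is governed by the permutation FDR q, not by p
    s1 <- run_stage(sqrt(pmat), perms)
    p1 <- colSums(s1$f_perm >= rep(s1$f_obs, each = nrow(s1$f_perm)) - 1e-12) /
      n_eff
    ref <- which(p1 >= stats::median(p1))
    if (length(ref) == 0) stop("empty reference set")
    refsum <- pmax(rowSums(pmat[, ref, drop = FALSE]), 1e-12)
    ratio <- sqrt(sweep(pmat, 1, refsum, "/"))
    s2 <- run_stage(ratio, perms)
    p2 <- colSums(s2$f_perm >= rep(s2$f_obs, each = nrow(s2$f_perm)) - 1e-12) /
      n_eff
    # permutation FDR
    q <- vapply(seq_len(m), function(i) {
      null_exceed <- mean(rowSums(s2$f_perm >= s2$f_obs[i] - 1e-12))
      obs_exceed <- sum(s2$f_obs >= s2$f_obs[i] - 1e-12)
      min(null_exceed / max(obs_exceed, 1), 1)
    }, numeric(1))
    ord <- order(s2$f_obs, decreasing = TRUE)
    q[ord] <- cummax(q[ord])
    eff <- ols_columns(ratio, x_full)$effect
    res <- finish_da_result(ft_features(x), eff, p2, "ref_perm",
                            design$alpha, q = q)
    attr(res, "reference_set") <- ft_features(x)[ref]
    attr(res, "stage1_p") <- p1
    res
  })
}

da_engine_registry <- function() {
  list(lm_ast = list(fn = engine_ast_lm, prop_capable = TRUE),
       lm_clr_bias = list(fn = engine_clr_lm_bias, prop_capable = TRUE),
       ref_perm = list(fn = engine_reference_perm, prop_capable = TRUE),
       loglin_bias = list(fn = engine_loglinear_bias, prop_capable = FALSE),
       dirichlet_mc = list(fn = engine_dirichlet_mc, prop_capable = FALSE),
       negbin_wald = list(fn = engine_negbin_wald, prop_capable = FALSE))
}

#' Run all six engines on every feature level
#'
#' One shared prevalence filter is applied per level; proportions and
#' approximate counts are then derived from the unfiltered table and
#' subset to the retained features (no renormalization). Under
#' \code{input_mode = "proportions"} (method 1) the three
#' proportion-capable engines receive proportions and the rest approximate
#' counts; under \code{"counts"} (method 2) all six receive approximate
#' counts. An engine failure is recorded in the audit and does not abort
#' the run.
#'
#' @param tables named list, level -> relative-abundance
#'   \code{feature_table} (percent, proportion or RPK); count tables are
#'   used as-is.
#' @param meta validated metadata (with library sizes).
#' @param design a \code{\link{da_design}}.
#' @param input_mode \code{"proportions"} (method 1) or \code{"counts"}
#'   (method 2).
#' @param cfg an \code{\link{engine_config}}.
#' @param params a \code{\link{transform_params}}.
#' @return list with \code{results} (nested level -> engine -> data.frame)
#'   and \code{audit} (data.frame of level, engine, input unit, status).
#' @export
run_all_engines <- function(tables, meta, design = da_design(),
                            input_mode = c("proportions", "counts"),
                            cfg = engine_config(),
                            params = transform_params()) {
  input_mode <- match.arg(input_mode)
  registry <- da_engine_registry()
  results <- list(); audit <- list()
  for (lv in names(tables)) {
    tab <- tables[[lv]]
    filt <- prevalence_filter(tab, params)
    kept <- ft_features(filt)
    if (tab$unit == "count") {
      counts <- ft_subset(tab, features = kept)
      prop <- ft_subset(to_proportions(tab), features = kept)
    } else {
      prop <- ft_subset(to_proportions(tab), features = kept)
      counts <- ft_subset(to_approximate_counts(to_proportions(tab), meta),
                          features = kept)
    }
    lv_res <- list()
    for (eng in names(registry)) {
      use_prop <- input_mode == "proportions" && registry[[eng]]$prop_capable
      input <- if (use_prop) prop else counts
      cfg_e <- cfg
      cfg_e$seed <- derive_seed(cfg$seed, paste0(eng, ":", lv))
      out <- tryCatch(registry[[eng]]$fn(input, meta, design, cfg_e),
                      error = function(e) e)
      status <- if (inherits(out, "error")) paste0("error: ",
                                                   conditionMessage(out))
                else "ok"
      if (!inherits(out, "error")) lv_res[[eng]] <- out
      audit[[length(audit) + 1L]] <- data.frame(
        level = lv, engine = eng, input_unit = input$unit,
        status = status, stringsAsFactors = FALSE)
    }
    results[[lv]] <- lv_res
  }
  list(results = results, audit = do.call(rbind, audit))
}
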