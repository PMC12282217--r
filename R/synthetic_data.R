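#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a two-group (control/case), two-time-point
#' (early/late) paired shotgun-metagenomics cohort: a long-tailed baseline
#' composition shared by everyone, subject-level random intercepts per
#' feature (so a subject's two samples resemble each other), residual
#' log-scale noise, log-normal library sizes with an optional multiplicative
#' depth confound for the case group, and group effects implanted on the
#' log scale before compositional closure (so spillover onto other features
#' is real, as in relative-abundance data).
#'
#' Subject structure defaults to the emulated study design: 24 paired + 3
#' early-only + 1 late-only controls and 9 paired + 2 early-only cases.
#' Depth defaults reproduce post-QC buccal-swab depths (mean 375,199 paired
#' reads; log-sd matched to the reported IQR).
#'
#' @param n_features number of features (SGB-like units).
#' @param n_paired_control,n_early_only_control,n_late_only_control control
#'   subjects with both time points, early only, late only.
#' @param n_paired_case,n_early_only_case,n_late_only_case case subjects.
#' @param baseline_sd log-scale SD of the baseline composition; larger
#'   values give a more uneven, sparser community.
#' @param depth_logmean,depth_logsd log-normal library-size parameters.
#' @param depth_group_shift multiplicative depth factor for case samples
#'   (1 = no depth confound).
#' @param n_diff number of differential features to implant.
#' @param log2_fold_changes signed log2 fold changes, recycled to
#'   \code{n_diff}.
#' @param subject_sd SD of the per-subject, per-feature random intercept
#'   (log scale).
#' @param noise_sd residual per-sample log-scale SD.
#' @param bmi_effect per-unit-BMI log-scale slope applied to
#'   \code{n_bmi_features} designated features.
#' @param n_bmi_features number of BMI-covariate features.
#' @param seed integer seed.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_features = 300,
                       n_paired_control = 24, n_early_only_control = 3,
                       n_late_only_control = 1,
                       n_paired_case = 9, n_early_only_case = 2,
                       n_late_only_case = 0,
                       baseline_sd = 3,
                       depth_logmean = log(375199), depth_logsd = 0.63,
                       depth_group_shift = 1,
                       n_diff = 0, log2_fold_changes = 3,
                       subject_sd = 1, noise_sd = 0.6,
                       bmi_effect = 0, n_bmi_features = 0,
                       seed = 1) {
  cfg <- list(n_features = n_features,
              n_paired_control = n_paired_control,
              n_early_only_control = n_early_only_control,
              n_late_only_control = n_late_only_control,
              n_paired_case = n_paired_case,
              n_early_only_case = n_early_only_case,
              n_late_only_case = n_late_only_case,
              baseline_sd = baseline_sd,
              depth_logmean = depth_logmean, depth_logsd = depth_logsd,
              depth_group_shift = depth_group_shift,
              n_diff = n_diff, log2_fold_changes = log2_fold_changes,
              subject_sd = subject_sd, noise_sd = noise_sd,
              bmi_effect = bmi_effect, n_bmi_features = n_bmi_features,
              seed = seed)
  if (cfg$n_features < 2) stop("n_features must be >= 2")
  if (cfg$n_diff > cfg$n_features) stop("n_diff exceeds n_features")
  if (cfg$subject_sd < 0 || cfg$noise_sd < 0 || cfg$depth_logsd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$depth_group_shift <= 0) stop("depth_group_shift must be > 0")
  if (cfg$n_diff > 0 && any(cfg$log2_fold_changes == 0))
    stop("implanted log2 fold changes must be non-zero")
  structure(cfg, class = "sim_config")
}

#' Baseline community composition
#'
#' Log-abundances are drawn i.i.d. normal with SD \code{baseline_sd} and
#' closed to sum one, giving a heavy-tailed (log-normal) rank-abundance
#' profile: a few dominant features and a long tail of rare ones, as in
#' oral shotgun profiles.
#'
#' @param n_features number of features (>= 2).
#' @param seed integer seed.
#' @param baseline_sd log-scale SD.
#' @return named numeric vector of proportions summing to one.
#' @export
simulate_baseline <- function(n_features, seed, baseline_sd = 3) {
  if (n_features < 2) stop("n_features must be >= 2")
  lam <- with_seed(seed, stats::rnorm(n_features, 0, baseline_sd))
  p <- exp(lam - max(lam))
  p <- p / sum(p)
  names(p) <- sprintf("SGB%04d", seq_len(n_features))
  p
}

#' Ground truth of a simulated cohort
#' @param feature_ids differential feature ids.
#' @param log2fc signed log2 fold changes (case vs control), one per id,
#'   all non-zero.
#' @param bmi_features ids of features carrying the BMI covariate effect.
#' @return a list of class \code{sim_truth}.
#' @export
sim_truth <- function(feature_ids = character(0), log2fc = numeric(0),
                      bmi_features = character(0)) {
  stopifnot(length(feature_ids) == length(log2fc))
  if (length(log2fc) && any(log2fc == 0)) stop("true fold changes must be non-zero")
  structure(list(feature_ids = as.character(feature_ids),
                 log2fc = as.numeric(log2fc),
                 bmi_features = as.character(bmi_features)),
            class = "sim_truth")
}

subject_plan <- function(cfg) {
  mk <- function(group, kind, n, from) {
    if (n == 0) return(NULL)
    prefix <- if (group == "control") "CTL" else "CAS"
    data.frame(subject_id = sprintf("%s%02d", prefix, from + seq_len(n) - 1),
               group = group, kind = kind, stringsAsFactors = FALSE)
  }
  rbind(
    mk("control", "paired", cfg$n_paired_control, 1),
    mk("control", "early_only", cfg$n_early_only_control,
       cfg$n_paired_control + 1),
    mk("control", "late_only", cfg$n_late_only_control,
       cfg$n_paired_control + cfg$n_early_only_control + 1),
    mk("case", "paired", cfg$n_paired_case, 1),
    mk("case", "early_only", cfg$n_early_only_case, cfg$n_paired_case + 1),
    mk("case", "late_only", cfg$n_late_only_case,
       cfg$n_paired_case + cfg$n_early_only_case + 1))
}

#' Simulate a full cohort with ground truth
#'
#' Per subject i in group g at time t, feature f:
#' \deqn{\log a = \lambda_f + 1[g=case]\,\Delta_f \log 2 +
#'       \beta_{bmi}(BMI_i - 30)\,1[f \in B] + u_{if} + \epsilon}
#' closed by softmax to proportions, then counts drawn multinomially at the
#' sample's library size. Paired subjects share \eqn{u_{if}} across their
#' two time points. Library sizes are log-normal, multiplied by
#' \code{depth_group_shift} for case samples. Differential features are
#' drawn from the mid-to-low abundance band (50th-85th percentile of
#' baseline share), mirroring the observation that group differences sit in
#' low-abundance taxa.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{table} (count \code{feature_table}, level sgb),
#'   \code{meta} (validated metadata with \code{bmi}) and \code{truth}
#'   (\code{\link{sim_truth}}).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    base <- stats::rnorm(cfg$n_features, 0, cfg$baseline_sd)
    feat_ids <- sprintf("SGB%04d", seq_len(cfg$n_features))
    names(base) <- feat_ids
    share <- exp(base - max(base)); share <- share / sum(share)

    delta <- stats::setNames(numeric(cfg$n_features), feat_ids)
    diff_ids <- character(0); lfc <- numeric(0)
    if (cfg$n_diff > 0) {
      band <- feat_ids[share > stats::quantile(share, 0.5) &
                         share <= stats::quantile(share, 0.85)]
      if (length(band) < cfg$n_diff) band <- feat_ids
      diff_ids <- sample(band, cfg$n_diff)
      lfc <- rep_len(cfg$log2_fold_changes, cfg$n_diff)
      delta[diff_ids] <- lfc
    }
    bmi_ids <- character(0)
    if (cfg$n_bmi_features > 0)
      bmi_ids <- sample(setdiff(feat_ids, diff_ids),
                        min(cfg$n_bmi_features, cfg$n_features - cfg$n_diff))
    beta_bmi <- stats::setNames(numeric(cfg$n_features), feat_ids)
    beta_bmi[bmi_ids] <- cfg$bmi_effect

    subj <- subject_plan(cfg)
    if (is.null(subj) || nrow(subj) == 0) stop("cohort has no subjects")
    subj$bmi <- ifelse(subj$group == "case",
                       pmax(17, stats::rnorm(nrow(subj), 34.5, 6)),
                       pmax(17, stats::rnorm(nrow(subj), 25.8, 4.5)))
    u <- matrix(stats::rnorm(nrow(subj) * cfg$n_features, 0, cfg$subject_sd),
                nrow(subj), cfg$n_features)

    rows <- list(); meta_rows <- list()
    for (i in seq_len(nrow(subj))) {
      tps <- switch(subj$kind[i], paired = c("early", "late"),
                    early_only = "early", late_only = "late")
      for (tp in tps) {
        la <- base + log(2) * delta * (subj$group[i] == "case") +
          beta_bmi * (subj$bmi[i] - 30) + u[i, ] +
          stats::rnorm(cfg$n_features, 0, cfg$noise_sd)
        pr <- exp(la - max(la)); pr <- pr / sum(pr)
        depth <- stats::rlnorm(1, cfg$depth_logmean, cfg$depth_logsd)
        if (subj$group[i] == "case") depth <- depth * cfg$depth_group_shift
        depth <- max(1L, as.integer(round(depth)))
        cnt <- as.integer(stats::rmultinom(1, depth, pr))
        sid <- paste0(subj$subject_id[i], "_", toupper(substr(tp, 1, 1)))
        rows[[sid]] <- cnt
        meta_rows[[sid]] <- data.frame(
          sample_id = sid, subject_id = subj$subject_id[i],
          group = subj$group[i], timepoint = tp, bmi = subj$bmi[i],
          library_size = depth, stringsAsFactors = FALSE)
      }
    }
    values <- do.call(rbind, rows)
    rownames(values) <- names(rows); colnames(values) <- feat_ids
    meta <- sample_metadata(do.call(rbind, meta_rows))
    rownames(meta) <- NULL
    list(table = feature_table(values, "count", "sgb", check_sums = FALSE),
         meta = meta,
         truth = sim_truth(diff_ids, lfc, bmi_ids))
  })
}

#' Implant a known signal into an existing null count table
#'
#' Multiplies the counts of chosen features in target-group samples by the
#' given fold changes (re-rounded half-to-even); all other cells are
#' untouched, and metadata library sizes are updated to the new row totals.
#'
#' @param x count \code{feature_table}.
#' @param feature_ids features to spike (must exist in \code{x}).
#' @param fold_changes positive multiplicative fold changes, recycled.
#' @param target_group \code{"case"} or \code{"control"}.
#' @param meta validated metadata.
#' @return list with \code{table}, \code{meta} (library sizes updated) and
#'   \code{truth}.
#' @export
implant_signal <- function(x, feature_ids, fold_changes, target_group, meta) {
  unknown <- setdiff(feature_ids, ft_features(x))
  if (length(unknown)) stop("unknown feature id: ", paste(unknown, collapse = ", "))
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  fc <- rep_len(fold_changes, length(feature_ids))
  meta <- meta_align(meta, x)
  v <- x$values
  tgt <- meta$group == target_group
  for (k in seq_along(feature_ids))
    v[tgt, feature_ids[k]] <- round_half_even(v[tgt, feature_ids[k]] * fc[k])
  meta$library_size <- rowSums(v)
  sgn <- if (target_group == "case") 1 else -1
  keep <- fc != 1
  list(table = feature_table(v, "count", x$level, check_sums = FALSE),
       meta = sample_metadata(meta),
       truth = sim_truth(feature_ids[keep], sgn * log2(fc[keep])))
}

#' Write a simulated cohort to disk
#'
#' Emits the same TSV dialects the readers consume, the ground truth as
#' JSON, the configuration as YAML, and a manifest with md5 checksums.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created; must be empty unless
#'   \code{force}).
#' @param cfg the \code{\link{sim_config}} used (echoed to YAML).
#' @param force overwrite a non-empty directory.
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, cfg = NULL, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output dir not empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_feature_table(cohort$table, files["counts"])
  utils::write.table(cohort$meta, files["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$truth), files["truth"],
                       auto_unbox = FALSE, digits = NA)
  if (!is.null(cfg)) yaml::write_yaml(unclass(cfg), files["config"])
  manifest <- data.frame(file = basename(files[file.exists(files)]),
                         md5 = unname(tools::md5sum(files[file.exists(files)])),
                         stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}
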