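#' Per-engine concordance metrics against the consensus set
#'
#' For one dataset (one level/comparison): the percentage of an engine's
#' calls that are consensus features, the percentage of all consensus
#' features the engine found, and the engine's call count min-max
#' normalized within the dataset (max-calling engine = 1, min = 0).
#' Engines with zero calls have an undefined calls-consensus percentage
#' (NA, encoded explicitly). Datasets without consensus features are
#' flagged so aggregation can exclude them.
#'
#' @param results named list of per-engine result data.frames.
#' @param cons consensus table computed from those same results.
#' @param dataset_id label for the dataset.
#' @return data.frame, one row per engine.
#' @export
tool_metrics <- function(results, cons, dataset_id = "dataset") {
  cset <- cons$feature_id[cons$consensus]
  calls <- lapply(results, function(r) r$feature_id[r$significant])
  n_calls <- vapply(calls, length, integer(1))
  rng <- range(n_calls)
  norm <- if (rng[2] > rng[1]) (n_calls - rng[1]) / (rng[2] - rng[1])
          else rep(0, length(n_calls))
  data.frame(
    engine = names(results), dataset_id = dataset_id,
    n_calls = n_calls,
    pct_calls_consensus = ifelse(
      n_calls == 0, NA_real_,
      100 * vapply(calls, function(cl) length(intersect(cl, cset)),
                   integer(1)) / pmax(n_calls, 1)),
    pct_consensus_found = if (length(cset) == 0) NA_real_ else
      100 * vapply(calls, function(cl) length(intersect(cl, cset)),
                   integer(1)) / length(cset),
    n_calls_normalized = unname(norm),
    has_consensus = length(cset) > 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate concordance metrics across datasets
#'
#' Per-engine median and IQR (linear-interpolation quartiles) of each
#' metric over the datasets that had consensus features.
#'
#' @param records row-bound \code{\link{tool_metrics}} outputs.
#' @return data.frame, one row per engine and metric.
#' @export
aggregate_metrics <- function(records) {
  records <- records[records$has_consensus, , drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(engine = character(0), metric = character(0),
                      median = numeric(0), q1 = numeric(0), q3 = numeric(0)))
  metrics <- c("pct_calls_consensus", "pct_consensus_found",
               "n_calls_normalized")
  out <- list()
  for (eng in unique(records$engine)) {
    sub <- records[records$engine == eng, , drop = FALSE]
    for (mt in metrics) {
      v <- sub[[mt]][!is.na(sub[[mt]])]
      if (length(v) == 0) next
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        engine = eng, metric = mt, median = qs[2], q1 = qs[1], q3 = qs[3],
        n_datasets = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Benchmark calls against simulated ground truth
#'
#' @param called feature ids called significant (engine or consensus).
#' @param truth a \code{\link{sim_truth}}.
#' @param directions optional named vector of call directions (by feature
#'   id) for sign accuracy.
#' @return list with \code{sensitivity} (TP / truth size),
#'   \code{observed_fdr} (FP / max(1, calls)) and \code{sign_accuracy}
#'   (fraction of true positives with the implanted sign; NA with no true
#'   positives or no directions).
#' @export
benchmark_vs_truth <- function(called, truth, directions = NULL) {
  tp_ids <- intersect(called, truth$feature_ids)
  fp <- length(setdiff(called, truth$feature_ids))
  sens <- if (length(truth$feature_ids) == 0) NA_real_
          else length(tp_ids) / length(truth$feature_ids)
  fdr <- fp / max(1, length(called))
  sign_acc <- NA_real_
  if (!is.null(directions) && length(tp_ids) > 0) {
    truth_sign <- sign(truth$log2fc[match(tp_ids, truth$feature_ids)])
    sign_acc <- mean(sign(directions[tp_ids]) == truth_sign)
  }
  list(sensitivity = sens, observed_fdr = fdr, sign_accuracy = sign_acc)
}

#' Test for a sequencing-depth difference between groups
#'
#' Two-sided rank-sum test of library size by group; a depth-group
#' confound means low-abundance detection differences can masquerade as
#' biology.
#'
#' @param meta validated metadata.
#' @return list with \code{p} and per-group median depths.
#' @export
depth_group_test <- function(meta) {
  meta <- sample_metadata(meta)
  x <- meta$library_size[meta$group == "control"]
  y <- meta$library_size[meta$group == "case"]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 samples per group for a depth test")
  list(p = rank_sum_test(x, y, exact_max = if (length(x) + length(y) <= 8) 8 else 0)$p,
       median_control = stats::median(x), median_case = stats::median(y))
}

#' Depth-matched sample subsets
#'
#' \code{min_threshold}: keep all case samples plus controls at least as
#' deep as the shallowest case. \code{top_k}: keep the k deepest samples
#' per group. Ties break deterministically by sample id.
#'
#' @param meta validated metadata.
#' @param mode \code{"min_threshold"} or \code{"top_k"}.
#' @param k samples per group for \code{top_k}.
#' @return character vector of retained sample ids.
#' @export
depth_matched_subset <- function(meta, mode = c("min_threshold", "top_k"),
                                 k = NULL) {
  mode <- match.arg(mode)
  meta <- sample_metadata(meta)
  ctl <- meta[meta$group == "control", ]
  cas <- meta[meta$group == "case", ]
  if (nrow(ctl) == 0 || nrow(cas) == 0) stop("both groups must be non-empty")
  if (mode == "min_threshold") {
    keep <- c(cas$sample_id,
              ctl$sample_id[ctl$library_size >= min(cas$library_size)])
  } else {
    if (is.null(k)) stop("top_k mode needs k")
    if (k > nrow(ctl) || k > nrow(cas))
      stop("k exceeds a group's size")
    top <- function(d) d$sample_id[order(-d$library_size, d$sample_id)][seq_len(k)]
    keep <- c(top(ctl), top(cas))
  }
  sort(keep)
}

#' Format a percentage the way clinical tables print them
#'
#' One decimal, rounded half away from zero, with a trailing ".0"
#' dropped (so 14/28 prints as "50", 10/28 as "35.7").
#'
#' @param num,den numerator and denominator.
#' @return character scalar (no percent sign).
#' @export
format_percent <- function(num, den) {
  p <- 100 * num / den
  r <- sign(p) * floor(abs(p) * 10 + 0.5) / 10
  s <- formatC(r, format = "f", digits = 1)
  sub("\\.0$", "", s)
}

#' Cohort characteristics summary table
#'
#' Continuous variables pass a normality gate in both groups
#' (Shapiro-Wilk at alpha 0.05 by default; strict mode additionally
#' requires Lilliefors, Anderson-Darling and Pearson chi-square, all
#' passing): normal variables are shown mean +/- sd with an unpaired
#' t-test, otherwise median (IQR, linear-interpolation quartiles) with a
#' rank-sum test. Categorical 2x2 variables use the exact hypergeometric
#' (Fisher) test with an odds ratio; larger tables use chi-square.
#' Constant or all-missing variables fall back to median (IQR) or are
#' skipped.
#'
#' @param data data.frame of per-subject variables including a group
#'   column.
#' @param types named character vector, variable -> \code{"continuous"} or
#'   \code{"categorical"}.
#' @param group_col name of the group column (two levels).
#' @param strict require all four normality tests to pass.
#' @return data.frame: variable, per-group summary strings, p, test used.
#' @export
cohort_summary <- function(data, types, group_col = "group",
                           strict = FALSE) {
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop("group column must have exactly 2 levels")
  lv <- levels(g)
  rows <- list()
  for (v in names(types)) {
    x <- data[[v]]
    if (all(is.na(x))) {
      message("skipping all-missing variable: ", v)
      next
    }
    if (types[[v]] == "continuous") {
      x1 <- x[g == lv[1] & !is.na(x)]; x2 <- x[g == lv[2] & !is.na(x)]
      normal <- is_normal_gate(x1, strict) && is_normal_gate(x2, strict)
      if (normal) {
        s1 <- sprintf("%.1f±%.1f", mean(x1), stats::sd(x1))
        s2 <- sprintf("%.1f±%.1f", mean(x2), stats::sd(x2))
        p <- stats::t.test(x1, x2)$p.value
        test <- "t"
      } else {
        qf <- function(z) sprintf("%.1f (%.1f–%.1f)",
                                  stats::median(z),
                                  stats::quantile(z, 0.25, type = 7),
                                  stats::quantile(z, 0.75, type = 7))
        s1 <- qf(x1); s2 <- qf(x2)
        p <- suppressWarnings(stats::wilcox.test(x1, x2,
                                                 exact = FALSE)$p.value)
        test <- "rank_sum"
      }
    } else {
      tab <- table(factor(x), g)
      if (nrow(tab) < 2) { s1 <- s2 <- "constant"; p <- NA; test <- "none" }
      else if (nrow(tab) == 2) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher_exact"
        s1 <- sprintf("%d (%s%%)", tab[2, 1],
                      format_percent(tab[2, 1], sum(tab[, 1])))
        s2 <- sprintf("%d (%s%%)", tab[2, 2],
                      format_percent(tab[2, 2], sum(tab[, 2])))
      } else {
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
        test <- "chi_square"
        s1 <- paste(tab[, 1], collapse = "/")
        s2 <- paste(tab[, 2], collapse = "/")
      }
    }
    rows[[v]] <- data.frame(variable = v, group1 = s1, group2 = s2,
                            p = p, test = test, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv
  rownames(out) <- NULL
  out
}

is_normal_gate <- function(x, strict = FALSE) {
  if (length(unique(x)) < 3 || length(x) < 3) return(FALSE)
  ok <- tryCatch(stats::shapiro.test(x)$p.value >= 0.05,
                 error = function(e) FALSE)
  if (!strict || !ok) return(ok)
  tests <- list(function(z) nortest::lillie.test(z)$p.value,
                function(z) nortest::ad.test(z)$p.value,
                function(z) nortest::pearson.test(z)$p.value)
  for (f in tests) {
    pv <- tryCatch(f(x), error = function(e) 0)
    if (pv < 0.05) return(FALSE)
  }
  TRUE
}
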