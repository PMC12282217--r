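#' Minimum votes for a consensus call
#'
#' The smallest number of engines k with k / n_engines >= threshold, i.e.
#' ceiling(threshold * n_engines). With six engines and the default 50%
#' threshold this is 3 — a simple majority.
#'
#' @param n_engines number of engines that ran (>= 1).
#' @param threshold vote fraction in (0, 1].
#' @return integer vote quota.
#' @export
min_votes <- function(n_engines, threshold = 0.5) {
  stopifnot(n_engines >= 1, threshold > 0, threshold <= 1)
  as.integer(ceiling(threshold * n_engines - 1e-12))
}

#' Majority vote across engine results for one level
#'
#' Counts, per feature, the engines calling it significant (q < alpha).
#' A feature is consensus when the count reaches the
#' \code{\link{min_votes}} quota. The majority direction is the sign of
#' the sum of directions among significant engines; features whose
#' significant engines disagree in sign carry a discordance flag (a tied
#' direction yields 0). Engines that failed are simply absent and shrink
#' \code{n_engines_run}.
#'
#' @param results named list of per-engine result data.frames (all on the
#'   same feature set).
#' @param threshold vote fraction.
#' @param level optional level label carried into the output.
#' @return data.frame, one row per feature: vote count, consensus flag,
#'   majority direction, discordance flag, and one logical column
#'   \code{sig_<engine>} per engine.
#' @export
vote <- function(results, threshold = 0.5, level = NA_character_) {
  if (length(results) == 0) stop("no engine results to vote on")
  feats <- results[[1]]$feature_id
  for (r in results)
    if (!identical(sort(r$feature_id), sort(feats)))
      stop("engines report on different feature sets")
  k <- length(results)
  quota <- min_votes(k, threshold)
  sig <- sapply(results, function(r)
    r$significant[match(feats, r$feature_id)])
  dirs <- sapply(results, function(r)
    r$direction[match(feats, r$feature_id)])
  sig <- matrix(sig, ncol = k,
                dimnames = list(NULL, names(results)))
  dirs <- matrix(dirs, ncol = k)
  n_sig <- rowSums(sig)
  dir_sum <- rowSums(dirs * sig)
  has_pos <- rowSums(sig & dirs > 0) > 0
  has_neg <- rowSums(sig & dirs < 0) > 0
  out <- data.frame(feature_id = feats, level = level,
                    n_engines_run = k, n_significant = as.integer(n_sig),
                    consensus = n_sig >= quota,
                    majority_direction = as.integer(sign(dir_sum)),
                    discordant = has_pos & has_neg,
                    row.names = NULL, stringsAsFactors = FALSE)
  sig_df <- as.data.frame(sig)
  names(sig_df) <- paste0("sig_", names(results))
  cbind(out, sig_df)
}

#' Vote independently at every feature level
#'
#' Levels are analysed separately; a consensus call at one level never
#' propagates to another.
#'
#' @param all_results nested list, level -> engine -> result data.frame
#'   (the \code{results} element of \code{\link{run_all_engines}}).
#' @param threshold vote fraction.
#' @return one tidy data.frame with a level column.
#' @export
consensus_across_levels <- function(all_results, threshold = 0.5) {
  out <- lapply(names(all_results), function(lv)
    vote(all_results[[lv]], threshold, level = lv))
  common <- Reduce(intersect, lapply(out, names))
  do.call(rbind, lapply(out, function(d) d[, common, drop = FALSE]))
}

#' Split a consensus table into main and supplementary tiers
#'
#' Consensus features (quota reached) form the main report; features
#' called by at least one engine but below quota form the supplementary
#' tier.
#'
#' @param cons output of \code{\link{vote}} or
#'   \code{\link{consensus_across_levels}}.
#' @return list with \code{main} and \code{supplementary} data.frames.
#' @export
consensus_tiers <- function(cons) {
  list(main = cons[cons$consensus, , drop = FALSE],
       supplementary = cons[!cons$consensus & cons$n_significant > 0, ,
                            drop = FALSE])
}

#' Compare consensus sets between input modes (method 1 vs method 2)
#'
#' Set algebra on consensus calls from two runs over the same feature
#' universe, additionally stratifying the overlap by vote count.
#'
#' @param cons_m1,cons_m2 consensus tables from the two input modes.
#' @return list with \code{shared}, \code{only_m1}, \code{only_m2}
#'   (feature keys) and \code{by_votes}, a data.frame with per-vote-tier
#'   overlap counts (tiers 3..6).
#' @export
compare_methods <- function(cons_m1, cons_m2) {
  key <- function(d) paste(d$level, d$feature_id, sep = ":")
  if (!setequal(key(cons_m1), key(cons_m2)))
    stop("mismatched feature universes between methods")
  c1 <- key(cons_m1)[cons_m1$consensus]
  c2 <- key(cons_m2)[cons_m2$consensus]
  tiers <- sort(unique(cons_m1$n_significant[cons_m1$consensus]))
  by_votes <- do.call(rbind, lapply(tiers, function(v) {
    cv <- key(cons_m1)[cons_m1$consensus & cons_m1$n_significant >= v]
    data.frame(min_votes = v, n_m1 = length(cv),
               n_also_m2 = length(intersect(cv, c2)))
  }))
  list(shared = intersect(c1, c2),
       only_m1 = setdiff(c1, c2),
       only_m2 = setdiff(c2, c1),
       by_votes = by_votes %||% data.frame(min_votes = integer(0),
                                           n_m1 = integer(0),
                                           n_also_m2 = integer(0)))
}
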