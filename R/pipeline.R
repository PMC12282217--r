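#' Full analysis of a cohort: diversity, engines, consensus, metrics
#'
#' Orchestrates the stage order of the study: rarefaction and alpha
#' diversity, Aitchison beta diversity with dispersion-gated PERMANOVA,
#' matched/unmatched stability, depth diagnostics, then the six DA engines
#' and the majority-vote consensus, with tool-concordance metrics. All
#' randomness flows from \code{seed} via named substreams so stages can be
#' re-run in isolation; re-running with the same inputs and seed
#' reproduces identical outputs.
#'
#' @param tables named list, level -> \code{feature_table}.
#' @param meta validated metadata.
#' @param design a \code{\link{da_design}}.
#' @param input_mode \code{"proportions"} (method 1) or \code{"counts"}
#'   (method 2).
#' @param threshold consensus vote fraction.
#' @param cfg an \code{\link{engine_config}}.
#' @param params a \code{\link{transform_params}}.
#' @param rarefy_depth depth for alpha diversity; NULL uses the minimum
#'   sample total of the first count-convertible table.
#' @param seed root seed (overrides \code{cfg$seed}).
#' @param run_diversity compute the diversity block (needs a count or
#'   relative taxonomic table plus library sizes).
#' @return list of class \code{condaba_run} with elements
#'   \code{diversity}, \code{engines}, \code{consensus}, \code{tiers},
#'   \code{metrics}, \code{depth}, \code{audit}, \code{config}.
#' @export
analyze_cohort <- function(tables, meta, design = da_design(),
                           input_mode = "proportions", threshold = 0.5,
                           cfg = engine_config(), params = transform_params(),
                           rarefy_depth = NULL, seed = 1,
                           run_diversity = TRUE) {
  cfg$seed <- seed
  meta <- sample_metadata(meta)
  stages <- list()

  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(out)))
    out
  }

  diversity <- NULL
  first <- tables[[1]]
  if (run_diversity) diversity <- run_stage("diversity", {
    counts <- if (first$unit == "count") first
              else to_approximate_counts(to_proportions(first), meta)
    depth <- rarefy_depth %||% min(rowSums(counts$values))
    rare <- rarefy(counts, depth, seed = derive_seed(seed, "rarefaction"))
    alpha_r <- alpha_diversity(rare)
    alpha_raw <- data.frame(sample_id = ft_samples(counts),
                            richness = as.integer(rowSums(counts$values > 0)))
    pseudo <- if (first$unit == "rpk") params$pseudo_pathway
              else params$pseudo_taxa
    rel <- if (first$unit == "count") {
      ft <- to_proportions(first)
      feature_table(ft$values * 100, "relative_percent", first$level,
                    check_sums = FALSE)
    } else first
    dm <- aitchison(rel, pseudo)
    meta_o <- meta[match(ft_samples(rel), meta$sample_id), ]
    disp <- permdisp(dm, meta_o$group, n_perm = min(cfg$n_perm, 999),
                     seed = derive_seed(seed, "permdisp"))
    pmv <- permanova(dm, meta_o$group, n_perm = min(cfg$n_perm * 10 + 9, 9999),
                     seed = derive_seed(seed, "permanova"))
    stability <- tryCatch(matched_unmatched(dm, meta_o),
                          error = function(e) NULL)
    list(rarefy_depth = depth, alpha = alpha_r,
         depth_richness = depth_richness_corr(meta, alpha_raw),
         permdisp = disp,
         permanova = pmv, permanova_reported = disp$gate_pass,
         stability = stability)
  })

  depth <- run_stage("depth", depth_group_test(meta))
  eng <- run_stage("da_engines",
                   run_all_engines(tables, meta, design, input_mode, cfg,
                                   params))
  cons <- run_stage("consensus",
                    consensus_across_levels(eng$results, threshold))
  tiers <- consensus_tiers(cons)
  metrics <- run_stage("metrics", do.call(rbind, lapply(
    names(eng$results), function(lv)
      tool_metrics(eng$results[[lv]], cons[cons$level == lv, , drop = FALSE],
                   dataset_id = lv))))

  structure(list(diversity = diversity, engines = eng$results,
                 consensus = cons, tiers = tiers, metrics = metrics,
                 depth = depth, audit = eng$audit,
                 config = list(input_mode = input_mode,
                               threshold = threshold, seed = seed,
                               alpha = design$alpha,
                               mc_samples = cfg$mc_samples,
                               n_perm = cfg$n_perm)),
            class = "condaba_run")
}

#' Write a run's tables to a directory
#'
#' Engine results, consensus (main + supplementary tier), diversity,
#' tool metrics, the method-1/method-2 audit and a JSON run summary, as
#' tidy TSV/JSON. Deterministic given the run object.
#'
#' @param run a \code{condaba_run}.
#' @param dir output directory (created).
#' @return invisibly, the vector of files written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wt <- function(d, name) {
    f <- file.path(dir, name)
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  eng_tidy <- do.call(rbind, lapply(names(run$engines), function(lv)
    do.call(rbind, lapply(run$engines[[lv]], function(r)
      cbind(level = lv, r)))))
  wt(eng_tidy, "engine_results.tsv")
  wt(run$consensus, "consensus_all.tsv")
  wt(run$tiers$main, "consensus_main.tsv")
  wt(run$tiers$supplementary, "consensus_supplementary.tsv")
  wt(run$metrics, "tool_metrics.tsv")
  wt(run$audit, "audit.tsv")
  if (!is.null(run$diversity)) {
    wt(run$diversity$alpha, "alpha_diversity.tsv")
  }
  summ <- file.path(dir, "run_summary.json")
  jsonlite::write_json(report_counts(run), summ, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, summ)
  invisible(files)
}

#' Human-readable run report
#'
#' Per-stage counts: per-engine call counts, consensus features with vote
#' counts and directions, and the depth diagnostic. Idempotent.
#'
#' @param run a \code{condaba_run}.
#' @return list of summary counts (also printed).
#' @export
report_counts <- function(run) {
  calls <- lapply(run$engines, function(lv)
    vapply(lv, function(r) sum(r$significant), integer(1)))
  list(levels = names(run$engines),
       per_engine_calls = calls,
       n_consensus = sum(run$consensus$consensus),
       consensus_features = run$tiers$main[
         , c("level", "feature_id", "n_significant", "majority_direction")],
       n_supplementary = nrow(run$tiers$supplementary),
       depth_p = run$depth$p,
       config = run$config)
}

#' @export
print.condaba_run <- function(x, ...) {
  r <- report_counts(x)
  cat(sprintf("<condaba_run> input_mode=%s threshold=%s seed=%s\n",
              x$config$input_mode, x$config$threshold, x$config$seed))
  for (lv in r$levels)
    cat(sprintf("  %s: engine calls [%s]\n", lv,
                paste(names(r$per_engine_calls[[lv]]),
                      r$per_engine_calls[[lv]], sep = "=", collapse = ", ")))
  cat(sprintf("  consensus features: %d (supplementary tier: %d)\n",
              r$n_consensus, r$n_supplementary))
  if (!is.null(x$diversity))
    cat(sprintf("  permanova p=%.4g (reported: %s), depth-group p=%.4g\n",
                x$diversity$permanova$p, x$diversity$permanova_reported,
                x$depth$p))
  invisible(x)
}
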