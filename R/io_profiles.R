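#' Transform and filtering parameters
#'
#' Defaults follow common practice for shotgun profiles: pseudo-count of
#' 0.0001 on the percent scale for taxa and 1 on the RPK scale for pathways
#' before CLR; a 10% prevalence filter with a tiny abundance floor so that
#' numerically-zero cells never count as present.
#'
#' @param pseudo_taxa pseudo-count added to percent-scale taxonomic tables.
#' @param pseudo_pathway pseudo-count added to RPK pathway tables.
#' @param min_prevalence fraction of samples, in (0, 1], in which a feature
#'   must exceed \code{min_abundance} to be retained.
#' @param min_abundance strictly-greater-than presence threshold. NULL picks
#'   0 for count tables and 1e-15 otherwise.
#' @return a list of class \code{transform_params}.
#' @export
transform_params <- function(pseudo_taxa = 1e-4, pseudo_pathway = 1,
                             min_prevalence = 0.1, min_abundance = NULL) {
  stopifnot(pseudo_taxa > 0, pseudo_pathway > 0,
            min_prevalence > 0, min_prevalence <= 1,
            is.null(min_abundance) || min_abundance >= 0)
  structure(list(pseudo_taxa = pseudo_taxa, pseudo_pathway = pseudo_pathway,
                 min_prevalence = min_prevalence, min_abundance = min_abundance),
            class = "transform_params")
}

rank_prefixes <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species", t = "sgb")

#' Read a merged MetaPhlAn-style taxonomy table, one table per rank
#'
#' The feature-name column holds pipe-delimited rank strings
#' (\code{k__...|p__...|...|t__SGB...}); a row belongs to the table of the
#' deepest rank present in its string, so each level's table holds a full
#' partition of abundance at that rank. Values are relative abundances on
#' the percent scale.
#'
#' @param path TSV path: first column feature strings, one numeric column
#'   per sample. Comment lines starting with '#' are skipped.
#' @return named list, level -> \code{feature_table} (unit
#'   \code{relative_percent}).
#' @export
read_merged_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy table needs a feature column and >=1 sample column")
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats))
    stop("duplicate feature string: ", feats[duplicated(feats)][1])
  depth_level <- character(length(feats))
  for (i in seq_along(feats)) {
    toks <- strsplit(feats[i], "|", fixed = TRUE)[[1]]
    pref <- sub("__.*$", "", toks)
    bad <- !pref %in% names(rank_prefixes) | !grepl("^[kpcofgst]__", toks)
    if (any(bad))
      stop(sprintf("malformed rank prefix '%s' in line %d ('%s')",
                   toks[bad][1], i, feats[i]))
    if (any(match(pref, names(rank_prefixes)) != seq_along(pref)))
      stop(sprintf("rank order violated in line %d ('%s')", i, feats[i]))
    depth_level[i] <- rank_prefixes[[pref[length(pref)]]]
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  out <- list()
  for (lv in intersect(unname(rank_prefixes), unique(depth_level))) {
    sel <- depth_level == lv
    m <- t(vals[sel, , drop = FALSE])
    colnames(m) <- feats[sel]
    out[[lv]] <- feature_table(m, "relative_percent", lv, check_sums = FALSE)
  }
  out
}

#' Read a HUMAnN-style pathway abundance table (RPK)
#'
#' Keeps unstratified pathway rows only; stratified rows (containing a
#' \code{|genus.species} suffix) are dropped, as are UNMAPPED/UNINTEGRATED
#' bookkeeping rows unless requested.
#'
#' @param path TSV path, first column pathway id, one column per sample.
#' @param keep_unmapped keep the UNMAPPED/UNINTEGRATED rows (default drop).
#' @return a \code{feature_table} with unit \code{rpk}, level
#'   \code{pathway}.
#' @export
read_pathway_table <- function(path, keep_unmapped = FALSE) {
  # HUMAnN headers start with '#', so comment skipping must not eat them
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  unstrat <- !grepl("|", feats, fixed = TRUE)
  special <- feats %in% c("UNMAPPED", "UNINTEGRATED")
  keep <- unstrat & (keep_unmapped | !special)
  if (!any(keep)) stop("no unstratified pathway rows in ", path)
  m <- t(as.matrix(df[keep, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- feats[keep]
  feature_table(m, "rpk", "pathway", check_sums = FALSE)
}

#' Write a feature table as TSV (features x samples)
#'
#' Count tables round-trip bit-identically through
#' \code{\link{read_feature_table}}.
#' @param x a \code{feature_table}.
#' @param path output TSV path.
#' @param id_column header of the feature-id column.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  m <- t(x$values)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_feature_table}}
#' @param path TSV path.
#' @param unit,level unit and level tags to attach.
#' @return a \code{feature_table}.
#' @export
read_feature_table <- function(path, unit, level) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- as.character(df[[1]])
  feature_table(m, unit, level, check_sums = FALSE)
}

#' Read a sample metadata table (TSV or CSV by extension)
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  sample_metadata(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE))
}

#' Convert a relative table to proportions summing to one
#'
#' Percent tables are divided by 100; count and RPK tables are closed by
#' their row totals.
#' @param x a \code{feature_table}.
#' @return a \code{feature_table} with unit \code{proportion}.
#' @export
to_proportions <- function(x) {
  v <- switch(x$unit,
    proportion = x$values,
    relative_percent = x$values / 100,
    count = ,
    rpk = {
      rs <- rowSums(x$values)
      if (any(rs == 0)) stop("cannot close a sample with zero total abundance")
      sweep(x$values, 1, rs, "/")
    })
  feature_table(v, "proportion", x$level, check_sums = FALSE)
}

#' Approximate read counts from relative abundances
#'
#' Shotgun profilers report relative abundance, not counts; engines that
#' model sequencing counts receive approximate counts obtained by
#' multiplying each sample's abundance fraction by its post-QC library
#' size. Optional rounding (half-to-even, unbiased over many cells) meets
#' integer-input requirements.
#'
#' @param x \code{feature_table} with unit \code{relative_percent} or
#'   \code{proportion}.
#' @param meta validated metadata supplying \code{library_size}.
#' @param round_to_int round counts half-to-even.
#' @return a \code{feature_table} with unit \code{count}.
#' @export
to_approximate_counts <- function(x, meta, round_to_int = TRUE) {
  if (!x$unit %in% c("relative_percent", "proportion"))
    stop("to_approximate_counts expects a relative table, got unit=", x$unit)
  meta <- meta_align(meta, x)
  if (anyNA(meta$library_size)) stop("missing library_size")
  frac <- if (x$unit == "relative_percent") x$values / 100 else x$values
  v <- sweep(frac, 1, meta$library_size, "*")
  if (round_to_int) v <- round_half_even(v)
  feature_table(v, "count", x$level, check_sums = FALSE)
}

#' Prevalence filter
#'
#' Keeps features whose abundance exceeds \code{min_abundance} (strictly) in
#' at least \code{ceiling(min_prevalence * n_samples)} samples. The sample
#' set is unchanged and rows are deliberately not renormalized, so filtered
#' relative tables are open compositions.
#'
#' @param x a \code{feature_table}.
#' @param params a \code{\link{transform_params}} object.
#' @return filtered \code{feature_table} (possibly with zero features).
#' @export
prevalence_filter <- function(x, params = transform_params()) {
  min_ab <- params$min_abundance %||% if (x$unit == "count") 0 else 1e-15
  need <- ceiling(params$min_prevalence * nrow(x$values))
  keep <- colSums(x$values > min_ab) >= need
  ft_subset(x, features = keep)
}

#' Centred log-ratio transform
#'
#' Per sample, \code{log(x + pseudo)} centred by its mean, so each output
#' row sums to zero and per-sample scale multiples map to the same point.
#' The pseudo-count is applied on the table's native unit scale.
#'
#' @param x a \code{feature_table} or non-negative matrix.
#' @param pseudo strictly positive pseudo-count.
#' @return matrix of CLR values (samples x features).
#' @export
clr_transform <- function(x, pseudo) {
  v <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (pseudo < 0 || (pseudo == 0 && any(v <= 0)))
    stop("pseudo-count must be > 0 (or 0 for strictly positive data)")
  if (any(v < 0)) stop("negative abundance in CLR input")
  lg <- log(v + pseudo)
  lg - rowMeans(lg)
}

#' Arcsine square root transform
#'
#' Variance-stabilizing transform for proportions: \code{asin(sqrt(x))},
#' mapping [0, 1] monotonically onto [0, pi/2].
#' @param x a proportion-unit \code{feature_table} or matrix in [0, 1].
#' @return transformed matrix.
#' @export
ast_transform <- function(x) {
  v <- if (inherits(x, "feature_table")) {
    if (x$unit != "proportion") stop("ast_transform expects proportions")
    x$values
  } else as.matrix(x)
  if (any(v < 0 | v > 1)) stop("AST input outside [0, 1]")
  asin(sqrt(v))
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via \code{vegan::rrarefy}) so every retained sample sums
#' exactly to \code{depth}. Samples shallower than \code{depth} are dropped
#' with a warning (the logged default) or cause an error.
#'
#' @param x integer-count \code{feature_table}.
#' @param depth target depth, > 0.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param drop_low drop samples below depth (TRUE) or error (FALSE).
#' @return rarefied \code{feature_table} (unit count).
#' @export
rarefy <- function(x, depth, seed, drop_low = TRUE) {
  if (depth <= 0) stop("rarefaction depth must be > 0")
  v <- round(x$values)
  totals <- rowSums(v)
  low <- totals < depth
  if (any(low)) {
    if (!drop_low)
      stop("samples below rarefaction depth: ",
           paste(rownames(v)[low], collapse = ", "))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth, paste(rownames(v)[low], collapse = ", ")))
    v <- v[!low, , drop = FALSE]
  }
  if (nrow(v) == 0) stop("no samples at or above rarefaction depth")
  # rrarefy warns whenever the smallest positive count exceeds 1, which is
  # the norm for deep shotgun tables; shallow samples are handled above
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(v, depth)))
  feature_table(out, "count", x$level, check_sums = FALSE)
}
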