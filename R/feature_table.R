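#' Feature abundance table
#'
#' The central container of the pipeline: a samples-by-features matrix of
#' non-negative abundances tagged with its measurement unit and the feature
#' level (a taxonomic rank, SGB, or pathway). Absences are explicit zeros;
#' missing cells are not permitted.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   row and column names. Must be non-negative with no missing values.
#' @param unit one of \code{"relative_percent"}, \code{"proportion"},
#'   \code{"count"}, \code{"rpk"}.
#' @param level one of the taxonomic ranks (\code{"kingdom"} ...
#'   \code{"sgb"}) or \code{"pathway"}.
#' @param require_integer if TRUE and \code{unit == "count"}, values must be
#'   whole numbers.
#' @param check_sums if TRUE, percent tables must have rows summing to 100
#'   (tolerance 1e-6) and proportion tables to 1 (tolerance 1e-9). Disable
#'   after filtering, which deliberately does not renormalize.
#' @return an object of class \code{feature_table}.
#' @export
feature_table <- function(values, unit, level,
                          require_integer = FALSE, check_sums = TRUE) {
  unit <- match.arg(unit, c("relative_percent", "proportion", "count", "rpk"))
  level <- match.arg(level, c("kingdom", "phylum", "class", "order",
                              "family", "genus", "species", "sgb", "pathway"))
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature_table values need sample (row) and feature (column) names")
  if (anyNA(values)) stop("feature_table has missing cells; absences must be explicit zeros")
  if (any(values < 0)) stop("feature_table has negative abundances")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids within a level")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (check_sums && nrow(values) > 0 && ncol(values) > 0) {
    rs <- rowSums(values)
    if (unit == "relative_percent" && any(abs(rs - 100) > 1e-6))
      stop("relative_percent rows must sum to 100 (got range ",
           paste(signif(range(rs), 8), collapse = "-"), ")")
    if (unit == "proportion" && any(abs(rs - 1) > 1e-9))
      stop("proportion rows must sum to 1")
  }
  if (unit == "count" && require_integer && any(abs(values - round(values)) > 1e-9))
    stop("count table contains non-integer values")
  structure(list(values = values, unit = unit, level = level),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, unit=%s, level=%s\n",
              nrow(x$values), ncol(x$values), x$unit, x$level))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample and feature identifiers of a feature table
#' @param x a \code{feature_table}.
#' @return character vector of ids.
#' @export
ft_samples <- function(x) rownames(x$values)

#' @rdname ft_samples
#' @export
ft_features <- function(x) colnames(x$values)

#' Subset a feature table by samples and/or features
#' @param x a \code{feature_table}.
#' @param samples,features index vectors (names, logical or integer); NULL
#'   keeps everything.
#' @return a \code{feature_table}; unit sums are not re-checked (subsets of
#'   closed compositions are open).
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  feature_table(v, x$unit, x$level, check_sums = FALSE)
}

#' Validate a sample metadata table
#'
#' Required columns: \code{sample_id}, \code{subject_id}, \code{group}
#' (control/case), \code{timepoint} (early/late), \code{library_size}
#' (post-QC read count, strictly positive). \code{bmi} is optional.
#'
#' @param meta a data.frame.
#' @param table optional \code{feature_table}; if given, every sample of the
#'   table must resolve to exactly one metadata row.
#' @return the metadata, with group and timepoint as factors with fixed
#'   level order (control before case, early before late).
#' @export
sample_metadata <- function(meta, table = NULL) {
  req <- c("sample_id", "subject_id", "group", "timepoint", "library_size")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$group %in% c("control", "case")))
    stop("group must be 'control' or 'case'")
  if (!all(meta$timepoint %in% c("early", "late")))
    stop("timepoint must be 'early' or 'late'")
  if (any(!is.finite(meta$library_size)) || any(meta$library_size <= 0))
    stop("library_size must be > 0 for every sample")
  meta$group <- factor(meta$group, levels = c("control", "case"))
  meta$timepoint <- factor(meta$timepoint, levels = c("early", "late"))
  if (!is.null(table)) {
    unmatched <- setdiff(ft_samples(table), meta$sample_id)
    if (length(unmatched))
      stop("samples absent from metadata: ", paste(unmatched, collapse = ", "))
  }
  meta
}

#' Align metadata rows to the sample order of a table
#' @param meta validated metadata.
#' @param x a \code{feature_table}.
#' @return metadata reordered to match \code{ft_samples(x)}.
#' @export
meta_align <- function(meta, x) {
  meta <- sample_metadata(meta, x)
  meta[match(ft_samples(x), meta$sample_id), , drop = FALSE]
}
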