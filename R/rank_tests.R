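#' Two-sample rank-sum test (Wilcoxon/Mann-Whitney)
#'
#' Exact enumeration of all group assignments when the total sample size is
#' at most \code{exact_max} (ties handled by enumerating midrank sums);
#' otherwise midranks with the normal approximation, tie-corrected variance
#' and continuity correction. Two-sided.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max largest total n for which exact enumeration is used.
#' @return list with \code{statistic} (rank sum of \code{x}) and \code{p}.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  s <- sum(r[seq_len(nx)])
  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    dev <- abs(sums - nx * (n + 1) / 2)
    p <- mean(dev >= abs(s - nx * (n + 1) / 2) - 1e-12)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = s, p = 1))
    z <- (abs(s - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(statistic = s, p = p)
}

#' Column-wise rank-sum p-values for a two-group design
#'
#' Applies \code{\link{rank_sum_test}} to every column of a matrix; used by
#' engines that test many features per Monte-Carlo instance.
#'
#' @param z numeric matrix, samples x features.
#' @param in_x logical vector marking group-1 rows.
#' @param exact_max see \code{\link{rank_sum_test}}.
#' @return numeric vector of two-sided p-values, one per column.
#' @export
rank_sum_columns <- function(z, in_x, exact_max = 8) {
  nx <- sum(in_x); ny <- sum(!in_x); n <- nx + ny
  if (n <= exact_max) {
    return(vapply(seq_len(ncol(z)), function(j)
      rank_sum_test(z[in_x, j], z[!in_x, j], exact_max)$p, numeric(1)))
  }
  mu <- nx * (n + 1) / 2
  p <- numeric(ncol(z))
  for (j in seq_len(ncol(z))) {
    r <- rank(z[, j])
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p[j] <- 1; next }
    zstat <- (abs(sum(r[in_x]) - mu) - 0.5) / sqrt(sig2)
    p[j] <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
  }
  p
}
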