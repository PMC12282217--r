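#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a root seed and a label
#'
#' Named substreams let pipeline stages (simulation, rarefaction,
#' permutation, each engine) be re-run in isolation while all randomness
#' flows from one root seed. Result stays below 2^31.
#'
#' @param seed root integer seed.
#' @param label character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All permutations of 1..n
#'
#' Used for exhaustive permutation tests at small n (n! grows fast; capped
#' at n = 9).
#' @param n integer (<= 9).
#' @return list of integer vectors.
#' @keywords internal
all_perms <- function(n) {
  if (n > 9) stop("exhaustive enumeration capped at n = 9")
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos)
  }
  out
}

#' Round half to even (banker's rounding)
#'
#' Base \code{round()} already implements IEC 60559 round-half-to-even for
#' \code{digits = 0}; this wrapper exists to name the policy at call sites.
#' @param x numeric.
#' @return numeric of the same shape.
#' @keywords internal
round_half_even <- function(x) round(x)
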