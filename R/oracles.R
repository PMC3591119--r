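#' Exhaustive small-instance alignment oracles
#'
#' Brute-force references for the DP cores: every strictly monotone set of
#' index pairs of an `m x n` instance is enumerated and scored directly,
#' so the oracles share no code path with the DP recurrences they check.
#' Cost grows combinatorially; intended for `m, n <= 7`.
#'
#' `enumerate_monotone_alignments()` returns every alignment (including
#' the empty one) as a two-column index matrix. `oracle_linear_score()`
#' and `oracle_affine_score()` return the optimum of the corresponding
#' gap-scoring objective (interior gaps only, free ends).
#' `oracle_numpairs()` returns the maximum cardinality of a monotone
#' pairing with all paired distances at most `d`.
#'
#' @param m,n instance dimensions.
#' @return For `enumerate_monotone_alignments()`, a list of 2-column
#'   integer matrices.
#' @export
enumerate_monotone_alignments <- function(m, n) {
  key <- paste(m, n)
  if (!is.null(.enum_cache[[key]])) return(.enum_cache[[key]])
  rec <- function(i0, j0) {
    out <- list(matrix(integer(0), 0, 2))
    if (i0 > m || j0 > n) return(out)
    for (i in i0:m) for (j in j0:n) {
      for (tail in rec(i + 1L, j + 1L))
        out[[length(out) + 1L]] <- rbind(c(i, j), tail)
    }
    out
  }
  res <- rec(1L, 1L)
  .enum_cache[[key]] <- res
  res
}
.enum_cache <- new.env(parent = emptyenv())

# Interior skipped positions / gap runs of one alignment matrix.
interior_gaps <- function(p) {
  if (nrow(p) < 2L) return(c(positions = 0L, runs = 0L))
  di <- diff(p[, 1]); dj <- diff(p[, 2])
  c(positions = sum(di - 1L) + sum(dj - 1L),
    runs = sum(di > 1L) + sum(dj > 1L))
}

#' @param S score matrix.
#' @param gap per-position penalty.
#' @rdname enumerate_monotone_alignments
#' @export
oracle_linear_score <- function(S, gap) {
  best <- 0
  for (p in enumerate_monotone_alignments(nrow(S), ncol(S))) {
    if (!nrow(p)) next
    v <- sum(S[p]) - gap * interior_gaps(p)[["positions"]]
    if (v > best) best <- v
  }
  best
}

#' @param open,extend affine penalties (a run of `g` positions costs
#'   `open + (g - 1) * extend`).
#' @rdname enumerate_monotone_alignments
#' @export
oracle_affine_score <- function(S, open, extend) {
  best <- 0
  for (p in enumerate_monotone_alignments(nrow(S), ncol(S))) {
    if (!nrow(p)) next
    g <- interior_gaps(p)
    v <- sum(S[p]) - open * g[["runs"]] -
      extend * (g[["positions"]] - g[["runs"]])
    if (v > best) best <- v
  }
  best
}

#' @param a,b_hat structures or coordinate matrices.
#' @param d distance cutoff (Angstroms).
#' @rdname enumerate_monotone_alignments
#' @export
oracle_numpairs <- function(a, b_hat, d) {
  ok <- dist2_matrix(a, b_hat) <= d^2
  best <- 0L
  for (p in enumerate_monotone_alignments(nrow(ok), ncol(ok))) {
    if (nrow(p) > best && all(ok[p])) best <- nrow(p)
  }
  best
}
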