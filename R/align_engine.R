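#' Sequential alignment of two structures
#'
#' The universal output of every aligner: a strictly increasing list of
#' residue index pairs `(i, j)` (1-based positions in each chain's residue
#' order), with the score of the scheme that produced it.
#'
#' @param i,j integer index vectors, each strictly increasing, equal
#'   length.
#' @param score scheme-dependent alignment score.
#' @param scheme tag naming the scoring scheme (`"structal"`,
#'   `"tmalign"`, `"threshold"`, `"lock2"`, `"reference"`, ...).
#' @return An object of class `alignment` with elements `i`, `j`,
#'   `score`, `scheme`.
#' @export
alignment <- function(i, j, score = NA_real_, scheme = "none") {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (length(i) > 1L && (any(diff(i) <= 0L) || any(diff(j) <= 0L)))
    stop("alignment indices must be strictly increasing in both sequences")
  structure(list(i = i, j = j, score = as.numeric(score),
                 scheme = as.character(scheme)), class = "alignment")
}

#' @param al an `alignment`.
#' @rdname alignment
#' @export
alignment_length <- function(al) length(al$i)

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment (%s): %d pairs, score %.4g\n", x$scheme,
              alignment_length(x), x$score))
  invisible(x)
}

#' @export
as.data.frame.alignment <- function(x, ...) {
  data.frame(i = x$i, j = x$j)
}

# Squared inter-structure distance matrix ||a_i - b_j||^2 (m x n).
dist2_matrix <- function(a, b) {
  A <- as_xyz(a); B <- as_xyz(b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' STRUCTAL score matrix
#'
#' `S(i, j) = 20 / (1 + d_ij^2 / 5)` with `d_ij` the distance between
#' C-alpha `i` of `a` and C-alpha `j` of the already-superposed `b_hat`;
#' 20 at zero distance, strictly decreasing, never negative.
#'
#' @param a,b_hat structures (or coordinate matrices); `b_hat` must
#'   already carry the superposition under which scores are wanted.
#' @return `m x n` numeric matrix.
#' @export
structal_score_matrix <- function(a, b_hat) {
  20 / (1 + dist2_matrix(a, b_hat) / 5)
}

#' TM-align length-dependent distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` with `L` the length of the shorter
#' structure, floored at 0.5 Angstroms so the score matrix stays well
#' defined on short chains (the raw formula is non-positive for
#' `L <= 18` and below the floor up to `L = 21`).
#'
#' @param L integer length of the shorter structure.
#' @return Positive scale in Angstroms.
#' @examples
#' tmalign_d0(140)  # 4.4
#' tmalign_d0(42)   # 1.92
#' @export
tmalign_d0 <- function(L) {
  stopifnot(L >= 1)
  raw <- ifelse(L > 15, 1.24 * (L - 15)^(1 / 3) - 1.8, -Inf)
  pmax(raw, 0.5)
}

#' TM-align score matrix
#'
#' `S(i, j) = 1 / (1 + (d_ij / d0)^2)`: 1 at zero distance, 0.5 at
#' `d_ij = d0`, bounded in `(0, 1]`.
#'
#' @inheritParams structal_score_matrix
#' @param d0 distance scale (Angstroms), usually [tmalign_d0()] of the
#'   shorter length.
#' @return `m x n` numeric matrix.
#' @export
tmalign_score_matrix <- function(a, b_hat, d0) {
  stopifnot(d0 > 0)
  1 / (1 + dist2_matrix(a, b_hat) / d0^2)
}

#' Linear-gap alignment DP
#'
#' Maximizes the summed score of matched pairs minus `gap` for every
#' skipped position strictly inside the aligned span (either sequence);
#' with the default `free_ends = TRUE` unmatched prefixes and suffixes
#' cost nothing. `free_ends = FALSE` runs the classical zero-boundary
#' recurrence `D(i,j) = max{D(i-1,j-1)+S(i,j), D(i-1,j)-gap,
#' D(i,j-1)-gap}` and reports `D(m,n)`. Traceback ties are broken
#' deterministically (diagonal, then vertical, then horizontal), so
#' outputs are bit-reproducible.
#'
#' @param S score matrix (`m x n`).
#' @param gap nonnegative penalty per skipped position (STRUCTAL uses 10).
#' @param free_ends free end gaps at both ends (default).
#' @param scheme scheme tag stored on the result.
#' @return An [alignment] achieving the maximum; empty matrix or no
#'   positive-scoring alignment gives an empty alignment with score 0.
#' @export
dp_linear <- function(S, gap = 10, free_ends = TRUE, scheme = "linear") {
  stopifnot(gap >= 0)
  r <- .dp_linear_cpp(as.matrix(S), gap, isTRUE(free_ends))
  alignment(r$i, r$j, score = r$score, scheme = scheme)
}

#' Affine-gap alignment DP (Gotoh)
#'
#' Maximizes the summed score of matched pairs minus, for every gap run
#' strictly inside the aligned span, `open` for the run plus `extend` per
#' additional gapped position; end gaps are free. Defaults are the
#' TM-align penalties (0.6 open, 0.0 extend).
#'
#' @inheritParams dp_linear
#' @param open nonnegative gap-opening penalty per run.
#' @param extend nonnegative penalty per additional gapped position.
#' @return An [alignment].
#' @export
dp_affine <- function(S, open = 0.6, extend = 0, scheme = "affine") {
  stopifnot(open >= 0, extend >= 0)
  r <- .dp_affine_cpp(as.matrix(S), open, extend)
  alignment(r$i, r$j, score = r$score, scheme = scheme)
}

#' Maximum residue pairs under a distance cutoff, fixed superposition
#'
#' The largest strictly monotone (sequential) pairing of residues of `a`
#' with residues of the superposed `b_hat` in which every matched pair is
#' within `d` Angstroms; forbidden cells are simply never matched, and
#' skipping costs nothing. The score of the returned alignment is the
#' pair count.
#'
#' @param a,b_hat structures or coordinate matrices (`b_hat` superposed).
#' @param d distance cutoff in Angstroms.
#' @return An [alignment] with `score` equal to the (integer) pair count.
#' @export
numpairs_dp <- function(a, b_hat, d) {
  stopifnot(d > 0)
  r <- .numpairs_cpp(as_xyz(a), as_xyz(b_hat), d)
  alignment(r$i, r$j, score = r$score, scheme = "threshold")
}

#' STRUCTAL total score of an alignment
#'
#' Sum over aligned pairs of `20 / (1 + d^2/5)` minus `gap` times the gap
#' count `G`. By default (`gap_count = "positions"`) `G` counts every
#' unaligned position strictly inside the aligned span, the convention
#' consistent with the per-position DP recurrence; `gap_count = "runs"`
#' counts maximal runs of such positions instead.
#'
#' @param al an [alignment] valid for `a` and `b_hat`.
#' @param a,b_hat structures or coordinate matrices (`b_hat` superposed).
#' @param gap penalty constant (10).
#' @param gap_count `"positions"` or `"runs"`.
#' @return Numeric score.
#' @export
structal_total_score <- function(al, a, b_hat, gap = 10,
                                 gap_count = c("positions", "runs")) {
  gap_count <- match.arg(gap_count)
  A <- as_xyz(a); B <- as_xyz(b_hat)
  k <- alignment_length(al)
  if (k == 0L) return(0)
  d2 <- rowSums((A[al$i, , drop = FALSE] - B[al$j, , drop = FALSE])^2)
  G <- if (gap_count == "positions") {
    sum(diff(al$i) - 1L) + sum(diff(al$j) - 1L)
  } else {
    sum(diff(al$i) > 1L) + sum(diff(al$j) > 1L)
  }
  sum(20 / (1 + d2 / 5)) - gap * G
}
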