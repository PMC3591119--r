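#' Method-specific NumPairs(d)
#'
#' The number of pairs in a given alignment whose residues lie within `d`
#' Angstroms after superposition. Unlike the alignment-independent
#' [pairs_under()], this counts only pairs the method itself aligned, so
#' it can never exceed [pairs_under()] at the same transform.
#'
#' @param al an [alignment].
#' @param a,b_hat structures or coordinate matrices (`b_hat` superposed).
#' @param d cutoff in Angstroms.
#' @return Integer count.
#' @export
numpairs <- function(al, a, b_hat, d) {
  if (alignment_length(al) == 0L) return(0L)
  A <- as_xyz(a); B <- as_xyz(b_hat)
  d2 <- rowSums((A[al$i, , drop = FALSE] - B[al$j, , drop = FALSE])^2)
  sum(d2 <= d^2)
}

#' Similarity Index (SI)
#'
#' `cRMS x min(L(a), L(b)) / Nmat` over the aligned pairs: balances the
#' tightness of the fit against its coverage; lower is better. Undefined
#' (error) for an empty alignment.
#'
#' @inheritParams numpairs
#' @return Nonnegative scalar.
#' @export
similarity_index <- function(al, a, b_hat) {
  k <- alignment_length(al)
  if (k == 0L) stop("similarity_index is undefined for an empty alignment")
  A <- as_xyz(a); B <- as_xyz(b_hat)
  cr <- crms(A[al$i, , drop = FALSE], B[al$j, , drop = FALSE])
  cr * min(nrow(A), nrow(B)) / k
}

#' Percentage of structural similarity PSI(d)
#'
#' `NumPairs(d) / min(L(a), L(b))`: the fraction of the shorter protein
#' aligned within `d` Angstroms; in `[0, 1]`, empty alignments give 0.
#'
#' @inheritParams numpairs
#' @return Scalar in `[0, 1]`.
#' @export
psi <- function(al, a, b_hat, d) {
  numpairs(al, a, b_hat, d) / min(nrow(as_xyz(a)), nrow(as_xyz(b_hat)))
}

#' Shift-tolerant agreement with a reference alignment
#'
#' For each shift tolerance `s = 0..s_max`, computes `I_s / L_ref` where
#' `I_s` is the number of test pairs `(i, j)` whose `a`-side residue the
#' reference aligns to some `j'` with `|j - j'| <= s`, and `L_ref` is the
#' reference length. `s = 0` is exact agreement (the percentage of
#' correctly aligned residue pairs); test pairs whose `a` residue is
#' absent from the reference never count. Undefined for an empty
#' reference.
#'
#' @param test an [alignment] to evaluate.
#' @param ref the reference alignment (same structure pair, same residue
#'   order).
#' @param s_max largest shift tolerance.
#' @return A data frame of class `agreement_curve` with columns `s` and
#'   `agreement` (nondecreasing in `s`, values in `[0, 1]`).
#' @export
shift_agreement <- function(test, ref, s_max = 5L) {
  l_ref <- alignment_length(ref)
  if (l_ref == 0L) stop("shift agreement is undefined for an empty reference")
  ref_j <- setNames(ref$j, ref$i)
  partner <- ref_j[as.character(test$i)]      # NA where i not in reference
  shift <- abs(test$j - partner)
  agreement <- vapply(0:s_max,
                      function(s) sum(shift <= s, na.rm = TRUE) / l_ref,
                      numeric(1))
  structure(data.frame(s = 0:s_max, agreement = agreement),
            class = c("agreement_curve", "data.frame"))
}

#' Full quality report for one alignment
#'
#' Bundles the quality measures of a method's alignment under a given
#' superposition: `nmat` (aligned pairs), `crms_aligned`, `numpairs_d`,
#' `psi_d`, `si`, the chain lengths and the cutoff.
#'
#' @param al an [alignment].
#' @param a,b structures (untransformed `b`).
#' @param tr the superposition of `b` onto `a` the alignment lives on.
#' @param d cutoff in Angstroms.
#' @return A one-row data frame.
#' @export
quality_report <- function(al, a, b, tr, d = 3) {
  b_hat <- apply_transform(tr, b)
  k <- alignment_length(al)
  data.frame(
    nmat = k,
    crms_aligned = if (k) crms(a$xyz[al$i, , drop = FALSE],
                               b_hat$xyz[al$j, , drop = FALSE]) else NA_real_,
    numpairs_d = numpairs(al, a, b_hat, d),
    psi_d = psi(al, a, b_hat, d),
    si = if (k) similarity_index(al, a, b_hat) else NA_real_,
    len_a = nres(a), len_b = nres(b), d = d)
}
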