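#' Fragment-pair seed superpositions
#'
#' Initial transforms for the iterative aligners and the deep search:
#' every length-`k` fragment of `a` (at stride `stride`) is least-squares
#' superposed onto every length-`k` fragment of `b`, and the resulting
#' transforms are deduplicated by rotation-and-translation distance. The
#' order is deterministic (fragment start positions ascending), standing
#' in for each published method's own (unpublished) initial-superposition
#' heuristics.
#'
#' @param a,b structures ([structure3d]).
#' @param k fragment length (residues).
#' @param stride fragment start stride.
#' @param dedup_angle,dedup_trans a new seed within this rotation angle
#'   (degrees) and translation distance (Angstroms) of a kept seed is
#'   dropped.
#' @return A list of [rigid_transform]s.
#' @export
seed_superpositions <- function(a, b, k = 8L, stride = 4L, dedup_angle = 5,
                                dedup_trans = 2) {
  m <- nres(a); n <- nres(b)
  stopifnot(m >= k, n >= k)
  ia <- seq(1L, m - k + 1L, by = stride)
  jb <- seq(1L, n - k + 1L, by = stride)
  seeds <- list()
  qs <- matrix(numeric(0), 0, 4)  # kept quaternions for fast dedup
  ts <- matrix(numeric(0), 0, 3)
  for (i in ia) {
    fa <- a$xyz[i:(i + k - 1L), , drop = FALSE]
    for (j in jb) {
      fb <- b$xyz[j:(j + k - 1L), , drop = FALSE]
      tr <- superpose_lsq(fa, fb)$transform
      if (nrow(qs)) {
        q <- rotation_to_quaternion(tr$rotation)
        ang <- 2 * acos(pmin(1, abs(qs %*% q))) * 180 / pi
        dt <- sqrt(rowSums(sweep(ts, 2, tr$translation)^2))
        if (any(ang < dedup_angle & dt < dedup_trans)) next
        qs <- rbind(qs, q)
      } else {
        qs <- rbind(qs, rotation_to_quaternion(tr$rotation))
      }
      ts <- rbind(ts, tr$translation)
      seeds[[length(seeds) + 1L]] <- tr
    }
  }
  seeds
}

# Shared iterative loop: recompute alignment under the current transform,
# re-superpose on the aligned pairs, stop when the pair list repeats
# (cycle guard via key hashing) or max_iter is reached.
iterate_alignment <- function(a, b, init, align_fun, max_iter = 100L) {
  tr <- init
  seen <- character(0)
  trace <- list()
  al <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    b_hat <- apply_transform(tr, b)
    al <- align_fun(a, b_hat)
    k <- alignment_length(al)
    cr <- if (k) crms(a$xyz[al$i, , drop = FALSE],
                      b_hat$xyz[al$j, , drop = FALSE]) else NA_real_
    trace[[it]] <- data.frame(iteration = it, k = k, score = al$score,
                              crms = cr)
    if (k == 0L) break
    key <- paste(al$i, al$j, collapse = ";")
    if (key %in% seen) { converged <- TRUE; break }
    seen <- c(seen, key)
    fit <- superpose_lsq(a$xyz[al$i, , drop = FALSE],
                         b$xyz[al$j, , drop = FALSE])
    tr <- fit$transform
  }
  list(alignment = al, transform = tr,
       trace = list(iterations = length(trace), converged = converged,
                    steps = do.call(rbind, trace)))
}

#' STRUCTAL-style iterative dynamic-programming alignment
#'
#' For each seed superposition, alternates (i) building the STRUCTAL score
#' matrix under the current superposition, (ii) linear-gap DP with penalty
#' `gap`, and (iii) least-squares superposition on the aligned pairs,
#' until the alignment repeats (cycle guard) or `max_iter` iterations.
#' The seed run with the highest final STRUCTAL total score wins.
#'
#' @param a,b structures (length >= 3).
#' @param seeds list of [rigid_transform] starting superpositions;
#'   defaults to [seed_superpositions()].
#' @param gap linear gap penalty per skipped position (10).
#' @param max_iter iteration cap per seed.
#' @return A list with `alignment`, `transform`, `score` (STRUCTAL total
#'   score of the returned alignment under `transform`), `trace` (of the
#'   winning seed) and `seeds_evaluated`; `alignment` is empty with
#'   `score = -Inf` replaced by an explicit `no_alignment = TRUE` flag if
#'   no seed yields any aligned pair.
#' @export
structal_align <- function(a, b, seeds = NULL, gap = 10, max_iter = 100L) {
  stopifnot(nres(a) >= 3L, nres(b) >= 3L)
  if (is.null(seeds)) seeds <- default_seeds(a, b)
  stopifnot(length(seeds) > 0L)
  align_fun <- function(a, b_hat)
    dp_linear(structal_score_matrix(a, b_hat), gap = gap,
              scheme = "structal")
  best <- NULL
  best_score <- -Inf
  for (s in seeds) {
    run <- iterate_alignment(a, b, s, align_fun, max_iter)
    if (alignment_length(run$alignment) == 0L) next
    sc <- structal_total_score(run$alignment, a,
                               apply_transform(run$transform, b), gap = gap)
    if (sc > best_score) { best_score <- sc; best <- run }
  }
  if (is.null(best))
    return(list(alignment = alignment(integer(0), integer(0), 0, "structal"),
                transform = transform_identity(), score = NA_real_,
                trace = NULL, seeds_evaluated = length(seeds),
                no_alignment = TRUE))
  list(alignment = best$alignment, transform = best$transform,
       score = best_score, trace = best$trace,
       seeds_evaluated = length(seeds), no_alignment = FALSE)
}

# Seeds at the default fragment length, shrunk for tiny chains.
default_seeds <- function(a, b, k = 8L, stride = 4L) {
  k <- min(k, nres(a), nres(b))
  stride <- max(1L, min(stride, nres(a) - k + 1L, nres(b) - k + 1L))
  seed_superpositions(a, b, k = k, stride = stride)
}

#' TM-align-style scoring alignment on a given superposition
#'
#' Applies `tr` to `b`, builds the TM-align score matrix with `d0` from
#' the shorter length, and runs affine-gap DP (0.6 open, 0.0 extend).
#' By default the superposition is *not* re-estimated, matching the
#' protocol of aligning on an externally supplied (e.g. deep-search)
#' superposition; `refine = TRUE` instead iterates alignment and
#' re-superposition from `tr` to convergence, for use as a stand-alone
#' aligner. The final transform and iteration trace are attached as
#' attributes `"transform"` and `"trace"`.
#'
#' @param a,b structures.
#' @param tr a [rigid_transform] superposing `b` onto `a`.
#' @param open,extend affine gap penalties.
#' @param refine iterate alignment/superposition instead of a single pass.
#' @param max_iter iteration cap when refining.
#' @return An [alignment] (scheme `"tmalign"`).
#' @export
tmscore_align <- function(a, b, tr, open = 0.6, extend = 0, refine = FALSE,
                          max_iter = 100L) {
  d0 <- tmalign_d0(min(nres(a), nres(b)))
  align_fun <- function(a, b_hat)
    dp_affine(tmalign_score_matrix(a, b_hat, d0), open = open,
              extend = extend, scheme = "tmalign")
  if (refine) {
    run <- iterate_alignment(a, b, tr, align_fun, max_iter)
    al <- run$alignment
    attr(al, "transform") <- run$transform
    attr(al, "trace") <- run$trace
    return(al)
  }
  al <- align_fun(a, apply_transform(tr, b))
  attr(al, "transform") <- tr
  al
}

# Mutual-nearest-neighbour residue pairs within d (unordered set).
# Ties between equidistant neighbours go to the lower index (which.min).
mutual_nn_pairs <- function(a, b_hat, d) {
  d2 <- dist2_matrix(a, b_hat)
  nn_b <- apply(d2, 1, which.min)   # nearest j for each i
  nn_a <- apply(d2, 2, which.min)   # nearest i for each j
  i <- which(nn_a[nn_b] == seq_along(nn_b) &
               d2[cbind(seq_along(nn_b), nn_b)] <= d^2)
  cbind(i = i, j = nn_b[i],
        dist = sqrt(d2[cbind(i, nn_b[i])]))
}

#' LOCK2-style iterative superposition refinement
#'
#' From an initial superposition, alternates collecting mutual-nearest-
#' neighbour residue pairs within `d` Angstroms and least-squares
#' superposition on them (the RMSD-minimization loop with a 3 Angstrom
#' atomic threshold), until the pair set stabilizes or `max_iter`.
#'
#' @param a,b structures.
#' @param init initial [rigid_transform].
#' @param d distance threshold in Angstroms (3).
#' @param max_iter iteration cap.
#' @return A list with `transform`, `trace` (iterations, converged,
#'   per-iteration pair count and cRMS) and `no_pairs` (`TRUE` if some
#'   iteration found no pairs within `d`; the last valid transform is
#'   returned).
#' @export
lock2_refine <- function(a, b, init, d = 3, max_iter = 100L) {
  tr <- init
  seen <- character(0)
  steps <- list()
  converged <- FALSE
  no_pairs <- FALSE
  for (it in seq_len(max_iter)) {
    b_hat <- apply_transform(tr, b)
    p <- mutual_nn_pairs(a, b_hat, d)
    if (nrow(p) == 0L) { no_pairs <- TRUE; break }
    cr <- crms(a$xyz[p[, "i"], , drop = FALSE],
               b_hat$xyz[p[, "j"], , drop = FALSE])
    steps[[it]] <- data.frame(iteration = it, k = nrow(p), score = nrow(p),
                              crms = cr)
    key <- paste(p[, "i"], p[, "j"], collapse = ";")
    if (key %in% seen) { converged <- TRUE; break }
    seen <- c(seen, key)
    tr <- superpose_lsq(a$xyz[p[, "i"], , drop = FALSE],
                        b$xyz[p[, "j"], , drop = FALSE])$transform
  }
  list(transform = tr,
       trace = list(iterations = length(steps), converged = converged,
                    steps = do.call(rbind, steps)),
       no_pairs = no_pairs)
}

#' LOCK2-style final nearest-neighbour alignment
#'
#' Step 1 collects all residue pairs `(i, j)` that are each other's
#' nearest neighbours at distance <= `d` under the given superposition;
#' step 2 keeps the maximum-cardinality subset that is strictly
#' increasing in both indices (colinearity in the sequential-order sense:
#' crossing matches are removed by a longest-increasing-subsequence DP,
#' ties broken by smaller total distance).
#'
#' @param a,b_hat structures (`b_hat` already superposed).
#' @param d distance threshold in Angstroms (3).
#' @return An [alignment] (scheme `"lock2"`, score = pair count); may be
#'   empty.
#' @export
lock2_final_alignment <- function(a, b_hat, d = 3) {
  p <- mutual_nn_pairs(a, b_hat, d)
  if (nrow(p) == 0L)
    return(alignment(integer(0), integer(0), 0, "lock2"))
  # mutual NN implies distinct i and distinct j; sort by i, then LIS in j
  p <- p[order(p[, "i"]), , drop = FALSE]
  np <- nrow(p)
  len <- integer(np); tot <- numeric(np); prev <- integer(np)
  for (u in seq_len(np)) {
    len[u] <- 1L; tot[u] <- p[u, "dist"]; prev[u] <- 0L
    for (v in seq_len(u - 1L)) {
      if (p[v, "j"] < p[u, "j"]) {
        cand_len <- len[v] + 1L
        cand_tot <- tot[v] + p[u, "dist"]
        if (cand_len > len[u] ||
            (cand_len == len[u] && cand_tot < tot[u])) {
          len[u] <- cand_len; tot[u] <- cand_tot; prev[u] <- v
        }
      }
    }
  }
  ends <- which(len == max(len))
  best <- ends[which.min(tot[ends])]
  idx <- integer(0)
  u <- best
  while (u > 0L) { idx <- c(u, idx); u <- prev[u] }
  alignment(p[idx, "i"], p[idx, "j"], score = length(idx), scheme = "lock2")
}

#' LOCK2-style aligner from seed superpositions
#'
#' Convenience wrapper running [lock2_refine()] from each seed and
#' [lock2_final_alignment()] on the refined superposition; the seed whose
#' final alignment has the most pairs (ties: lower cRMS over the aligned
#' pairs) wins.
#'
#' @inheritParams structal_align
#' @param d distance threshold in Angstroms.
#' @return As [structal_align()]: list with `alignment`, `transform`,
#'   `score` (pair count), `trace`, `seeds_evaluated`, `no_alignment`.
#' @export
lock2_align <- function(a, b, seeds = NULL, d = 3, max_iter = 100L) {
  if (is.null(seeds)) seeds <- default_seeds(a, b)
  stopifnot(length(seeds) > 0L)
  best <- NULL; best_k <- -1L; best_cr <- Inf
  for (s in seeds) {
    rf <- lock2_refine(a, b, s, d = d, max_iter = max_iter)
    b_hat <- apply_transform(rf$transform, b)
    al <- lock2_final_alignment(a, b_hat, d = d)
    k <- alignment_length(al)
    if (k == 0L) next
    cr <- crms(a$xyz[al$i, , drop = FALSE], b_hat$xyz[al$j, , drop = FALSE])
    if (k > best_k || (k == best_k && cr < best_cr)) {
      best <- list(alignment = al, transform = rf$transform,
                   trace = rf$trace)
      best_k <- k; best_cr <- cr
    }
  }
  if (is.null(best))
    return(list(alignment = alignment(integer(0), integer(0), 0, "lock2"),
                transform = transform_identity(), score = NA_real_,
                trace = NULL, seeds_evaluated = length(seeds),
                no_alignment = TRUE))
  list(alignment = best$alignment, transform = best$transform,
       score = best_k, trace = best$trace, seeds_evaluated = length(seeds),
       no_alignment = FALSE)
}
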