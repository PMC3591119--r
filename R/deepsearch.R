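#' Deep-search parameters
#'
#' Settings of the superposition-space search: the distance cutoff `d`
#' (default 3 Angstroms) and accuracy slack `epsilon` (default 1
#' Angstrom) follow the study conditions `d = 3`, `epsilon = 1`; going
#' below `epsilon = 1` buys little and costs much. Fragment lengths and
#' stride control the seed set; `budget` caps the number of seeds
#' evaluated; `rng_seed` is reserved for optional randomized restarts
#' (the default search is fully deterministic and does not consume
#' randomness).
#'
#' @param d distance cutoff in Angstroms.
#' @param epsilon annealing slack in Angstroms (`>= 0`).
#' @param fragment_lengths fragment lengths used for seeding.
#' @param stride fragment start stride.
#' @param refine_iterations cap on alternation steps per refinement pass.
#' @param budget maximum number of seeds evaluated.
#' @param top_refine how many best seeds get the `d + epsilon` annealing
#'   pass.
#' @param rng_seed integer, reserved for randomized restarts.
#' @return A list of class `search_params`.
#' @export
search_params <- function(d = 3, epsilon = 1, fragment_lengths = c(6L, 12L),
                          stride = 4L, refine_iterations = 32L,
                          budget = Inf, top_refine = 8L, rng_seed = 1L) {
  stopifnot(d > 0, epsilon >= 0, all(fragment_lengths >= 3L), stride >= 1L)
  structure(list(d = d, epsilon = epsilon,
                 fragment_lengths = as.integer(fragment_lengths),
                 stride = as.integer(stride),
                 refine_iterations = as.integer(refine_iterations),
                 budget = budget, top_refine = as.integer(top_refine),
                 rng_seed = as.integer(rng_seed)),
            class = "search_params")
}

# One refinement pass: alternate threshold-DP matching and least-squares
# superposition on the matched pairs from a starting transform, tracking
# the best (count, then cRMS) state visited at cutoff `dcut`.
refine_threshold <- function(a, b, tr, dcut, iters) {
  best <- NULL
  seen <- character(0)
  for (it in seq_len(iters)) {
    b_hat <- apply_transform(tr, b)
    al <- numpairs_dp(a, b_hat, dcut)
    k <- alignment_length(al)
    cr <- if (k) crms(a$xyz[al$i, , drop = FALSE],
                      b_hat$xyz[al$j, , drop = FALSE]) else Inf
    if (is.null(best) || k > best$count ||
        (k == best$count && cr < best$crms))
      best <- list(transform = tr, count = k, crms = cr, alignment = al)
    if (k < 3L) break
    key <- paste(al$i, al$j, collapse = ";")
    if (key %in% seen) break
    seen <- c(seen, key)
    tr <- superpose_lsq(a$xyz[al$i, , drop = FALSE],
                        b$xyz[al$j, , drop = FALSE])$transform
  }
  best
}

#' Deep search of superposition space for the CA <= d measure
#'
#' Searches rigid superpositions of `b` onto `a` for the one that
#' maximizes the number of residue pairs matchable in sequential order
#' within `d` Angstroms (the CA <= d measure). The search enumerates
#' fragment-pair seed superpositions at several fragment lengths, refines
#' each by alternating threshold-DP matching with least-squares
#' superposition on the matched pairs, then anneals the best seeds by
#' refining at the relaxed cutoff `d + epsilon` before tightening back to
#' `d`. Ties between equal-count transforms go to the lower cRMS of the
#' matched set. Deterministic given `params`.
#'
#' @param a,b structures (length >= 3).
#' @param params a [search_params()] list.
#' @return A list of class `maxpairs_result`: `transform`,
#'   `pairs_under_d` (recomputed under `transform`), `alignment`,
#'   `seeds_evaluated`, `trace` (per-seed best counts), `truncated`
#'   (budget exhausted).
#' @export
maxpairs_search <- function(a, b, params = search_params()) {
  stopifnot(inherits(params, "search_params"), nres(a) >= 3L, nres(b) >= 3L)
  d <- params$d
  nmin <- min(nres(a), nres(b))
  fl <- unique(pmin(params$fragment_lengths, nmin))
  stride <- params$stride
  if (nmin <= 15L) {  # tiny chains: denser seeding
    fl <- sort(unique(c(fl, 3L, 4L)))
    stride <- 1L
  }
  seeds <- list()
  for (k in fl)
    seeds <- c(seeds, seed_superpositions(a, b, k = k, stride = stride))
  truncated <- FALSE
  if (length(seeds) > params$budget) {
    seeds <- seeds[seq_len(params$budget)]
    truncated <- TRUE
  }
  states <- vector("list", length(seeds))
  counts <- integer(length(seeds))
  for (s in seq_along(seeds)) {
    st <- refine_threshold(a, b, seeds[[s]], d, params$refine_iterations)
    states[[s]] <- st
    counts[s] <- st$count
  }
  pick_best <- function(cand, best) {
    if (is.null(best) || cand$count > best$count ||
        (cand$count == best$count && cand$crms < best$crms)) cand else best
  }
  best <- NULL
  for (st in states) best <- pick_best(st, best)
  # d + epsilon annealing of the most promising seeds
  top <- order(-counts)[seq_len(min(params$top_refine, length(states)))]
  if (params$epsilon > 0) {
    for (s in top) {
      relaxed <- refine_threshold(a, b, states[[s]]$transform,
                                  d + params$epsilon,
                                  params$refine_iterations)
      tightened <- refine_threshold(a, b, relaxed$transform, d,
                                    params$refine_iterations)
      best <- pick_best(tightened, best)
    }
  }
  structure(list(transform = best$transform,
                 pairs_under_d = pairs_under(a, b, best$transform, d),
                 alignment = best$alignment,
                 seeds_evaluated = length(seeds),
                 trace = data.frame(seed = seq_along(seeds),
                                    count = counts),
                 truncated = truncated),
            class = "maxpairs_result")
}

#' @export
print.maxpairs_result <- function(x, ...) {
  cat(sprintf(
    "maxpairs_result: %d pairs under cutoff (%d seeds evaluated%s)\n",
    x$pairs_under_d, x$seeds_evaluated,
    if (x$truncated) ", budget truncated" else ""))
  invisible(x)
}

#' Exhaustive grid oracle for the CA <= d measure
#'
#' Toy-scale exhaustive scan of superposition space: a zyz-Euler rotation
#' grid at `angular_step` crossed with a cubic translation grid at
#' `translation_step` covering the displacement bounding box (padded by
#' `d`), each candidate scored by the threshold-pair DP. Because the grid
#' is discrete, the guarantee is stated via a computed worst-case
#' displacement bound `delta`: the best grid count at cutoff `d + delta`
#' is at least the true optimum at `d` (any superposition can be moved to
#' a grid point displacing no atom by more than `delta`). Restricted to
#' chains of at most 12 residues.
#'
#' @param a,b structures.
#' @param d cutoff in Angstroms.
#' @param angular_step rotation grid step (degrees).
#' @param translation_step translation grid step (Angstroms).
#' @param certify also scan at cutoff `d + delta` to produce the
#'   upper-bound certificate (roughly doubles the, already substantial,
#'   cost; `count_upper` is `NA` when `FALSE`).
#' @return A list with `count` (best grid count at cutoff `d`),
#'   `count_upper` (best grid count at `d + delta`, an upper-bound
#'   certificate for the optimum at `d`), `delta`, `transform` (best
#'   transform at cutoff `d`), `evaluated` (superpositions scored).
#' @export
grid_oracle <- function(a, b, d = 3, angular_step = 30,
                        translation_step = 1.5, certify = TRUE) {
  if (max(nres(a), nres(b)) > 12L)
    stop("grid_oracle is an exhaustive toy-scale scan; chains must have ",
         "at most 12 residues")
  A <- as_xyz(a); B <- as_xyz(b)
  rots <- euler_rotation_grid(angular_step)
  # worst-case displacement of any b atom between a superposition and its
  # nearest grid point: three Euler offsets of at most step/2 compose to a
  # rotation of angle <= 1.5 * step, acting at radius r_max, plus the
  # translation cell half-diagonal.
  cb <- colMeans(B)
  r_max <- sqrt(max(rowSums(sweep(B, 2, cb)^2)))
  ang <- min(pi, 1.5 * angular_step * pi / 180)
  delta <- 2 * sin(ang / 2) * r_max + sqrt(3) / 2 * translation_step
  scan <- function(cutoff) {
    r <- .grid_scan_cpp(A, B, rots, translation_step, cutoff, cutoff)
    R <- matrix(rots[r$rot_index, ], 3, 3, byrow = TRUE)
    list(count = r$count,
         transform = rigid_transform(
           R, r$translation - as.numeric(R %*% r$centroid_b)),
         evaluated = r$evaluated)
  }
  at_d <- scan(d)
  upper <- if (certify) scan(d + delta) else list(count = NA_integer_,
                                                  evaluated = 0)
  list(count = at_d$count, count_upper = upper$count, delta = delta,
       transform = at_d$transform,
       evaluated = at_d$evaluated + upper$evaluated)
}

#' Alignment-independent pair count under a transform
#'
#' The maximum number of residue pairs matchable in sequential order
#' within `d` Angstroms after applying `tr` to `b`: the quantity the deep
#' search maximizes, and the alignment-independent ceiling against which
#' method-specific NumPairs counts are compared.
#'
#' @param a,b structures.
#' @param tr a [rigid_transform].
#' @param d cutoff in Angstroms.
#' @return Integer pair count.
#' @export
pairs_under <- function(a, b, tr, d) {
  alignment_length(numpairs_dp(a, apply_transform(tr, b), d))
}
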