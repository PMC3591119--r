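test_that("fragment seeding covers the identity for identical structures", {
  s <- make_chain(30, "mixed", rng_seed = 51)
  seeds <- seed_superpositions(s, s)
  angs <- vapply(seeds, function(tr)
    rotation_angle(tr$rotation) + sqrt(sum(tr$translation^2)), numeric(1))
  expect_lt(min(angs), 1e-5)
})

test_that("seed count is bounded by the fragment-pair combinatorics", {
  a <- make_chain(33, "mixed", rng_seed = 52)
  b <- make_chain(21, "random_walk", rng_seed = 53)
  seeds <- seed_superpositions(a, b, k = 8, stride = 4)
  expect_lte(length(seeds), ceiling(33 / 4) * ceiling(21 / 4))
})

test_that("some seed lands near the planted transform of a synthetic pair", {
  for (seed in c(4, 14)) {
    p <- make_pair(n = 50, noise_sigma = 0, overlap_fraction = 1,
                   rng_seed = seed)
    seeds <- seed_superpositions(p$a, p$b)
    angs <- vapply(seeds, rotation_distance, numeric(1), r2 = p$transform)
    expect_lt(min(angs), 10)
  }
})

test_that("STRUCTAL aligns a rigid copy onto itself exactly", {
  p <- make_pair(n = 40, noise_sigma = 0, overlap_fraction = 1, rng_seed = 54)
  r <- structal_align(p$a, p$b, seeds = list(p$transform))
  expect_equal(alignment_length(r$alignment), 40L)
  b_hat <- apply_transform(r$transform, p$b)
  expect_lt(crms(p$a$xyz[r$alignment$i, ], b_hat$xyz[r$alignment$j, ]), 1e-6)
})

test_that("STRUCTAL recovers a full alignment from noisy copies at the noise scale", {
  p <- make_pair(n = 60, noise_sigma = 1, overlap_fraction = 1, rng_seed = 6)
  r <- structal_align(p$a, p$b)
  expect_gte(alignment_length(r$alignment), 57L)  # essentially all residues
  b_hat <- apply_transform(r$transform, p$b)
  cr <- crms(p$a$xyz[r$alignment$i, ], b_hat$xyz[r$alignment$j, ])
  expect_equal(cr, sqrt(3), tolerance = 0.2)  # 3 noisy coordinates per atom
})

test_that("STRUCTAL's reported score is the total score of its own output", {
  p <- make_pair(n = 40, noise_sigma = 0.8, overlap_fraction = 0.8,
                 rng_seed = 55)
  r <- structal_align(p$a, p$b)
  expect_equal(r$score,
               structal_total_score(r$alignment, p$a,
                                    apply_transform(r$transform, p$b)),
               tolerance = 1e-9)
  expect_gte(r$trace$iterations, 1L)
})

test_that("multi-seed STRUCTAL never scores below a single-seed run", {
  p <- make_pair(n = 40, noise_sigma = 0.5, overlap_fraction = 0.7,
                 rng_seed = 56)
  seeds <- seed_superpositions(p$a, p$b)
  all_seeds <- structal_align(p$a, p$b, seeds = seeds)
  one_seed <- structal_align(p$a, p$b, seeds = seeds[1])
  expect_gte(all_seeds$score, one_seed$score)
})

test_that("TM-style alignment of identical structures is full length and self-consistent", {
  s <- make_chain(35, "mixed", rng_seed = 57)
  al <- tmscore_align(s, s, transform_identity())
  expect_equal(alignment_length(al), 35L)
  d0 <- tmalign_d0(35)
  Smat <- tmalign_score_matrix(s, s, d0)
  runs <- sum(diff(al$i) > 1) + sum(diff(al$j) > 1)
  expect_equal(al$score, sum(Smat[cbind(al$i, al$j)]) - 0.6 * runs,
               tolerance = 1e-9)
})

test_that("TM-style score is invariant under conjugation by a common rigid motion", {
  set.seed(58)
  p <- make_pair(n = 30, noise_sigma = 0.6, overlap_fraction = 0.7,
                 rng_seed = 58)
  tr <- p$transform
  al0 <- tmscore_align(p$a, p$b, tr)
  q <- rand_transform()
  a2 <- apply_transform(q, p$a)
  b2 <- apply_transform(q, p$b)
  tr2 <- transform_compose(q, transform_compose(tr, transform_inverse(q)))
  al1 <- tmscore_align(a2, b2, tr2)
  expect_equal(al1$score, al0$score, tolerance = 1e-9)
  expect_equal(al1$i, al0$i)
})

test_that("LOCK2 refinement converges immediately on an already-optimal start", {
  s <- make_chain(30, "mixed", rng_seed = 59)
  rf <- lock2_refine(s, s, transform_identity())
  expect_true(rf$trace$converged)
  expect_lte(rf$trace$iterations, 2L)
  expect_equal(rf$trace$steps$k[1], 30L)
  expect_false(rf$no_pairs)
})

test_that("LOCK2 refinement pulls a tilted start back to the planted transform", {
  p <- make_pair(n = 50, noise_sigma = 0, overlap_fraction = 1, rng_seed = 8)
  tilt <- rigid_transform(axis_rotation(c(0, 0, 1), 5), c(0.3, 0, 0))
  rf <- lock2_refine(p$a, p$b, transform_compose(tilt, p$transform), d = 3)
  expect_lt(rotation_distance(rf$transform, p$transform), 1)
  expect_true(rf$trace$converged)
})

test_that("LOCK2 refinement stops cleanly when no pairs fall within d", {
  a <- make_chain(10, "helix")
  b <- structure3d(a$xyz + 500)
  rf <- lock2_refine(a, b, transform_identity(), d = 3)
  expect_true(rf$no_pairs)
  expect_equal(rf$transform$rotation, diag(3))
})

test_that("LOCK2 final alignment keeps all pairs for identical structures", {
  s <- make_chain(25, "mixed", rng_seed = 60)
  al <- lock2_final_alignment(s, s, d = 3)
  expect_equal(alignment_length(al), 25L)
  expect_equal(al$i, al$j)
})

test_that("colinearity filtering removes crossing nearest-neighbour pairs", {
  a <- structure3d(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
  b <- structure3d(rbind(c(3.8, 0.1, 0), c(0, 0.1, 0), c(7.6, 0.1, 0)))
  # mutual NN pairs are (1,2), (2,1), (3,3): only two can be sequential
  al <- lock2_final_alignment(a, b, d = 3)
  expect_equal(alignment_length(al), 2L)
  expect_true(3L %in% al$i && 3L %in% al$j)
  expect_true(all(diff(al$i) > 0) && all(diff(al$j) > 0))
})

test_that("LOCK2 final alignment is empty beyond the distance threshold", {
  a <- make_chain(10, "helix")
  expect_equal(alignment_length(
    lock2_final_alignment(a, structure3d(a$xyz + 50), d = 3)), 0L)
})

test_that("LOCK2 output pairs are mutual nearest neighbours within d", {
  p <- make_pair(n = 40, noise_sigma = 0.8, overlap_fraction = 0.7,
                 rng_seed = 61)
  b_hat <- apply_transform(p$transform, p$b)
  al <- lock2_final_alignment(p$a, b_hat, d = 3)
  mnn <- deepalign:::mutual_nn_pairs(p$a, b_hat, 3)
  key <- paste(mnn[, "i"], mnn[, "j"])
  expect_true(all(paste(al$i, al$j) %in% key))
  expect_true(all(diff(al$i) > 0) && all(diff(al$j) > 0))
})
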