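test_that("deep search fits every residue of a rigid copy", {
  p <- make_pair(n = 40, noise_sigma = 0, overlap_fraction = 1, rng_seed = 71)
  sr <- maxpairs_search(p$a, p$b, search_params(d = 1))
  expect_equal(sr$pairs_under_d, 40L)
  expect_s3_class(sr, "maxpairs_result")
})

test_that("deep search is deterministic given identical parameters", {
  p <- make_pair(n = 40, noise_sigma = 0.6, overlap_fraction = 0.7,
                 rng_seed = 72)
  s1 <- maxpairs_search(p$a, p$b)
  s2 <- maxpairs_search(p$a, p$b)
  expect_identical(s1$pairs_under_d, s2$pairs_under_d)
  expect_equal(s1$transform$rotation, s2$transform$rotation)
  expect_equal(s1$transform$translation, s2$transform$translation)
  expect_identical(s1$trace, s2$trace)
})

test_that("deep search never returns fewer pairs than its best unrefined seed", {
  p <- make_pair(n = 40, noise_sigma = 0.6, overlap_fraction = 0.6,
                 rng_seed = 73)
  sr <- maxpairs_search(p$a, p$b)
  expect_gte(sr$pairs_under_d, max(sr$trace$count))
  expect_equal(sr$pairs_under_d,
               pairs_under(p$a, p$b, sr$transform, 3))
  expect_equal(alignment_length(sr$alignment), sr$pairs_under_d)
})

test_that("deep-search counts are invariant under a common rigid motion", {
  set.seed(74)
  p <- make_pair(n = 35, noise_sigma = 0.5, overlap_fraction = 0.8,
                 rng_seed = 74)
  base <- maxpairs_search(p$a, p$b)
  q <- rand_transform()
  moved <- maxpairs_search(apply_transform(q, p$a), apply_transform(q, p$b))
  expect_equal(moved$pairs_under_d, base$pairs_under_d)
})

test_that("deep search meets the planted-overlap certificate", {
  for (seed in c(5, 15)) {
    p <- make_pair(n = 60, noise_sigma = 0.5, overlap_fraction = 0.6,
                   rng_seed = seed)
    expect_true(check_certificate(p)$ok)
    sr <- maxpairs_search(p$a, p$b)
    expect_gte(sr$pairs_under_d, ceiling(0.6 * nres(p$b)))
  }
})

test_that("seed budgets truncate deterministically and are flagged", {
  p <- make_pair(n = 40, noise_sigma = 0.5, overlap_fraction = 0.8,
                 rng_seed = 75)
  sr <- maxpairs_search(p$a, p$b, search_params(budget = 10))
  expect_true(sr$truncated)
  expect_equal(sr$seeds_evaluated, 10L)
  expect_gte(sr$pairs_under_d, max(sr$trace$count))
})

test_that("the grid oracle fits identical toys fully and guards its size", {
  a <- make_chain(4, "helix")
  go <- grid_oracle(a, a, d = 3, angular_step = 45, translation_step = 1.5,
                    certify = FALSE)
  expect_equal(go$count, 4L)
  expect_error(grid_oracle(make_chain(13, "helix"), a), "12 residues")
})

test_that("refining the rotation grid never loses pairs (nested steps)", {
  a <- make_chain(5, "random_walk", rng_seed = 76)
  b <- make_chain(5, "random_walk", rng_seed = 77)
  coarse <- grid_oracle(a, b, d = 3, angular_step = 60,
                        translation_step = 2, certify = FALSE)
  fine <- grid_oracle(a, b, d = 3, angular_step = 30,
                      translation_step = 2, certify = FALSE)
  expect_gte(fine$count, coarse$count)
})

test_that("deep search is sandwiched by the grid oracle's certificates", {
  for (seed in c(78, 79)) {
    a <- make_chain(6, "random_walk", rng_seed = seed)
    b <- make_pair(n = 6, kind = "random_walk", noise_sigma = 0.3,
                   overlap_fraction = 1, rng_seed = seed)$b
    go <- grid_oracle(a, b, d = 3, angular_step = 45, translation_step = 2,
                      certify = TRUE)
    sr <- maxpairs_search(a, b)
    # the grid's best transform is feasible, so the search should match it;
    # the relaxed-cutoff scan upper-bounds any superposition at d
    expect_gte(sr$pairs_under_d, go$count)
    expect_lte(sr$pairs_under_d, go$count_upper)
    expect_gt(go$delta, 0)
  }
})

test_that("pairs_under agrees with the threshold DP it wraps", {
  p <- make_pair(n = 30, noise_sigma = 0.4, overlap_fraction = 0.8,
                 rng_seed = 80)
  tr <- p$transform
  al <- numpairs_dp(p$a, apply_transform(tr, p$b), 3)
  expect_equal(pairs_under(p$a, p$b, tr, 3), alignment_length(al))
  far <- rigid_transform(diag(3), c(1000, 0, 0))
  expect_equal(pairs_under(p$a, p$b, far, 3), 0L)
})

test_that("search parameters validate their domains", {
  expect_error(search_params(d = -1))
  expect_error(search_params(epsilon = -0.5))
  expect_silent(search_params(epsilon = 0))
})
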