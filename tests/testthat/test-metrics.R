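test_that("NumPairs counts aligned pairs within the cutoff", {
  a <- structure3d(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  b <- structure3d(rbind(c(1, 0, 0), c(12.5, 0, 0), c(23.5, 0, 0)))
  al <- alignment(1:3, 1:3)  # pair distances 1, 2.5, 3.5
  expect_equal(numpairs(al, a, b, 3), 2)
  expect_equal(numpairs(al, a, b, 0.5), 0)
  expect_equal(numpairs(al, a, a, 1), 3)
  expect_equal(numpairs(alignment(integer(0), integer(0)), a, b, 3), 0L)
})

test_that("the Similarity Index reproduces its worked value", {
  h <- make_chain(100, "helix")
  b <- h
  b$xyz[1:50, 1] <- b$xyz[1:50, 1] + 2   # 50 aligned pairs at 2 A
  al <- alignment(1:50, 1:50)
  expect_equal(similarity_index(al, h, b), 2 * 100 / 50)  # = 4.0
  expect_equal(similarity_index(alignment(1:100, 1:100), h, h), 0)
  expect_error(similarity_index(alignment(integer(0), integer(0)), h, b),
               "empty")
})

test_that("doubling the aligned count at fixed cRMS halves the SI", {
  h <- make_chain(100, "helix")
  b <- h
  b$xyz[, 1] <- b$xyz[, 1] + 2
  expect_equal(similarity_index(alignment(1:50, 1:50), h, b),
               2 * similarity_index(alignment(1:100, 1:100), h, b))
})

test_that("SI scales linearly under uniform coordinate scaling", {
  p <- make_pair(n = 30, noise_sigma = 0.5, overlap_fraction = 1,
                 rng_seed = 91)
  b_hat <- apply_transform(p$transform, p$b)
  al <- numpairs_dp(p$a, b_hat, 3)
  s1 <- similarity_index(al, p$a, b_hat)
  a2 <- structure3d(2 * p$a$xyz)
  b2 <- structure3d(2 * b_hat$xyz)
  expect_equal(similarity_index(al, a2, b2), 2 * s1, tolerance = 1e-9)
})

test_that("PSI is the fraction of the shorter chain matched within d", {
  a <- make_chain(60, "helix")
  b <- make_chain(80, "helix")
  al <- alignment(1:30, 1:30)
  expect_equal(psi(al, a, b, 3), 30 / 60)
  expect_equal(psi(alignment(1:60, 1:60), a, a, 1), 1.0)
  expect_equal(psi(alignment(integer(0), integer(0)), a, b, 3), 0)
})

test_that("shift agreement is exact for a self-reference and shifts as built", {
  ref <- alignment(1:10, 1:10, scheme = "reference")
  self <- shift_agreement(alignment(1:10, 1:10), ref, s_max = 2)
  expect_equal(self$agreement[self$s == 0], 1.0)
  shifted <- shift_agreement(alignment(1:9, 2:10), ref, s_max = 2)
  expect_equal(shifted$agreement[shifted$s == 0], 0.0)
  expect_equal(shifted$agreement[shifted$s == 1], 0.9)  # 9 of 10 ref pairs
  expect_error(shift_agreement(ref, alignment(integer(0), integer(0))),
               "empty reference")
})

test_that("shift agreement matches a direct pair-by-pair count", {
  set.seed(92)
  for (rep in 1:25) {
    test <- rand_monotone_alignment(10, 12)
    ref <- rand_monotone_alignment(10, 12)
    curve <- shift_agreement(test, ref, s_max = 4)
    for (s in 0:4) {
      direct <- 0L
      for (r in seq_along(test$i)) {
        hit <- which(ref$i == test$i[r])
        if (length(hit) && abs(test$j[r] - ref$j[hit]) <= s)
          direct <- direct + 1L
      }
      expect_equal(curve$agreement[curve$s == s],
                   direct / alignment_length(ref))
    }
    expect_true(all(diff(curve$agreement) >= 0))
    expect_true(all(curve$agreement >= 0 & curve$agreement <= 1))
  }
})

test_that("quality reports satisfy their internal identities", {
  p <- make_pair(n = 40, noise_sigma = 0.7, overlap_fraction = 0.8,
                 rng_seed = 93)
  b_hat <- apply_transform(p$transform, p$b)
  al <- numpairs_dp(p$a, b_hat, 3)
  qr <- quality_report(al, p$a, p$b, p$transform, d = 3)
  expect_equal(qr$psi_d, qr$numpairs_d / min(qr$len_a, qr$len_b))
  expect_lte(qr$numpairs_d, qr$nmat)
  expect_equal(qr$nmat, alignment_length(al))
  expect_equal(qr$si, similarity_index(al, p$a, b_hat), tolerance = 1e-12)
})

test_that("method-specific NumPairs never exceeds the alignment-independent count", {
  p <- make_pair(n = 40, noise_sigma = 0.8, overlap_fraction = 0.7,
                 rng_seed = 94)
  sr <- maxpairs_search(p$a, p$b)
  b_hat <- apply_transform(sr$transform, p$b)
  ceiling_count <- pairs_under(p$a, p$b, sr$transform, 3)
  for (al in list(
    dp_linear(structal_score_matrix(p$a, b_hat), 10),
    tmscore_align(p$a, p$b, sr$transform),
    lock2_final_alignment(p$a, b_hat, 3))) {
    expect_lte(numpairs(al, p$a, b_hat, 3), ceiling_count)
  }
})
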