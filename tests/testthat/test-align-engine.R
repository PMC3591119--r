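test_that("score matrices match their closed forms and monotonicity", {
  a <- structure3d(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  b <- structure3d(rbind(c(0, 0, 0), c(sqrt(5), 0, 0), c(40, 0, 0)))
  S <- structal_score_matrix(a, b)
  expect_equal(S[1, 1], 20)           # distance 0
  expect_equal(S[1, 2], 10)           # distance sqrt(5)
  expect_true(all(diff(S[1, ]) < 0))  # strictly decreasing in distance
  expect_true(all(S > 0 & S <= 20))
  d0 <- 4.4
  Tm <- tmalign_score_matrix(a, structure3d(rbind(c(0, 0, 0), c(d0, 0, 0))),
                             d0 = d0)
  expect_equal(Tm[1, 1], 1)
  expect_equal(Tm[1, 2], 0.5)         # distance d0 scores one half
  expect_true(all(Tm > 0 & Tm <= 1))
})

test_that("tmalign_d0 matches the published closed form and short-chain floor", {
  expect_equal(tmalign_d0(140), 4.4)
  expect_equal(tmalign_d0(42), 1.92)
  expect_equal(tmalign_d0(15), 0.5)
  expect_equal(tmalign_d0(3), 0.5)
  expect_equal(tmalign_d0(18), 0.5)   # raw formula still negative here
  expect_equal(tmalign_d0(21), 0.5)   # raw positive but below the floor
  expect_gt(tmalign_d0(22), 0.5)
})

test_that("linear-gap DP handles trivial instances", {
  al <- dp_linear(matrix(7, 1, 1), gap = 10)
  expect_equal(list(al$i, al$j, al$score), list(1L, 1L, 7))
  expect_equal(dp_linear(matrix(0, 4, 5), gap = 10)$score, 0)
  expect_equal(alignment_length(dp_linear(matrix(0, 0, 0), 10)), 0L)
  al2 <- dp_linear(matrix(7, 1, 1), gap = 10, free_ends = FALSE)
  expect_equal(al2$score, 7)
})

test_that("linear-gap DP equals exhaustive enumeration on random matrices", {
  set.seed(41)
  for (rep in 1:40) {
    S <- matrix(sample(-9:20, 20, replace = TRUE), 4, 5)
    al <- dp_linear(S, gap = 10)
    expect_equal(al$score, oracle_linear_score(S, 10))
    # reported score is reproducible from the returned pairs
    if (alignment_length(al)) {
      g <- sum(diff(al$i) - 1L) + sum(diff(al$j) - 1L)
      expect_equal(sum(S[cbind(al$i, al$j)]) - 10 * g, al$score)
    }
  }
})

test_that("literal zero-boundary recurrence reproduces a hand-worked table", {
  # 2x2 instance, gap 10: D(1,1)=5, D(1,2)=max(0+1,-10,5-10)=1,
  # D(2,1)=max(0+2,5-10,-10)=2, D(2,2)=max(5+8,1-10,2-10)=13
  S <- matrix(c(5, 2, 1, 8), 2, 2)
  al <- dp_linear(S, gap = 10, free_ends = FALSE)
  expect_equal(al$score, 13)
  expect_equal(al$i, c(1L, 2L))
  expect_equal(al$j, c(1L, 2L))
})

test_that("affine-gap DP equals exhaustive enumeration with run accounting", {
  set.seed(42)
  for (rep in 1:40) {
    S <- matrix(runif(25), 5, 5)
    expect_equal(dp_affine(S, 0.6, 0)$score, oracle_affine_score(S, 0.6, 0))
    S2 <- matrix(runif(20, -0.5, 1), 4, 5)
    expect_equal(dp_affine(S2, 0.3, 0.1)$score,
                 oracle_affine_score(S2, 0.3, 0.1))
  }
})

test_that("affine-gap DP with zero penalties is the unpenalized monotone optimum", {
  set.seed(43)
  S <- matrix(runif(30), 5, 6)
  expect_equal(dp_affine(S, 0, 0)$score, oracle_affine_score(S, 0, 0))
  al <- dp_affine(matrix(0.9, 1, 1), open = 0.6)
  expect_equal(list(al$i, al$j, al$score), list(1L, 1L, 0.9))
})

test_that("threshold DP counts the maximal monotone pairing under d", {
  a <- make_chain(9, "helix")
  expect_equal(numpairs_dp(a, a, 3)$score, 9)
  far <- structure3d(a$xyz + 100)
  expect_equal(numpairs_dp(a, far, 3)$score, 0)
  set.seed(44)
  for (rep in 1:25) {
    A <- matrix(rnorm(21, sd = 3), 7, 3)
    B <- matrix(rnorm(21, sd = 3), 7, 3)
    al <- numpairs_dp(A, B, 3)
    expect_equal(al$score, oracle_numpairs(A, B, 3))
    expect_equal(alignment_length(al), al$score)
    if (alignment_length(al))
      expect_true(all(rowSums((A[al$i, , drop = FALSE] -
                                 B[al$j, , drop = FALSE])^2) <= 9))
  }
})

test_that("threshold DP is nondecreasing in d and symmetric in its arguments", {
  set.seed(45)
  A <- matrix(rnorm(24, sd = 3), 8, 3)
  B <- matrix(rnorm(30, sd = 3), 10, 3)
  counts <- sapply(c(0.5, 1, 2, 3, 5, 8), function(d) numpairs_dp(A, B, d)$score)
  expect_true(all(diff(counts) >= 0))
  for (d in c(1, 3, 5))
    expect_equal(numpairs_dp(A, B, d)$score, numpairs_dp(B, A, d)$score)
})

test_that("DP scores dominate every hand-constructed alignment", {
  set.seed(46)
  S <- matrix(runif(30, -2, 10), 5, 6)
  lin <- dp_linear(S, gap = 4)$score
  aff <- dp_affine(S, open = 1, extend = 0.2)$score
  for (p in enumerate_monotone_alignments(5, 6)) {
    if (!nrow(p)) next
    pos <- sum(diff(p[, 1]) - 1L) + sum(diff(p[, 2]) - 1L)
    runs <- sum(diff(p[, 1]) > 1L) + sum(diff(p[, 2]) > 1L)
    expect_gte(lin, sum(S[p]) - 4 * pos)
    expect_gte(aff, sum(S[p]) - 1 * runs - 0.2 * (pos - runs))
  }
})

test_that("STRUCTAL total score follows the gap-count convention", {
  a <- structure3d(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
  expect_equal(structal_total_score(alignment(1:3, 1:3), a, a), 60)
  b <- structure3d(rbind(c(0, 0, 0), c(7.6, 0, 0)))
  al <- alignment(c(1L, 3L), c(1L, 2L))       # skips position 2 of a
  pair_scores <- 20 / (1 + c(0, 0) / 5)
  expect_equal(structal_total_score(al, a, b), sum(pair_scores) - 10)
  expect_equal(structal_total_score(al, a, b, gap_count = "runs"),
               sum(pair_scores) - 10)
  al2 <- alignment(c(1L, 4L), c(1L, 2L))      # two skipped positions, one run
  a4 <- structure3d(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                          c(11.4, 0, 0)))
  b2 <- structure3d(rbind(c(0, 0, 0), c(11.4, 0, 0)))
  expect_equal(structal_total_score(al2, a4, b2), 40 - 20)
  expect_equal(structal_total_score(al2, a4, b2, gap_count = "runs"), 40 - 10)
})

test_that("dp_linear's reported score equals the STRUCTAL total score of its output", {
  set.seed(47)
  for (rep in 1:10) {
    A <- matrix(rnorm(18, sd = 4), 6, 3)
    B <- matrix(rnorm(21, sd = 4), 7, 3)
    S <- structal_score_matrix(A, B)
    al <- dp_linear(S, gap = 10)
    expect_equal(structal_total_score(al, A, B), al$score, tolerance = 1e-9)
  }
})

test_that("alignments enforce strict monotonicity at construction", {
  expect_error(alignment(c(1, 1), c(1, 2)), "strictly increasing")
  expect_error(alignment(c(1, 2), c(2, 1)), "strictly increasing")
  expect_silent(alignment(integer(0), integer(0)))
})
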