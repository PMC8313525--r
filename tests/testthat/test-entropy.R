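test_that("random entropy is log2 of the location count", {
  expect_equal(random_entropy(1), 0)
  expect_equal(random_entropy(2), 1)
  expect_equal(random_entropy(8), 3)
  expect_error(random_entropy(0), "count")
})

test_that("uncorrelated entropy matches the Shannon formula on counts", {
  expect_equal(uncorrelated_entropy(c(A = 1)), 0)
  expect_equal(uncorrelated_entropy(c(A = 2, B = 2)), 1)
  expect_equal(uncorrelated_entropy(c(A = 9, B = 1)),
               -0.9 * log2(0.9) - 0.1 * log2(0.1))
  expect_equal(uncorrelated_entropy(c(A = 9, B = 1)), 0.4690, tolerance = 1e-4)
  expect_equal(uncorrelated_entropy(c(A = 3, B = 0, C = 3)), 1)  # zero counts ignored
  expect_error(uncorrelated_entropy(numeric(0)), "empty")
})

test_that("uncorrelated entropy never exceeds random entropy, equal iff uniform", {
  set.seed(6)
  for (i in 1:20) {
    L <- sample(2:8, 1)
    cnt <- sample(1:30, L, replace = TRUE)
    expect_lte(uncorrelated_entropy(cnt), random_entropy(L) + 1e-12)
  }
  expect_equal(uncorrelated_entropy(rep(7, 16)), random_entropy(16))
  expect_lt(uncorrelated_entropy(c(5, 1)), random_entropy(2))
})

test_that("hand-traced Lempel-Ziv match lengths are reproduced", {
  expect_equal(lz_match_lengths(c("A", "B")), c(1L, 1L))
  expect_equal(lz_entropy_estimate(c("A", "B")), 1)
  expect_equal(lz_match_lengths(c("A", "A", "A", "A")), c(1L, 2L, 3L, 2L))
  expect_equal(lz_entropy_estimate(c("A", "A", "A", "A")), 1)  # log2(4) / mean 2
  expect_error(lz_entropy_estimate(c("A")), "at least 2")
  expect_error(lz_entropy_estimate(c(NA, 1), drop_nulls = TRUE), "at least 2")
})

test_that("match lengths agree with the brute-force oracle on random sequences", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    k <- sample(2:5, 1)
    s <- sample(letters[1:k], n, replace = TRUE)
    expect_identical(lz_match_lengths(s), brute_lz_lambda(s))
  }
})

test_that("nulls are dropped before estimation and the symbols concatenated", {
  s <- c(1, NA, 1, 2, NA, NA, 1, 2)
  expect_equal(lz_entropy_estimate(s), lz_entropy_estimate(c(1, 1, 2, 1, 2)))
})

test_that("the Fano bound solves the worked two-location case and its limits", {
  expect_equal(as.numeric(solve_fano(1, 2)), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(solve_fano(0, 7)), 1)
  for (L in c(2, 5, 17, 300)) {
    expect_equal(as.numeric(solve_fano(log2(L), L)), 1 / L, tolerance = 1e-9)
  }
  expect_equal(as.numeric(solve_fano(0.5, 1)), 1)
  expect_error(solve_fano(-0.1, 4), "non-negative")
  clamped <- solve_fano(3, 2)  # entropy above log2(L): estimator noise
  expect_equal(as.numeric(clamped), 0.5)
  expect_true(attr(clamped, "clamped"))
})

test_that("the Fano solver is monotone in E and round-trips through fano_entropy", {
  set.seed(15)
  for (i in 1:50) {
    L <- sample(2:200, 1)
    E <- sort(runif(2, 0, log2(L)))
    p1 <- as.numeric(solve_fano(E[1], L))
    p2 <- as.numeric(solve_fano(E[2], L))
    expect_gte(p1, p2)
    expect_lt(abs(fano_entropy(p1, L) - E[1]), 1e-9)
  }
})

test_that("the Markov entropy rate oracle matches closed forms", {
  expect_equal(markov_entropy_rate(matrix(0.25, 4, 4)), 2)
  expect_equal(markov_entropy_rate(diag(3)), 0)
  P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(markov_entropy_rate(P), -0.9 * log2(0.9) - 0.1 * log2(0.1))
  expect_error(markov_entropy_rate(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0), c(0, 0, 1))),
               "stationary")
})

test_that("the LZ estimator approaches known entropy rates on long sequences", {
  set.seed(16)
  s <- sample(1:4, 20000, replace = TRUE)
  expect_lt(abs(lz_entropy_estimate(s) - 2), 0.12)
  P <- rbind(c(0.85, 0.15), c(0.15, 0.85))
  m <- generate_markov_sequence(P, 20000, seed = 17)
  expect_lt(abs(lz_entropy_estimate(m) - markov_entropy_rate(P)) / markov_entropy_rate(P), 0.08)
})

test_that("predictability profiles satisfy their structural identities", {
  # constant sequences collapse to full predictability
  prof <- predictability_profile(rep(3L, 10))
  expect_equal(prof$pi_max, 1)
  expect_equal(prof$L, 1)
  # single-record sequences are degenerate and completely predictable
  prof1 <- predictability_profile(c(NA, 2L, NA))
  expect_true(prof1$degenerate)
  expect_equal(prof1$pi_max, 1)
  # pi_rand is exactly 1/L and the entropy ordering holds
  set.seed(18)
  for (i in 1:10) {
    s <- sample(1:sample(2:6, 1), 400, replace = TRUE)
    p <- predictability_profile(s)
    expect_equal(p$pi_rand, 1 / p$L, tolerance = 1e-9)
    expect_lte(p$s_unc, p$s_rand + 1e-12)
    expect_lte(p$pi_rand, p$pi_unc + 1e-12)
    expect_gte(p$pi_unc, 1 / p$L)
    expect_lte(p$pi_max, 1)
  }
})
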