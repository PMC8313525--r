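flat_curve <- function(form = "offset_exponential", a = 0, b = 1) {
  structure(
    list(levels = data.frame(q_prime = c(0, 0.9), delta_e = c(0, 0)),
         points = data.frame(q_prime = numeric(0), delta_e = numeric(0)),
         fit = list(form = form, a = a, b = b, r_squared = 1),
         n_reference_users = 1L),
    class = "delta_e_curve"
  )
}

test_that("degradation reaches the target exactly and is seed-deterministic", {
  s <- rep(1:4, 25)  # n = 100, q = 0
  d <- degrade_sequence(s, 0.5, seed = 2)
  expect_equal(sum(is.na(d)), 50)
  expect_identical(d, degrade_sequence(s, 0.5, seed = 2))
  expect_false(identical(d, degrade_sequence(s, 0.5, seed = 3)))
  # target equal to the current q leaves the sequence unchanged
  expect_identical(degrade_sequence(d, 0.5, seed = 2), d)
  expect_error(degrade_sequence(d, 0.3, seed = 2), "below current")
})

test_that("degradation is nested: lower-q null sets are subsets of higher-q ones", {
  set.seed(20)
  s <- sample(1:5, 200, replace = TRUE)
  s[sample(200, 10)] <- NA
  plan <- degradation_plan(seed = 4)
  prev <- which(is.na(s))
  for (q in plan$q_levels) {
    d <- degrade_sequence(s, q, seed = plan$seed)
    cur <- which(is.na(d))
    expect_true(all(prev %in% cur))
    expect_lte(abs(mean(is.na(d)) - q), 1 / length(s))
    prev <- cur
  }
})

test_that("the q' grid runs from the sequence's q to 0.90 in 0.05 steps", {
  expect_equal(build_q_prime_grid(0.8), c(0.80, 0.85, 0.90))
  expect_equal(build_q_prime_grid(0.9), 0.9)
  g <- build_q_prime_grid(0.15)
  expect_equal(unique(round(diff(g), 10)), 0.05)
  expect_equal(g[1], 0.15)
  expect_equal(g[length(g)], 0.90)
})

test_that("order-parameter estimators reject degenerate inputs", {
  expect_error(estimate_H_shuff(rep(1L, 50)), "constant")
  expect_error(estimate_H_unc(c(1L, NA, NA)), "non-null")
  s <- c(rep(NA, 95), 1L, 2L, 1L, 2L, 1L)  # q above 0.90
  expect_error(estimate_H_shuff(s), "0.90")
})

test_that("order-parameter estimators are seeded and near the raw estimate on complete data", {
  set.seed(21)
  s <- sample(1:4, 20000, replace = TRUE)
  ref <- lz_entropy_estimate(s)
  h1 <- estimate_H_unc(s, seed = 5)
  expect_identical(as.numeric(h1), as.numeric(estimate_H_unc(s, seed = 5)))
  expect_lt(abs(as.numeric(h1) - ref) / ref, 0.10)
  h2 <- estimate_H_shuff(s, seed = 5)
  expect_lt(abs(as.numeric(h2) - ref) / ref, 0.10)
  # within 10% of the true 2-bit rate even from q = 0.3
  d <- degrade_sequence(s, 0.3, seed = 6)
  h3 <- estimate_H_shuff(d, seed = 7)
  expect_lt(abs(as.numeric(h3) - 2) / 2, 0.10)
})

test_that("reference curves anchor at zero error and reject high-q references", {
  P <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  refs <- lapply(1:5, function(i) generate_markov_sequence(P, 5000, seed = 30 + i))
  curve <- build_delta_e_curve(refs, degradation_plan(seed = 8))
  # delta_e at q' = q (= 0 here) is exactly 0 by definition
  expect_equal(curve$levels$delta_e[curve$levels$q_prime == 0], 0)
  expect_equal(predict_delta_e(curve, 0), 0)
  expect_equal(curve$n_reference_users, 5)
  bad <- refs[[1]]
  bad[seq(1, 5000, by = 5)] <- NA  # q = 0.2
  expect_error(build_delta_e_curve(list(bad)), ">= 0.15")
  expect_error(build_delta_e_curve(list()), "empty")
})

test_that("the delta_e correction applies the fitted curve arithmetically", {
  set.seed(22)
  s <- sample(1:3, 500, replace = TRUE)
  ref <- lz_entropy_estimate(s)
  expect_equal(estimate_H_delta_e(s, flat_curve()), ref)          # flat zero curve
  half <- flat_curve(form = "linear", a = Inf)
  half$fit$a <- 1 / compute_q(degrade_sequence(s, 0.5, seed = 1)) # delta_e(q) = 1
  expect_equal(estimate_H_delta_e(degrade_sequence(s, 0.5, seed = 1), half),
               lz_entropy_estimate(degrade_sequence(s, 0.5, seed = 1)) / 2)
  # a curve that does not cover the sequence's q is an error
  short <- flat_curve()
  short$levels <- data.frame(q_prime = c(0, 0.2), delta_e = c(0, 0))
  expect_error(estimate_H_delta_e(degrade_sequence(s, 0.5, seed = 1), short), "cover")
  # nonsensical corrections are refused
  neg <- flat_curve(form = "linear", a = -3)
  expect_error(estimate_H_delta_e(degrade_sequence(s, 0.5, seed = 1), neg), "-1")
})

test_that("estimator evaluation reports pooled errors with confidence intervals", {
  P <- rbind(c(0.85, 0.1, 0.05), c(0.1, 0.85, 0.05), c(0.05, 0.1, 0.85))
  refs <- lapply(1:4, function(i) generate_markov_sequence(P, 4000, seed = 40 + i))
  evals <- lapply(1:4, function(i) generate_markov_sequence(P, 4000, seed = 50 + i))
  curve <- build_delta_e_curve(refs, degradation_plan(seed = 9))
  tab <- evaluate_estimators(evals, degradation_plan(q_levels = c(0.3, 0.5), seed = 10),
                             curve, delta_t = 3600)
  expect_equal(sort(tab$estimator), c("delta_e", "shuff", "unc"))
  expect_equal(tab$delta_t, rep(3600, 3))
  expect_true(all(tab$mean_error_pct >= 0))
  expect_true(all(is.finite(tab$ci95)))
  detail <- attr(tab, "detail")
  expect_equal(nrow(detail), 4 * 2 * 3)  # sequences x levels x estimators
})
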