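test_that("each bin takes the region with the longest dwell, nulls when empty", {
  # bin 0: A for 40 min, B for 20 min -> A; bin 1: empty -> NA; bin 2: B
  v <- make_visits(region = c(1, 2, 2),
                   start_s = c(0, 2400, 7200),
                   end_s = c(2400, 3600, 10800))
  tb <- build_time_bin_sequence(v, 3600)
  expect_equal(tb$symbols, c(1L, NA, 2L))
  expect_equal(as.numeric(tb$origin), as.numeric(v$start[1]))  # already aligned
})

test_that("dwell ties break by overall visit frequency, then smallest id", {
  # bin 0: A and B 30 min each; A visited 3 times in the whole history
  v <- make_visits(region = c(1, 2, 1, 1),
                   start_s = c(0, 1800, 3700, 4600),
                   end_s = c(1800, 3600, 4500, 5400))
  tb <- build_time_bin_sequence(v, 3600)
  expect_equal(tb$symbols[1], 1L)
  # equal dwell and equal frequency: the smaller region id wins
  v2 <- make_visits(region = c(2, 1), start_s = c(0, 1800), end_s = c(1800, 3600))
  expect_equal(build_time_bin_sequence(v2, 3600)$symbols[1], 1L)
})

test_that("bins are anchored to delta_t multiples from midnight UTC", {
  t0 <- as.POSIXct("2023-01-02 05:40:00", tz = "UTC")
  v <- make_visits(1, 0, 7200, t0 = t0)
  tb <- build_time_bin_sequence(v, 3600)
  expect_equal(format(tb$origin, "%H:%M"), "05:00")
  expect_equal(length(tb$symbols), ceiling(as.numeric(7200 + 2400) / 3600))
})

test_that("bin count equals ceiling(span / delta_t) and shrinking delta_t keeps records", {
  v <- make_visits(region = c(1, 2), start_s = c(0, 50000), end_s = c(40000, 90000))
  for (dt in c(900, 3600, 21600)) {
    tb <- build_time_bin_sequence(v, dt)
    expect_equal(length(tb$symbols), ceiling((90000) / dt))
  }
  n_rec <- sapply(c(21600, 10800, 5400), function(dt) {
    sequence_stats(build_time_bin_sequence(v, dt))$n_records
  })
  expect_true(all(diff(n_rec) >= 0))
})

test_that("next place sequences collapse consecutive repeats", {
  v <- make_visits(region = c(1, 1, 2, 2, 1),
                   start_s = (0:4) * 1000, end_s = (0:4) * 1000 + 900)
  expect_equal(build_next_place_sequence(v)$symbols, c(1L, 2L, 1L))
  v2 <- make_visits(region = c(3, 3, 3), start_s = (0:2) * 1000, end_s = (0:2) * 1000 + 900)
  expect_equal(build_next_place_sequence(v2)$symbols, 3L)
  v3 <- make_visits(region = 7, start_s = 0, end_s = 900)
  expect_equal(build_next_place_sequence(v3)$symbols, 7L)
})

test_that("q is the null fraction and complements the record fraction", {
  expect_equal(compute_q(c(1, NA, 2, 3, 2, 1, 1, 2, 2, 1)), 0.1)
  expect_equal(compute_q(c(1, 2, 3)), 0)
  expect_equal(compute_q(c(NA, NA)), 1)
  expect_error(compute_q(integer(0)), "zero-length")
  set.seed(5)
  for (i in 1:5) {
    s <- sample(c(1:3, NA), 50, replace = TRUE)
    st <- sequence_stats(s)
    expect_equal(compute_q(s) + st$n_records / length(s), 1)
  }
})

test_that("sequence statistics count records, regions and self-transitions", {
  expect_equal(sequence_stats(c(1, 1, 2)),
               list(n_records = 3L, n_regions = 2L, n_self_transitions = 1L))
  # a null breaks adjacency
  expect_equal(sequence_stats(c(1, NA, 1)),
               list(n_records = 2L, n_regions = 1L, n_self_transitions = 0L))
  # place sequences have no self-transitions by construction
  v <- make_visits(region = c(1, 1, 2, 1), start_s = (0:3) * 1000, end_s = (0:3) * 1000 + 900)
  ps <- build_next_place_sequence(v)
  expect_equal(sequence_stats(ps)$n_self_transitions, 0L)
  s <- c(1, 1, 1, 2, 2, NA, 2)
  expect_lte(sequence_stats(s)$n_self_transitions, sequence_stats(s)$n_records - 1)
})

test_that("time-bin symbols collapse to the place sequence when visits span full bins", {
  set.seed(9)
  for (i in 1:5) {
    k <- sample(4:9, 1)
    regions <- sample(1:3, k, replace = TRUE)
    # durations of at least two bins and positive gaps keep bin ownership contiguous
    dur <- sample(2:4, k, replace = TRUE) * 3600
    gap <- sample(0:2, k, replace = TRUE) * 3600
    starts <- cumsum(c(0, head(dur + gap, -1)))
    v <- make_visits(regions, starts, starts + dur)
    tb <- build_time_bin_sequence(v, 3600)
    ps <- build_next_place_sequence(v)
    expect_equal(collapse_runs(tb$symbols), ps$symbols)
  }
})

test_that("user filtering applies the completeness and span thresholds", {
  pop <- data.frame(user = c("a", "b", "c"), q = c(0.04, 0.2, 0.1), days = c(30, 30, 27))
  kept <- filter_users(pop)
  expect_equal(kept$user, "a")
  expect_equal(nrow(filter_users(pop, q_max = 0.25, d_min_days = 27)), 3)
})

test_that("the temporal sweep lists the documented resolutions once each", {
  v <- delta_t_sweep_values()
  expect_equal(v[1], 300)
  expect_equal(v[length(v)], 144 * 3600)
  expect_true(all(diff(v) > 0))
  expect_length(v, 12)  # 60 min and 1 h deduplicated
  expect_true(3600 %in% v)
})
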