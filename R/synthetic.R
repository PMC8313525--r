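#' Configure the synthetic mobility model
#'
#' The simulator emulates multi-week individual trajectories over a small set
#' of repeatedly visited anchor locations (home, work, and so on). An
#' individual follows a Markov visit schedule over the anchors: each visit
#' dwells at an anchor for a random duration, then moves in a straight line at
#' constant speed to the next anchor drawn from the transition matrix.
#' Positions are sampled at a fixed interval; dwell positions get isotropic
#' Gaussian GNSS-like noise. Finally, whole hour-long windows are emptied at
#' random until the hour-level fraction of missing records matches the target
#' — mirroring how record completeness is measured on hour-long intervals.
#'
#' @param anchor_coords two-column matrix (or data.frame) of anchor x/y
#'   coordinates, in metres on a planar metric frame.
#' @param transition_matrix row-stochastic matrix over anchors. Rows must sum
#'   to 1 within 1e-9 and all entries must be non-negative. Self-transitions
#'   extend the current dwell rather than triggering travel.
#' @param dwell_mean_per_anchor mean dwell duration in seconds; scalar or one
#'   value per anchor. Dwells are drawn from a shifted exponential so that
#'   every visit lasts at least `min(900, mean/2)` seconds while keeping the
#'   configured mean exactly.
#' @param travel_speed straight-line travel speed, metres per second.
#' @param sampling_interval position sampling interval, seconds.
#' @param gnss_noise_sigma standard deviation of isotropic positional noise
#'   during dwells, metres.
#' @param duration_days length of the simulated observation window, days.
#' @param missing_fraction_target target hour-level fraction of missing
#'   records, in `[0, 1)`.
#' @param seed integer seed; identical configurations with identical seeds
#'   yield byte-identical trajectories.
#' @param start_time POSIXct start of the observation window (UTC).
#'
#' @return an object of class `mobility_config`.
#' @export
mobility_config <- function(anchor_coords,
                            transition_matrix,
                            dwell_mean_per_anchor = 3 * 3600,
                            travel_speed = 10,
                            sampling_interval = 240,
                            gnss_noise_sigma = 10,
                            duration_days = 28,
                            missing_fraction_target = 0.04,
                            seed = 1L,
                            start_time = as.POSIXct("2023-03-06", tz = "UTC")) {
  anchor_coords <- as.matrix(anchor_coords)
  storage.mode(anchor_coords) <- "double"
  if (ncol(anchor_coords) != 2) stopf("anchor_coords must have two columns (x, y)")
  n <- nrow(anchor_coords)
  transition_matrix <- as.matrix(transition_matrix)
  check_stochastic(transition_matrix, n)
  if (length(dwell_mean_per_anchor) == 1) {
    dwell_mean_per_anchor <- rep(dwell_mean_per_anchor, n)
  }
  if (length(dwell_mean_per_anchor) != n) {
    stopf("dwell_mean_per_anchor must be scalar or one value per anchor")
  }
  if (any(dwell_mean_per_anchor <= 0)) stopf("dwell means must be positive")
  if (duration_days < 1) stopf("duration_days must be >= 1")
  if (sampling_interval <= 0) stopf("sampling_interval must be positive")
  if (gnss_noise_sigma < 0) stopf("gnss_noise_sigma must be >= 0")
  if (missing_fraction_target < 0 || missing_fraction_target >= 1) {
    stopf("missing_fraction_target must be in [0, 1)")
  }
  if (travel_speed <= 0) stopf("travel_speed must be positive")
  if (n > 1) {
    d <- as.matrix(stats::dist(anchor_coords))
    diag(d) <- Inf
    if (min(d) < 2 * gnss_noise_sigma) {
      warning("anchors closer than 2*gnss_noise_sigma: ground truth may be unrecoverable",
              call. = FALSE)
    }
  }
  structure(
    list(
      n_anchors = n,
      anchor_coords = anchor_coords,
      transition_matrix = transition_matrix,
      dwell_mean_per_anchor = as.double(dwell_mean_per_anchor),
      travel_speed = travel_speed,
      sampling_interval = sampling_interval,
      gnss_noise_sigma = gnss_noise_sigma,
      duration_days = duration_days,
      missing_fraction_target = missing_fraction_target,
      seed = as.integer(seed),
      start_time = as_utc(start_time)
    ),
    class = "mobility_config"
  )
}

check_stochastic <- function(P, n = nrow(P)) {
  if (nrow(P) != n || ncol(P) != n) stopf("transition matrix must be %d x %d", n, n)
  if (any(P < 0)) stopf("transition matrix entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9)) stopf("transition matrix rows must sum to 1")
  invisible(P)
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P row-stochastic transition matrix.
#' @param tol tolerance used both for the uniqueness check (multiplicity of
#'   the unit eigenvalue) and the final `pi P = pi` verification.
#' @return probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P, tol = 1e-9) {
  check_stochastic(P)
  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) != 1) {
    stopf("transition matrix has no unique stationary distribution")
  }
  v <- Re(e$vectors[, unit])
  pi <- v / sum(v)
  if (any(pi < -tol) || max(abs(as.vector(pi %*% P) - pi)) > tol) {
    stopf("failed to compute stationary distribution to tolerance")
  }
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Simulate a Markov symbol sequence
#'
#' Generates a length-`n` realisation of the Markov chain defined by
#' `transition_matrix`. Unless `start` is given, the chain is started from its
#' stationary distribution (so marginal symbol frequencies are at steady
#' state from the first symbol); a matrix without a unique stationary
#' distribution is then an error.
#'
#' @param transition_matrix row-stochastic matrix.
#' @param n sequence length, `>= 1`.
#' @param seed integer seed.
#' @param start optional fixed initial state (1-based index).
#' @return integer vector of states in `1..nrow(P)`.
#' @export
generate_markov_sequence <- function(transition_matrix, n, seed = 1L, start = NULL) {
  P <- as.matrix(transition_matrix)
  check_stochastic(P)
  if (n < 1) stopf("n must be >= 1")
  m <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  with_seed(seed, {
    state <- if (is.null(start)) {
      pi <- stationary_distribution(P)
      sample.int(m, 1, prob = pi)
    } else {
      as.integer(start)
    }
    out <- integer(n)
    out[1] <- state
    if (n > 1) {
      u <- runif(n - 1)
      for (j in 2:n) {
        state <- findInterval(u[j - 1], cum[state, ], left.open = TRUE) + 1L
        out[j] <- state
      }
    }
    out
  })
}

#' Generate one synthetic trajectory with ground truth
#'
#' Runs the Markov visit schedule of a [mobility_config()] for
#' `duration_days`, samples positions at the configured interval (anchor plus
#' Gaussian noise during dwells, exact straight-line interpolation during
#' travel), and then empties randomly chosen whole hour-long windows until the
#' hour-level missing fraction is as close to the target as the number of
#' hours permits.
#'
#' @param config a [mobility_config()].
#' @param user_id identifier stored in the trajectory.
#' @return list with elements `trajectory` (data.frame `user_id, x, y, t`,
#'   class `trajectory`) and `truth` (list with `visits` — data.frame
#'   `anchor, start, end` — and `anchor_coords`).
#' @export
generate_trajectory <- function(config, user_id = "u1") {
  stopifnot(inherits(config, "mobility_config"))
  with_seed(config$seed, {
    total <- config$duration_days * 86400
    sched <- simulate_schedule(config, total)
    traj <- sample_positions(config, sched, total, user_id)
    traj <- apply_hour_missingness(traj, config, total)
    truth <- list(
      visits = data.frame(
        anchor = sched$anchor,
        start = config$start_time + sched$start,
        end = config$start_time + sched$end
      ),
      anchor_coords = config$anchor_coords
    )
    list(trajectory = traj, truth = truth)
  })
}

# Markov visit schedule in seconds relative to start; consecutive visits to
# the same anchor (self-transitions) are merged into one longer visit.
simulate_schedule <- function(config, total) {
  P <- config$transition_matrix
  m <- config$n_anchors
  cum <- t(apply(P, 1, cumsum))
  state <- if (m == 1) 1L else {
    pi <- tryCatch(stationary_distribution(P), error = function(e) rep(1 / m, m))
    sample.int(m, 1, prob = pi)
  }
  anchor <- integer(0); vstart <- numeric(0); vend <- numeric(0)
  t <- 0
  cur_start <- 0
  repeat {
    d <- draw_dwell(config$dwell_mean_per_anchor[state])
    t_end <- min(t + d, total)
    t <- t + d
    if (t >= total) {
      anchor <- c(anchor, state); vstart <- c(vstart, cur_start); vend <- c(vend, total)
      break
    }
    nxt <- if (m == 1) 1L else findInterval(runif(1), cum[state, ], left.open = TRUE) + 1L
    if (nxt == state) next  # extend the current dwell
    anchor <- c(anchor, state); vstart <- c(vstart, cur_start); vend <- c(vend, t_end)
    tt <- travel_time(config, state, nxt)
    t <- t + tt
    if (t >= total) break
    state <- nxt
    cur_start <- t
  }
  list(anchor = anchor, start = vstart, end = vend)
}

draw_dwell <- function(mean_dwell) {
  min_dwell <- min(900, mean_dwell / 2)
  min_dwell + rexp(1, rate = 1 / (mean_dwell - min_dwell))
}

travel_time <- function(config, from, to) {
  dx <- config$anchor_coords[to, ] - config$anchor_coords[from, ]
  sqrt(sum(dx^2)) / config$travel_speed
}

sample_positions <- function(config, sched, total, user_id) {
  ts <- (seq_len(ceiling(total / config$sampling_interval)) - 1) * config$sampling_interval
  n <- length(ts)
  x <- numeric(n); y <- numeric(n)
  idx <- findInterval(ts, sched$start)
  for (k in seq_len(n)) {
    i <- idx[k]
    if (i >= 1 && ts[k] < sched$end[i]) {
      a <- sched$anchor[i]
      x[k] <- config$anchor_coords[a, 1]
      y[k] <- config$anchor_coords[a, 2]
    } else {
      # travelling between visit i and i+1 (or before/after the schedule)
      i0 <- max(i, 1)
      i1 <- min(i + 1, length(sched$anchor))
      a0 <- sched$anchor[i0]; a1 <- sched$anchor[i1]
      t0 <- if (i >= 1) sched$end[i] else 0
      t1 <- if (i + 1 <= length(sched$start)) sched$start[i + 1] else total
      f <- if (t1 > t0) (ts[k] - t0) / (t1 - t0) else 0
      f <- min(max(f, 0), 1)
      x[k] <- config$anchor_coords[a0, 1] + f * (config$anchor_coords[a1, 1] - config$anchor_coords[a0, 1])
      y[k] <- config$anchor_coords[a0, 2] + f * (config$anchor_coords[a1, 2] - config$anchor_coords[a0, 2])
    }
  }
  if (config$gnss_noise_sigma > 0) {
    dwell <- idx >= 1 & ts < sched$end[pmax(idx, 1)]
    nd <- sum(dwell)
    x[dwell] <- x[dwell] + rnorm(nd, 0, config$gnss_noise_sigma)
    y[dwell] <- y[dwell] + rnorm(nd, 0, config$gnss_noise_sigma)
  }
  trajectory(user_id, x, y, config$start_time + ts)
}

apply_hour_missingness <- function(traj, config, total) {
  target <- config$missing_fraction_target
  if (target <= 0) return(traj)
  n_hours <- as.integer(ceiling(total / 3600))
  n_remove <- round(target * n_hours)
  if (n_remove == 0) return(traj)
  removed <- sample.int(n_hours, n_remove)
  hour <- floor(as.numeric(traj$t - config$start_time, units = "secs") / 3600) + 1
  out <- traj[!(hour %in% removed), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(traj)
  out
}

#' Construct a trajectory object
#'
#' A trajectory is a data.frame with columns `user_id`, `x`, `y` (metres on a
#' planar metric frame) and `t` (POSIXct, UTC), with strictly increasing
#' timestamps.
#'
#' @param user_id identifier.
#' @param x,y coordinates in metres.
#' @param t POSIXct timestamps (coerced to UTC).
#' @return data.frame of class `trajectory`.
#' @export
trajectory <- function(user_id, x, y, t) {
  t <- as_utc(t)
  if (length(x) == 0) {
    out <- data.frame(user_id = character(0), x = numeric(0), y = numeric(0),
                      t = as.POSIXct(character(0), tz = "UTC"))
    class(out) <- c("trajectory", "data.frame")
    return(out)
  }
  if (length(t) > 1 && any(diff(as.numeric(t)) <= 0)) {
    stopf("trajectory timestamps must be strictly increasing")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("coordinates must be finite")
  structure(
    data.frame(user_id = user_id, x = x, y = y, t = t),
    class = c("trajectory", "data.frame")
  )
}

#' Simulate a population of synthetic individuals
#'
#' Draws per-user anchor layouts and visit dynamics, then generates one
#' trajectory per user. Anchors are placed uniformly in a square of side
#' `extent` with a minimum mutual separation; anchor attractiveness follows a
#' Zipf-like weighting (one dominant "home" anchor), transition rows are
#' proportional to target attractiveness with no self-transitions, and the
#' per-anchor mean dwell is longest for the dominant anchor. Per-user missing
#' fractions are Beta-distributed with median close to `missing_median`.
#'
#' @param n_users number of individuals.
#' @param duration_days observation window per user, days.
#' @param n_anchors_range inclusive range of anchors per user.
#' @param extent side of the square placement region, metres.
#' @param min_anchor_sep minimum separation between anchors, metres.
#' @param missing_median target median hour-level missing fraction.
#' @param sampling_interval,gnss_noise_sigma,travel_speed passed to
#'   [mobility_config()].
#' @param seed global seed; per-user seeds are derived deterministically.
#' @return list of per-user results as returned by [generate_trajectory()],
#'   each with an added `config` element; class `mobility_population`.
#' @export
simulate_population <- function(n_users = 50,
                                duration_days = 28,
                                n_anchors_range = c(5, 8),
                                extent = 20000,
                                min_anchor_sep = 2000,
                                missing_median = 0.04,
                                sampling_interval = 240,
                                gnss_noise_sigma = 10,
                                travel_speed = 10,
                                seed = 1L) {
  users <- vector("list", n_users)
  for (i in seq_len(n_users)) {
    si <- derive_seed(seed, i)
    cfg <- with_seed(si, {
      k <- sample(seq(n_anchors_range[1], n_anchors_range[2]), 1)
      coords <- place_anchors(k, extent, min_anchor_sep)
      w <- 1 / seq_len(k)  # Zipf-like attractiveness, anchor 1 dominant
      P <- outer(rep(1, k), w)
      diag(P) <- 0
      P <- P / rowSums(P)
      dwell <- 3600 * c(8, rep(2, k - 1)) * exp(rnorm(k, 0, 0.2))
      # Beta(2, b) with b chosen so the distribution's median sits at
      # missing_median (median ~ (a - 1/3)/(a + b - 2/3))
      b_shape <- (2 - 1 / 3) / missing_median - 2 + 2 / 3
      qmiss <- rbeta(1, 2, b_shape)
      mobility_config(
        anchor_coords = coords,
        transition_matrix = P,
        dwell_mean_per_anchor = dwell,
        travel_speed = travel_speed,
        sampling_interval = sampling_interval,
        gnss_noise_sigma = gnss_noise_sigma,
        duration_days = duration_days,
        missing_fraction_target = min(qmiss, 0.9),
        seed = derive_seed(si, 1)
      )
    })
    res <- generate_trajectory(cfg, user_id = sprintf("u%03d", i))
    res$config <- cfg
    users[[i]] <- res
  }
  structure(users, class = "mobility_population")
}

place_anchors <- function(k, extent, min_sep) {
  coords <- matrix(runif(2, 0, extent), ncol = 2)
  tries <- 0
  while (nrow(coords) < k && tries < 10000) {
    cand <- runif(2, 0, extent)
    d2 <- (coords[, 1] - cand[1])^2 + (coords[, 2] - cand[2])^2
    if (min(d2) >= min_sep^2) coords <- rbind(coords, cand)
    tries <- tries + 1
  }
  if (nrow(coords) < k) stopf("could not place %d anchors with separation %g in extent %g",
                              k, min_sep, extent)
  coords
}
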