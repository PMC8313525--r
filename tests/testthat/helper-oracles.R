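# Independent oracles and fixture builders shared across tests.

# Brute-force Lempel-Ziv match lengths: encode symbols as single characters
# and, for each position j, grow the substring starting at j until it no
# longer occurs (plain fixed-string search) in the length-(j-1) prefix.
# Completely independent of the suffix-automaton path in the package.
brute_lz_lambda <- function(s) {
  codes <- match(s, unique(s))
  stopifnot(max(codes) <= 26)
  ch <- letters[codes]
  str <- paste(ch, collapse = "")
  n <- length(ch)
  lambda <- integer(n)
  for (j in seq_len(n)) {
    prefix <- substr(str, 1, j - 1)
    lam <- n - j + 2L
    for (l in seq_len(n - j + 1)) {
      pat <- substr(str, j, j + l - 1)
      if (!grepl(pat, prefix, fixed = TRUE)) {
        lam <- l
        break
      }
    }
    lambda[j] <- lam
  }
  lambda
}

# Union-find over all pairwise distances: the clustering oracle for
# dbscan_aggregate (connected components at distance < eps).
brute_components <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < eps) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Collapse consecutive duplicates of a vector (NA entries removed first).
collapse_runs <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0) return(z)
  z[c(TRUE, z[-1] != z[-length(z)])]
}

# Visit fixture: data.frame of class region_visits with POSIXct times offset
# in seconds from a fixed aligned origin (midnight-aligned hour).
make_visits <- function(region, start_s, end_s,
                        t0 = as.POSIXct("2023-01-02 05:00:00", tz = "UTC")) {
  out <- data.frame(region = region, start = t0 + start_s, end = t0 + end_s)
  attr(out, "user_id") <- "test"
  class(out) <- c("region_visits", "data.frame")
  out
}

# Stay-point fixture from bare coordinates (intervals are back-to-back hours).
make_staypoints <- function(x, y, t0 = as.POSIXct("2023-01-02", tz = "UTC")) {
  n <- length(x)
  out <- data.frame(
    x = x, y = y,
    start = t0 + (seq_len(n) - 1) * 3600,
    end = t0 + (seq_len(n) - 1) * 3600 + 3000,
    n_points = rep(5L, n)
  )
  attr(out, "user_id") <- "test"
  class(out) <- c("staypoints", "data.frame")
  out
}

# Trajectory fixture from offsets in minutes.
make_traj <- function(x, y, minutes, user = "t1",
                      t0 = as.POSIXct("2023-01-02", tz = "UTC")) {
  trajectory(user, x, y, t0 + minutes * 60)
}

# Regular 5-anchor layout on a circle, noiseless dynamics.
five_anchor_config <- function(seed, duration_days = 7, noise = 0, missing = 0) {
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  coords <- cbind(10000 + 5000 * cos(ang), 10000 + 5000 * sin(ang))
  P <- matrix(1 / 4, 5, 5)
  diag(P) <- 0
  P <- P / rowSums(P)
  mobility_config(coords, P,
                  dwell_mean_per_anchor = 3 * 3600,
                  gnss_noise_sigma = noise,
                  missing_fraction_target = missing,
                  duration_days = duration_days, seed = seed)
}
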