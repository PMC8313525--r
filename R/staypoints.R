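#' Detect stay-points in a trajectory
#'
#' Scans the trajectory in temporal order, accumulating consecutive points
#' while each lies within `delta` metres (planar Euclidean) of the *first*
#' point of the current candidate. On the first point at distance `>= delta`,
#' the accumulated run is emitted as a stay-point if its elapsed time (first
#' to last accumulated timestamp) strictly exceeds `tau`, and discarded
#' otherwise; the scan restarts at the violating point. The trailing candidate
#' at end-of-data is subjected to the same `tau` test, so dwells that run into
#' the end of the observation window are kept.
#'
#' A stay-point's coordinates are the arithmetic mean of its member points;
#' its interval is `[first, last]` member timestamp. A single-point candidate
#' can never pass `tau > 0` and is always discarded.
#'
#' @param trajectory a [trajectory()] (data.frame with `user_id, x, y, t`),
#'   timestamps strictly increasing. Coordinates must already be in metres on
#'   a planar metric frame; project lon/lat beforehand.
#' @param delta distance threshold in metres (default 300).
#' @param tau minimum dwell duration in seconds (default 600, i.e. 10 min).
#' @return data.frame of class `staypoints` with columns
#'   `x, y, start, end, n_points` and attributes `user_id`, `delta`, `tau`,
#'   and `members` (list of member-point index vectors, for diagnostics).
#' @export
detect_staypoints <- function(trajectory, delta = 300, tau = 600) {
  if (nrow(trajectory) == 0) {
    return(empty_staypoints(attr(trajectory, "user_id") %||% NA_character_, delta, tau))
  }
  stopifnot(all(c("x", "y", "t") %in% names(trajectory)))
  tsec <- as.numeric(trajectory$t)
  if (any(diff(tsec) <= 0)) stopf("trajectory timestamps must be strictly increasing")
  x <- trajectory$x
  y <- trajectory$y
  n <- length(x)
  user_id <- if ("user_id" %in% names(trajectory)) trajectory$user_id[1] else NA_character_

  sx <- numeric(0); sy <- numeric(0); s0 <- numeric(0); s1 <- numeric(0)
  np <- integer(0); members <- list()
  i <- 1L
  while (i <= n) {
    j <- i + 1L
    while (j <= n && (x[j] - x[i])^2 + (y[j] - y[i])^2 < delta^2) j <- j + 1L
    last <- j - 1L
    if (tsec[last] - tsec[i] > tau) {
      idx <- i:last
      sx <- c(sx, mean(x[idx])); sy <- c(sy, mean(y[idx]))
      s0 <- c(s0, tsec[i]); s1 <- c(s1, tsec[last])
      np <- c(np, length(idx)); members[[length(members) + 1L]] <- idx
    }
    i <- j
  }
  out <- data.frame(
    x = sx, y = sy,
    start = as.POSIXct(s0, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(s1, origin = "1970-01-01", tz = "UTC"),
    n_points = np
  )
  attr(out, "user_id") <- user_id
  attr(out, "delta") <- delta
  attr(out, "tau") <- tau
  attr(out, "members") <- members
  class(out) <- c("staypoints", "data.frame")
  out
}

empty_staypoints <- function(user_id, delta, tau) {
  out <- data.frame(
    x = numeric(0), y = numeric(0),
    start = as.POSIXct(character(0), tz = "UTC"),
    end = as.POSIXct(character(0), tz = "UTC"),
    n_points = integer(0)
  )
  attr(out, "user_id") <- user_id
  attr(out, "delta") <- delta
  attr(out, "tau") <- tau
  attr(out, "members") <- list()
  class(out) <- c("staypoints", "data.frame")
  out
}
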