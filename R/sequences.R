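#' Map stay-points to a region visit sequence
#'
#' Relabels a time-ordered stay-point sequence by its region assignment,
#' producing the visit history used to build symbolic sequences: one visit
#' per stay-point, carrying the stay-point's interval and its region id.
#'
#' @param staypoints a [detect_staypoints()] result.
#' @param assignment a `region_assignment` for those stay-points.
#' @return data.frame of class `region_visits` with columns
#'   `region, start, end`, attribute `user_id`.
#' @export
region_visit_sequence <- function(staypoints, assignment) {
  stopifnot(inherits(assignment, "region_assignment"))
  if (length(assignment$labels) != nrow(staypoints)) {
    stopf("assignment does not match stay-points")
  }
  out <- data.frame(
    region = assignment$labels,
    start = staypoints$start,
    end = staypoints$end
  )
  attr(out, "user_id") <- attr(staypoints, "user_id")
  class(out) <- c("region_visits", "data.frame")
  out
}

#' Build a next time-bin sequence from region visits
#'
#' Divides the observation window into consecutive bins of width `delta_t`
#' and assigns each bin the region where most of the bin's visited time was
#' spent. Ties on within-bin dwell are broken by the region's visit count
#' over the entire visit sequence (the more often visited region wins), and
#' remaining ties by the smaller region id. Bins with no visited time are
#' null (`NA`). Bins are anchored at the first visit's start floored to a
#' whole multiple of `delta_t` counted from the preceding midnight UTC, and
#' extend to cover the last visit's end, so the bin count is
#' `ceiling(span / delta_t)`.
#'
#' @param visits a [region_visit_sequence()] (data.frame `region, start,
#'   end`, time-ordered, non-overlapping).
#' @param delta_t bin width in seconds, `> 0`.
#' @return object of class `time_bin_sequence`: list with `user_id`,
#'   `delta_t`, `origin` (POSIXct) and `symbols` (integer region ids with
#'   `NA` for empty bins).
#' @export
build_time_bin_sequence <- function(visits, delta_t) {
  if (delta_t <= 0) stopf("delta_t must be positive")
  if (nrow(visits) == 0) stopf("empty visit sequence")
  vstart <- as.numeric(visits$start)
  vend <- as.numeric(visits$end)
  if (any(vend < vstart)) stopf("visit intervals must have end >= start")
  t0 <- vstart[1]
  midnight <- floor(t0 / 86400) * 86400
  origin <- midnight + floor((t0 - midnight) / delta_t) * delta_t
  span_end <- max(vend)
  n_bins <- max(1L, as.integer(ceiling((span_end - origin) / delta_t)))

  # total dwell per (bin, region)
  region <- visits$region
  acc <- new.env(parent = emptyenv())
  for (v in seq_along(region)) {
    if (vend[v] <= vstart[v]) next
    b0 <- floor((vstart[v] - origin) / delta_t)
    b1 <- ceiling((vend[v] - origin) / delta_t) - 1
    for (b in b0:b1) {
      lo <- max(vstart[v], origin + b * delta_t)
      hi <- min(vend[v], origin + (b + 1) * delta_t)
      if (hi <= lo) next
      key <- paste(b, region[v])
      acc[[key]] <- (acc[[key]] %||% 0) + (hi - lo)
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) stopf("no visited time overlaps any bin")
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  tab <- data.frame(
    bin = as.integer(parts[, 1]),
    region = as.integer(parts[, 2]),
    dwell = vapply(keys, function(k) acc[[k]], numeric(1))
  )
  visit_count <- table(region)
  tab$freq <- as.vector(visit_count[as.character(tab$region)])
  # majority dwell, then global visit frequency, then smallest region id
  ord <- order(tab$bin, -tab$dwell, -tab$freq, tab$region)
  tab <- tab[ord, , drop = FALSE]
  winner <- tab[!duplicated(tab$bin), , drop = FALSE]

  symbols <- rep(NA_integer_, n_bins)
  symbols[winner$bin + 1L] <- winner$region
  structure(
    list(
      user_id = attr(visits, "user_id") %||% NA_character_,
      delta_t = delta_t,
      origin = as.POSIXct(origin, origin = "1970-01-01", tz = "UTC"),
      symbols = symbols
    ),
    class = "time_bin_sequence"
  )
}

#' Build a next place sequence from region visits
#'
#' Keeps region ids in visit order and collapses consecutive repeats, so the
#' sequence represents transitions between places only. A visit history over
#' a single region collapses to length one.
#'
#' @param visits a [region_visit_sequence()].
#' @return object of class `place_sequence`: list with `user_id` and
#'   `symbols` (integer region ids, no adjacent repeats, no nulls).
#' @export
build_next_place_sequence <- function(visits) {
  if (nrow(visits) == 0) stopf("empty visit sequence")
  r <- visits$region
  keep <- c(TRUE, r[-1] != r[-length(r)])
  structure(
    list(user_id = attr(visits, "user_id") %||% NA_character_,
         symbols = as.integer(r[keep])),
    class = "place_sequence"
  )
}

#' Symbols of a sequence object
#'
#' @param x a `time_bin_sequence`, `place_sequence`, or bare vector.
#' @return the symbol vector (with `NA` for null bins where applicable).
#' @export
seq_symbols <- function(x) {
  if (inherits(x, "time_bin_sequence") || inherits(x, "place_sequence")) {
    x$symbols
  } else {
    x
  }
}

#' Fraction of empty records in a time-bin sequence
#'
#' @param seq a `time_bin_sequence` (or symbol vector with `NA` nulls).
#' @return `q`, the null-bin count divided by total bins.
#' @export
compute_q <- function(seq) {
  s <- seq_symbols(seq)
  if (length(s) == 0) stopf("zero-length sequence")
  mean(is.na(s))
}

#' Numerical properties of a symbolic sequence
#'
#' @param seq a `time_bin_sequence` or `place_sequence` (or symbol vector).
#' @return list with `n_records` (non-null length), `n_regions` (distinct
#'   non-null symbols), and `n_self_transitions` (adjacent equal non-null
#'   pairs; nulls break adjacency, and next place sequences have none by
#'   construction).
#' @export
sequence_stats <- function(seq) {
  s <- seq_symbols(seq)
  nn <- !is.na(s)
  a <- s[-length(s)]
  b <- s[-1]
  self <- sum(!is.na(a) & !is.na(b) & a == b)
  list(
    n_records = sum(nn),
    n_regions = length(unique(s[nn])),
    n_self_transitions = if (length(s) < 2) 0L else as.integer(self)
  )
}

#' Filter users by record completeness and observation span
#'
#' Retains users whose hour-level fraction of missing records does not exceed
#' `q_max` and whose observation span covers at least `d_min_days`
#' consecutive days.
#'
#' @param population data.frame with one row per user and columns `q`
#'   (hour-level missing fraction) and `days` (observation span in days), or
#'   a list of such records.
#' @param q_max maximum tolerated missing fraction (default 0.15).
#' @param d_min_days minimum span in days (default 28).
#' @return the retained subset, same shape as the input.
#' @export
filter_users <- function(population, q_max = 0.15, d_min_days = 28) {
  if (is.data.frame(population)) {
    population[population$q <= q_max & population$days >= d_min_days, , drop = FALSE]
  } else {
    Filter(function(u) u$q <= q_max && u$days >= d_min_days, population)
  }
}

#' Temporal resolutions of the sweep
#'
#' The bin widths used for next time-bin sequences: 5, 10, 15, 30, 45 and
#' 60 minutes, then 6, 12, 24, 48, 72 and 144 hours (60 min and 1 h being
#' the same resolution appear once).
#'
#' @return increasing numeric vector of bin widths in seconds.
#' @export
delta_t_sweep_values <- function() {
  c(c(5, 10, 15, 30, 45, 60) * 60, c(6, 12, 24, 48, 72, 144) * 3600)
}
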