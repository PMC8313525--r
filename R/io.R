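#' Read and write trajectory files
#'
#' Trajectories are exchanged as comma-separated text with a header
#' `user_id,x,y,timestamp`, timestamps in ISO-8601 UTC. Coordinates are
#' metres on a planar metric frame; project lon/lat before writing.
#'
#' @param trajectory a [trajectory()].
#' @param path file path.
#' @return `read_trajectory()` returns a `trajectory`; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(
    user_id = trajectory$user_id,
    x = trajectory$x,
    y = trajectory$y,
    timestamp = format(trajectory$t, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "x", "y", "timestamp")
  if (!all(need %in% names(df))) {
    stopf("trajectory file must have columns %s", paste(need, collapse = ", "))
  }
  trajectory(df$user_id, df$x, df$y,
             as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
}

#' Read and write stay-point files
#'
#' Stay-points are exchanged as comma-separated text with header
#' `user_id,x,y,start,end` (ISO-8601 UTC).
#'
#' @param staypoints a [detect_staypoints()] result.
#' @param path file path.
#' @return `read_staypoints()` returns a `staypoints` data.frame;
#'   `write_staypoints()` returns `path` invisibly.
#' @export
write_staypoints <- function(staypoints, path) {
  df <- data.frame(
    user_id = attr(staypoints, "user_id") %||% NA_character_,
    x = staypoints$x,
    y = staypoints$y,
    start = format(staypoints$start, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    end = format(staypoints$end, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_staypoints
#' @export
read_staypoints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    x = df$x, y = df$y,
    start = as.POSIXct(df$start, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    end = as.POSIXct(df$end, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    n_points = if ("n_points" %in% names(df)) df$n_points else NA_integer_
  )
  attr(out, "user_id") <- df$user_id[1]
  class(out) <- c("staypoints", "data.frame")
  out
}

#' Write a region assignment as text
#'
#' One row per stay-point: `user_id,staypoint_index,region_id,region_x,
#' region_y`.
#'
#' @param assignment a `region_assignment`.
#' @param path file path.
#' @param user_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_region_assignment <- function(assignment, path, user_id = NA_character_) {
  centres <- assignment$centres
  idx <- match(assignment$labels, centres$region)
  df <- data.frame(
    user_id = user_id,
    staypoint_index = seq_along(assignment$labels),
    region_id = assignment$labels,
    region_x = centres$x[idx],
    region_y = centres$y[idx]
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a symbolic sequence as text
#'
#' Time-bin sequences are written one row per bin (`user_id,bin_start,
#' region_id`, empty region field for null bins); place sequences one row
#' per rank (`user_id,rank,region_id`).
#'
#' @param seq a `time_bin_sequence` or `place_sequence`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  if (inherits(seq, "time_bin_sequence")) {
    starts <- seq$origin + (seq_along(seq$symbols) - 1) * seq$delta_t
    df <- data.frame(
      user_id = seq$user_id,
      bin_start = format(starts, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
      region_id = ifelse(is.na(seq$symbols), "", as.character(seq$symbols))
    )
  } else if (inherits(seq, "place_sequence")) {
    df <- data.frame(
      user_id = seq$user_id,
      rank = seq_along(seq$symbols),
      region_id = seq$symbols
    )
  } else {
    stopf("seq must be a time_bin_sequence or place_sequence")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth visits as text
#'
#' Side-car file for synthetic trajectories: `anchor,start,end` plus an
#' `# anchors:` header comment carrying the anchor coordinates.
#'
#' @param truth the `truth` element of a [generate_trajectory()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  coords <- apply(truth$anchor_coords, 1, function(r) sprintf("%g %g", r[1], r[2]))
  writeLines(sprintf("# anchors: %s", paste(coords, collapse = ";")), con)
  df <- data.frame(
    anchor = truth$visits$anchor,
    start = format(truth$visits$start, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    end = format(truth$visits$end, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  )
  writeLines("anchor,start,end", con)
  writeLines(sprintf("%d,%s,%s", df$anchor, df$start, df$end), con)
  invisible(path)
}
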