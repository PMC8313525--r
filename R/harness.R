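#' Stay-point sequences for a whole population
#'
#' @param population a [simulate_population()] result, or a list of per-user
#'   lists containing a `trajectory`.
#' @param delta,tau stay-point detection thresholds (metres, seconds).
#' @return list of `staypoints` objects, one per user.
#' @export
population_staypoints <- function(population, delta = 300, tau = 600) {
  lapply(population, function(u) detect_staypoints(u$trajectory, delta, tau))
}

#' Median and interquartile range of a metric
#'
#' Quantiles use linear interpolation (R's default type 7); the IQR is
#' `Q3 - Q1`. `NA` values are dropped.
#'
#' @param values numeric vector.
#' @return named numeric vector `c(median, iqr)`.
#' @export
summarize_distribution <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) return(c(median = NA_real_, iqr = NA_real_))
  qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = qs[2], iqr = qs[3] - qs[1])
}

# Per-user metrics at one aggregation setting. Degenerate sequences (fewer
# than two non-null symbols) are retained with pi_max = 1 and flagged, never
# dropped: a one-symbol sequence is completely predictable by definition.
user_metrics <- function(sp, parameter, method, sequence_type, delta_t) {
  if (nrow(sp) == 0) return(NULL)
  assignment <- if (method == "grid") grid_aggregate(sp, parameter) else dbscan_aggregate(sp, parameter)
  visits <- region_visit_sequence(sp, assignment)
  seq <- if (sequence_type == "time_bin") {
    build_time_bin_sequence(visits, delta_t)
  } else {
    build_next_place_sequence(visits)
  }
  prof <- predictability_profile(seq)
  st <- sequence_stats(seq)
  geo <- region_geometry(sp, assignment)
  data.frame(
    user_id = attr(sp, "user_id") %||% NA_character_,
    pi_rand = prof$pi_rand, pi_unc = prof$pi_unc, pi_max = prof$pi_max,
    degenerate = prof$degenerate,
    n_records = st$n_records, n_regions = st$n_regions,
    n_self_transitions = st$n_self_transitions,
    q = if (sequence_type == "time_bin") compute_q(seq) else 0,
    median_region_area = median(geo$area),
    single_point_fraction = mean(geo$is_single_point)
  )
}

sweep_metrics <- c("pi_rand", "pi_unc", "pi_max", "n_records", "n_regions",
                   "n_self_transitions", "q", "median_region_area",
                   "single_point_fraction")

#' Spatial aggregation sweep over a population
#'
#' For every spatial parameter (grid spacing or clustering radius), the full
#' pipeline is run per user — aggregate stay-points into regions, build the
#' symbolic sequence, compute entropies, predictability bounds and sequence
#' properties — and each metric is summarised across users by median and
#' IQR.
#'
#' @param staypoints_list per-user stay-points from [population_staypoints()].
#' @param method `"grid"` or `"dbscan"`.
#' @param params spatial parameters in metres (default
#'   [parameter_sweep_values()]).
#' @param sequence_type `"time_bin"` or `"next_place"`.
#' @param delta_t bin width in seconds for time-bin sequences (default 1 h;
#'   ignored for next place sequences).
#' @return object of class `sweep_result`: list with `axis`, `results`
#'   (per-user rows) and `summary` (one row per parameter x metric:
#'   `parameter, metric, median, iqr`).
#' @export
run_spatial_sweep <- function(staypoints_list,
                              method = c("grid", "dbscan"),
                              params = parameter_sweep_values(),
                              sequence_type = c("time_bin", "next_place"),
                              delta_t = 3600) {
  method <- match.arg(method)
  sequence_type <- match.arg(sequence_type)
  res <- list()
  for (p in params) {
    per_user <- do.call(rbind, lapply(staypoints_list, user_metrics,
                                      parameter = p, method = method,
                                      sequence_type = sequence_type,
                                      delta_t = delta_t))
    per_user$parameter <- p
    res[[length(res) + 1L]] <- per_user
  }
  results <- do.call(rbind, res)
  new_sweep_result(paste0("spatial_", method), "parameter", results)
}

#' Temporal aggregation sweep over a population
#'
#' Runs the pipeline at a fixed spatial aggregation for every bin width in
#' `delta_t_values`, for next time-bin sequences only (the next place
#' representation has no temporal parameter).
#'
#' @param staypoints_list per-user stay-points.
#' @param delta_t_values bin widths in seconds (default
#'   [delta_t_sweep_values()]).
#' @param method,parameter the fixed spatial aggregation.
#' @return a `sweep_result` with `parameter` holding `delta_t` in seconds.
#' @export
run_temporal_sweep <- function(staypoints_list,
                               delta_t_values = delta_t_sweep_values(),
                               method = c("dbscan", "grid"),
                               parameter = 300) {
  method <- match.arg(method)
  res <- list()
  for (dt in delta_t_values) {
    per_user <- do.call(rbind, lapply(staypoints_list, user_metrics,
                                      parameter = parameter, method = method,
                                      sequence_type = "time_bin", delta_t = dt))
    per_user$parameter <- dt
    res[[length(res) + 1L]] <- per_user
  }
  results <- do.call(rbind, res)
  new_sweep_result("temporal", "delta_t", results)
}

new_sweep_result <- function(axis, parameter_name, results) {
  rownames(results) <- NULL
  summary <- do.call(rbind, lapply(split(results, results$parameter), function(g) {
    do.call(rbind, lapply(sweep_metrics, function(m) {
      s <- summarize_distribution(g[[m]])
      data.frame(parameter = g$parameter[1], metric = m,
                 median = s["median"], iqr = s["iqr"])
    }))
  }))
  rownames(summary) <- NULL
  structure(list(axis = axis, parameter_name = parameter_name,
                 results = results, summary = summary),
            class = "sweep_result")
}

#' Extract one metric's summary curve from a sweep
#'
#' @param sweep a `sweep_result`.
#' @param metric one of the per-user metric names (for example `"pi_max"`).
#' @return data.frame `parameter, median, iqr` ordered by parameter.
#' @export
sweep_curve <- function(sweep, metric) {
  s <- sweep$summary[sweep$summary$metric == metric, , drop = FALSE]
  s <- s[order(s$parameter), c("parameter", "median", "iqr")]
  rownames(s) <- NULL
  s
}

#' Descriptive least-squares fit of a scaling relationship
#'
#' Fits the requested functional forms to `(xs, ys)` and reports each fit's
#' coefficients and R-squared on the original scale. Forms: `linear`
#' (`y = a + b x`), `exponential` (`y = a exp(b x)`), `logarithmic`
#' (`y = a + b log(x)`). Used descriptively to characterise sweep curves,
#' never for inference. A response with (numerically) zero variance is a
#' perfect constant fit: R-squared 1 by convention.
#'
#' @param xs,ys numeric vectors.
#' @param forms subset of `c("exponential", "linear", "logarithmic")`.
#' @return data.frame `form, a, b, r_squared`, one row per form (failed fits
#'   reported with `NA`).
#' @export
fit_relationship <- function(xs, ys, forms = c("exponential", "linear", "logarithmic")) {
  forms <- match.arg(forms, several.ok = TRUE)
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  denom <- sum((ys - mean(ys))^2)
  r2 <- function(pred) if (denom <= 0) 1 else 1 - sum((ys - pred)^2) / denom
  one <- function(form) {
    fit <- tryCatch(switch(
      form,
      linear = {
        m <- lm(ys ~ xs)
        c(a = unname(coef(m)[1]), b = unname(coef(m)[2]), r_squared = r2(predict(m)))
      },
      logarithmic = {
        if (any(xs <= 0)) stopf("logarithmic form needs positive x")
        m <- lm(ys ~ log(xs))
        c(a = unname(coef(m)[1]), b = unname(coef(m)[2]), r_squared = r2(predict(m)))
      },
      exponential = {
        if (denom <= 0) {
          c(a = mean(ys), b = 0, r_squared = 1)
        } else {
          b0 <- if (all(ys > 0)) unname(coef(lm(log(ys) ~ xs))[2]) else 0.001
          a0 <- if (all(ys > 0)) exp(unname(coef(lm(log(ys) ~ xs))[1])) else mean(ys)
          m <- minpack.lm::nlsLM(ys ~ a * exp(b * xs), start = list(a = a0, b = b0),
                                 control = minpack.lm::nls.lm.control(maxiter = 200))
          c(coef(m)["a"], coef(m)["b"], r_squared = r2(predict(m)))
        }
      }
    ), error = function(e) c(a = NA_real_, b = NA_real_, r_squared = NA_real_))
    data.frame(form = form, a = fit[["a"]], b = fit[["b"]], r_squared = fit[["r_squared"]])
  }
  out <- do.call(rbind, lapply(forms, one))
  rownames(out) <- NULL
  out
}
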