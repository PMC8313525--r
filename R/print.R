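#' @export
print.mobility_config <- function(x, ...) {
  cat(sprintf("<mobility_config> %d anchors, %d days, dt=%gs, noise=%gm, target q=%.3f, seed=%d\n",
              x$n_anchors, x$duration_days, x$sampling_interval,
              x$gnss_noise_sigma, x$missing_fraction_target, x$seed))
  invisible(x)
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("<region_assignment> method=%s parameter=%g: %d stay-points in %d regions\n",
              x$method, x$parameter, length(x$labels), nrow(x$centres)))
  invisible(x)
}

#' @export
print.time_bin_sequence <- function(x, ...) {
  cat(sprintf("<time_bin_sequence> user=%s dt=%gs bins=%d q=%.3f\n",
              x$user_id, x$delta_t, length(x$symbols), mean(is.na(x$symbols))))
  invisible(x)
}

#' @export
print.place_sequence <- function(x, ...) {
  cat(sprintf("<place_sequence> user=%s length=%d distinct=%d\n",
              x$user_id, length(x$symbols), length(unique(x$symbols))))
  invisible(x)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> axis=%s: %d parameter values, %d user rows\n",
              x$axis, length(unique(x$results$parameter)), nrow(x$results)))
  invisible(x)
}

#' @export
print.delta_e_curve <- function(x, ...) {
  cat(sprintf("<delta_e_curve> %d reference users, %d levels, fit=%s (R^2=%.3f)\n",
              x$n_reference_users, nrow(x$levels), x$fit$form, x$fit$r_squared))
  invisible(x)
}
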