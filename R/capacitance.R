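#' Estimate the voltage slew rate of a CV trace
#'
#' Central differences at interior samples, one-sided differences at the two
#' endpoints. For an ideal triangular staircase the result equals
#' `+/- s_rate` exactly at every sample at least one step away from a vertex
#' (and 0 at the vertex itself).
#'
#' @param trace A [cv_trace()] (>= 3 samples).
#' @return Numeric vector of dv/dt (V/s), one value per sample.
#' @examples
#' wf <- build_waveform(cv_program())
#' tr <- cv_trace(wf$time_s, wf$voltage_V, rep(0, nrow(wf)))
#' range(estimate_dvdt(tr)) # -0.04 .. 0.04
#' @export
estimate_dvdt <- function(trace) {
  if (nrow(trace) < 3) stop_voltphen("dv/dt needs at least 3 samples.")
  t <- trace$time_s
  v <- trace$voltage_V
  n <- length(v)
  dvdt <- numeric(n)
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dvdt[1] <- (v[2] - v[1]) / (t[2] - t[1])
  dvdt[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  dvdt
}

# sample indices at which the sweep slope changes sign (the waveform vertices)
vertex_indices <- function(v) {
  s <- sign(diff(v))
  which(s[-1] * s[-length(s)] < 0) + 1L
}

#' Extract a capacitance trace from a CV current trace
#'
#' Implements the core computation `C(t) = i(t) / (dv/dt)(t)`: the capacitive
#' current of a cell suspension is proportional to the rate of change of the
#' applied potential, with the capacitance as the constant of
#' proportionality. The quotient is ill-conditioned where `dv/dt` approaches
#' zero, so samples are masked invalid when `|dv/dt|` falls below
#' `min_slope_frac` times its maximum or when they lie within
#' `vertex_exclusion` samples of a slope sign change (a sweep vertex). Valid
#' samples are optionally smoothed with a centred moving average applied
#' within each contiguous valid run only (the window truncates at run edges,
#' so no valid sample is lost). The i/dv-dt sign convention makes a passive
#' capacitive load positive on both sweep branches.
#'
#' @param trace A [cv_trace()].
#' @param vertex_exclusion Samples excluded on each side of a vertex (>= 0).
#' @param min_slope_frac Minimum `|dv/dt|` as a fraction of its maximum,
#'   in `[0, 1)`.
#' @param smooth_window Moving-average window in samples (1 = no smoothing).
#' @return A tibble of class `cap_trace` with columns `time_s`, `voltage_V`,
#'   `capacitance_F` (smoothed), `capacitance_raw_F` and `valid`; sample
#'   metadata plus the extraction settings are in the `"meta"` attribute.
#' @examples
#' tr <- simulate_trace(
#'   suspension_model(noise_sd = 0, faradaic_peak_i = 0, r_series = 0),
#'   cv_program()
#' )
#' ct <- extract_capacitance(tr)
#' range(ct$capacitance_F[ct$valid]) * 1e6 # 0.8 uF
#' @export
extract_capacitance <- function(trace, vertex_exclusion = 3,
                                min_slope_frac = 0.5, smooth_window = 5) {
  validate_cv_trace(trace)
  check_number(vertex_exclusion, "vertex_exclusion", min = 0)
  check_number(min_slope_frac, "min_slope_frac", min = 0)
  if (min_slope_frac >= 1) stop_voltphen("`min_slope_frac` must be < 1.")
  check_number(smooth_window, "smooth_window", min = 1)

  dvdt <- estimate_dvdt(trace)
  max_slope <- max(abs(dvdt))
  slope_ok <- abs(dvdt) >= min_slope_frac * max_slope & abs(dvdt) > 0

  vx <- vertex_indices(trace$voltage_V)
  if (length(vx)) {
    idx <- seq_len(nrow(trace))
    dist_to_vertex <- do.call(pmin, lapply(vx, function(v0) abs(idx - v0)))
    away <- dist_to_vertex > vertex_exclusion
  } else {
    away <- rep(TRUE, nrow(trace))
  }

  valid <- slope_ok & away
  if (!any(valid)) {
    stop_voltphen(sprintf(
      "no valid samples remain after masking (vertex_exclusion = %g, min_slope_frac = %g).",
      vertex_exclusion, min_slope_frac
    ))
  }

  c_raw <- rep(NA_real_, nrow(trace))
  c_raw[valid] <- trace$current_A[valid] / dvdt[valid]
  c_smooth <- apply_over_valid_runs(
    c_raw, valid,
    function(x) moving_average_truncated(x, smooth_window)
  )

  out <- tibble(
    time_s = trace$time_s,
    voltage_V = trace$voltage_V,
    capacitance_F = c_smooth,
    capacitance_raw_F = c_raw,
    valid = valid
  )
  attr(out, "meta") <- c(
    trace_meta(trace),
    list(
      vertex_exclusion = vertex_exclusion,
      min_slope_frac = min_slope_frac,
      smooth_window = smooth_window
    )
  )
  attr(out, "program") <- attr(trace, "program")
  class(out) <- c("cap_trace", class(tibble()))
  out
}

# value column used by peak/readout helpers, by trace flavour
value_column <- function(ctrace) {
  if ("capacitance_F" %in% names(ctrace)) "capacitance_F" else if
  ("rescaled_F" %in% names(ctrace)) "rescaled_F" else
    stop_voltphen("expected a capacitance or de-embedded trace.")
}

#' Time of the capacitance maximum
#'
#' Returns the time of the global maximum of the (smoothed) capacitance over
#' valid samples; ties break toward the earliest time. With the default
#' simulator settings the maximum sits on the cathodic reduction peak
#' (-0.2 V, i.e. ~27.5 s into the default descending sweep), mirroring the
#' empirically fixed reference time used in peak-time concentration
#' analysis.
#'
#' @param ctrace A `cap_trace` or `deembedded_trace`.
#' @return Peak time (s).
#' @export
find_peak_time <- function(ctrace) {
  col <- value_column(ctrace)
  if (!any(ctrace$valid)) stop_voltphen("trace has no valid samples.")
  vals <- ctrace[[col]]
  vals[!ctrace$valid] <- -Inf
  ctrace$time_s[which.max(vals)] # which.max takes the first (earliest) maximum
}

#' Capacitance at (or nearest to) a given time
#'
#' Value at the valid sample nearest to `t`; equidistant neighbours resolve
#' to the earlier sample.
#'
#' @param ctrace A `cap_trace` or `deembedded_trace`.
#' @param t Query time (s).
#' @param tolerance Maximum allowed |sample time - t| (s).
#' @return Capacitance (F) or de-embedded value at the nearest valid sample.
#' @export
capacitance_at <- function(ctrace, t, tolerance = 0.5) {
  col <- value_column(ctrace)
  check_number(t, "t")
  if (!(is.numeric(tolerance) && length(tolerance) == 1 && !is.na(tolerance) &&
        tolerance >= 0)) {
    stop_voltphen("`tolerance` must be a non-negative number (Inf allowed).")
  }
  ok <- which(ctrace$valid)
  if (!length(ok)) stop_voltphen("trace has no valid samples.")
  d <- abs(ctrace$time_s[ok] - t)
  k <- ok[which.min(d)]
  if (min(d) > tolerance) {
    stop_voltphen(sprintf(
      "no valid sample within %g s of t = %g s (nearest is %g s away).",
      tolerance, t, min(d)
    ))
  }
  ctrace[[col]][k]
}
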