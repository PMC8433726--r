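#' Define a cyclic-voltammetry excitation program
#'
#' A CV sweep is a triangular staircase: the applied potential moves between
#' `v_min` and `v_max` in increments of `e_step`, at a scan rate `s_rate`
#' (V/s), so each potential step lasts `e_step / s_rate` seconds. The default
#' program is the measurement protocol used throughout this package: a sweep
#' between -0.9 V and 0.9 V with `e_step` = 0.002 V at 0.04 V/s, starting at
#' the positive vertex and descending, giving 900 steps (45 s) per half-sweep
#' at 0.05 s per step.
#'
#' @param v_min,v_max Sweep vertex potentials (V); `v_max > v_min`.
#' @param e_step Potential increment per acquisition step (V), > 0. Must
#'   divide `v_max - v_min` to within a relative tolerance of 1e-6.
#' @param s_rate Scan rate (V/s), > 0.
#' @param start_vertex `"high"` (start at `v_max`, descending first — the
#'   default, matching a 0.9 V to -0.9 V sweep) or `"low"`.
#' @param n_cycles Number of full triangular cycles (positive integer).
#'
#' @return An object of class `cv_program`.
#' @examples
#' cv_program()
#' cv_program(0, 1, e_step = 0.5, s_rate = 1)
#' @export
cv_program <- function(v_min = -0.9, v_max = 0.9, e_step = 0.002,
                       s_rate = 0.04, start_vertex = c("high", "low"),
                       n_cycles = 1) {
  start_vertex <- match.arg(start_vertex)
  check_number(v_min, "v_min")
  check_number(v_max, "v_max")
  check_number(e_step, "e_step", min = 0, strict_min = TRUE)
  check_number(s_rate, "s_rate", min = 0, strict_min = TRUE)
  check_number(n_cycles, "n_cycles", min = 1)
  if (n_cycles != round(n_cycles)) {
    stop_voltphen("`n_cycles` must be a positive integer.")
  }
  if (v_max <= v_min) {
    stop_voltphen(sprintf("`v_max` (%g) must exceed `v_min` (%g).", v_max, v_min))
  }
  k <- (v_max - v_min) / e_step
  if (k < 1 - 1e-9) {
    stop_voltphen("(v_max - v_min)/e_step must be at least 1.")
  }
  if (abs(k - round(k)) > 1e-6 * max(1, k)) {
    stop_voltphen(sprintf(
      "`e_step` (%g V) does not evenly divide the sweep range %g V (%.6f steps); adjust e_step or the vertices.",
      e_step, v_max - v_min, k
    ))
  }
  structure(
    list(
      v_min = v_min, v_max = v_max, e_step = e_step, s_rate = s_rate,
      start_vertex = start_vertex, n_cycles = as.integer(n_cycles),
      n_steps_half = as.integer(round(k)),
      step_duration = e_step / s_rate
    ),
    class = "cv_program"
  )
}

#' @export
print.cv_program <- function(x, ...) {
  cat(sprintf(
    "<cv_program> %g V to %g V, E_step %g V, S_rate %g V/s (%g s/step)\n  start %s, %d cycle(s), %d steps per half-sweep\n",
    x$v_max, x$v_min, x$e_step, x$s_rate, x$step_duration,
    x$start_vertex, x$n_cycles, x$n_steps_half
  ))
  invisible(x)
}

#' Sample the triangular excitation waveform of a CV program
#'
#' Produces the staircase-sampled triangular wave: one sample per potential
#' step (sampled at the step end), plus the initial point. Between vertices
#' the finite-difference slope is exactly `+/- s_rate`; over a full cycle the
#' per-step voltage increments sum to zero.
#'
#' @param program A [cv_program()].
#' @return A tibble with columns `time_s` and `voltage_V` and
#'   `2 * n_steps_half * n_cycles + 1` rows, carrying the program in the
#'   `"program"` attribute.
#' @examples
#' wf <- build_waveform(cv_program())
#' nrow(wf) # 1801
#' @export
build_waveform <- function(program) {
  if (!inherits(program, "cv_program")) {
    stop_voltphen("`program` must be a cv_program.")
  }
  n <- program$n_steps_half
  j <- 0:(2L * n * program$n_cycles)
  # distance (in steps) from the starting vertex, folded triangularly
  d <- n - abs((j %% (2L * n)) - n)
  voltage <- if (program$start_vertex == "high") {
    program$v_max - d * program$e_step
  } else {
    program$v_min + d * program$e_step
  }
  out <- tibble(
    time_s = j * program$step_duration,
    voltage_V = voltage
  )
  attr(out, "program") <- program
  out
}
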