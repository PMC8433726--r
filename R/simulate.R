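#' Equivalent-circuit model of a cell suspension on a two-electrode CV cell
#'
#' The suspension is modelled as the cells-free electrode/media capacitance
#' `c_media` in parallel with the summed membrane capacitance of the
#' suspended cells: each cell contributes `c_spec * area`, with per-cell
#' effective membrane areas drawn log-normally around `a_cell` with
#' coefficient of variation `area_cv`, so
#' `C_tot = c_media + c_spec * sum(areas)`. A series resistance `r_series`
#' models the media/electrode access resistance, and a Gaussian-shaped
#' cathodic (reduction) Faradaic peak centred at `faradaic_peak_v` is added
#' on the negative-going branch only. Additive i.i.d. Gaussian current noise
#' completes the model.
#'
#' Defaults emulate the measurement conditions this package targets: a media
#' capacitance of 0.8 uF (so media-dominated totals sit in the 0.8-1.0 uF
#' range), the standard ~1 uF/cm^2 (0.01 F/m^2) specific membrane
#' capacitance, a reduction peak at -0.2 V, and a 50 pA current noise floor
#' (about 0.16% of the 32 nA media-level capacitive current at 0.04 V/s).
#'
#' @param c_media Cells-free electrode/media capacitance (F), > 0.
#' @param c_spec Specific membrane capacitance (F/m^2), > 0.
#' @param a_cell Mean per-cell effective membrane area (m^2), > 0. The
#'   default corresponds to a round 14-um cell (~600 um^2 of membrane).
#' @param area_cv Coefficient of variation of per-cell area, >= 0.
#' @param n_cells Cells per 500 uL sample volume, >= 0 (0 = media only).
#' @param r_series Series resistance (Ohm), >= 0.
#' @param faradaic_peak_v Reduction-peak centre potential (V).
#' @param faradaic_peak_i Reduction-peak current amplitude (A), >= 0.
#' @param faradaic_width Gaussian width of the peak in potential (V), > 0.
#' @param noise_sd Current noise standard deviation (A), >= 0.
#' @param seed Integer seed; identical models give bit-identical traces.
#' @return An object of class `suspension_model`.
#' @examples
#' suspension_model(n_cells = 1000)
#' @export
suspension_model <- function(c_media = 0.8e-6, c_spec = 0.01, a_cell = 6e-10,
                             area_cv = 0.2, n_cells = 0, r_series = 100,
                             faradaic_peak_v = -0.2, faradaic_peak_i = 2e-9,
                             faradaic_width = 0.05, noise_sd = 5e-11,
                             seed = 1L) {
  check_number(c_media, "c_media", min = 0, strict_min = TRUE)
  check_number(c_spec, "c_spec", min = 0, strict_min = TRUE)
  check_number(a_cell, "a_cell", min = 0, strict_min = TRUE)
  check_number(area_cv, "area_cv", min = 0)
  check_number(n_cells, "n_cells", min = 0)
  if (n_cells != round(n_cells)) stop_voltphen("`n_cells` must be a whole number.")
  check_number(r_series, "r_series", min = 0)
  check_number(faradaic_peak_v, "faradaic_peak_v")
  check_number(faradaic_peak_i, "faradaic_peak_i", min = 0)
  check_number(faradaic_width, "faradaic_width", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(
      c_media = c_media, c_spec = c_spec, a_cell = a_cell, area_cv = area_cv,
      n_cells = as.double(n_cells), r_series = r_series,
      faradaic_peak_v = faradaic_peak_v, faradaic_peak_i = faradaic_peak_i,
      faradaic_width = faradaic_width, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "suspension_model"
  )
}

#' @export
print.suspension_model <- function(x, ...) {
  cat(sprintf(
    "<suspension_model> c_media %.3g uF, %g cells x c_spec %g F/m^2 (mean area %.3g um^2, CV %g)\n  r_series %g Ohm, Faradaic peak %g A at %g V (width %g V), noise %g A, seed %d\n",
    x$c_media * 1e6, x$n_cells, x$c_spec, x$a_cell * 1e12, x$area_cv,
    x$r_series, x$faradaic_peak_i, x$faradaic_peak_v, x$faradaic_width,
    x$noise_sd, x$seed
  ))
  invisible(x)
}

lognormal_params <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_cell_areas <- function(n_cells, mean_area, area_cv) {
  if (n_cells == 0) return(double(0))
  if (area_cv == 0) return(rep(mean_area, n_cells))
  p <- lognormal_params(mean_area, area_cv)
  rlnorm(n_cells, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Simulate a CV current trace for a suspension model
#'
#' The applied staircase waveform comes from [build_waveform()]. With
#' `r_series = 0` the capacitive current is `C_tot * dv/dt` (the staircase
#' branch slope, `+/- s_rate`). With `r_series > 0` the capacitor voltage
#' follows the RC relaxation `C_tot dv_c/dt = (v - v_c)/r_series`, integrated
#' exactly on the acquisition grid (per-step exponential update, which is the
#' closed-form response to a staircase input and stable for any step
#' duration); the reported current is the mean charging current over each
#' step, `C_tot * delta(v_c)/delta(t)`, which reduces to `C_tot * s_rate`
#' when the RC time constant is much shorter than the step. The cathodic
#' Faradaic peak and Gaussian noise are then added. Identical
#' (model, program) inputs give bit-identical traces.
#'
#' @param model A [suspension_model()].
#' @param program A [cv_program()].
#' @param meta Optional named list merged into the trace metadata
#'   (`sample_id`, `cell_type`, `concentration`, `replicate`).
#' @return A [cv_trace()].
#' @examples
#' tr <- simulate_trace(suspension_model(noise_sd = 0), cv_program())
#' max(abs(tr$current_A)) # ~ 0.8 uF * 0.04 V/s = 32 nA (plus the -0.2 V peak)
#' @export
simulate_trace <- function(model, program, meta = list()) {
  if (!inherits(model, "suspension_model")) stop_voltphen("`model` must be a suspension_model.")
  wf <- build_waveform(program)
  v <- wf$voltage_V
  t <- wf$time_s
  n <- length(v)
  dt <- program$step_duration

  draws <- withr::with_seed(model$seed, {
    list(
      areas = draw_cell_areas(model$n_cells, model$a_cell, model$area_cv),
      noise = if (model$noise_sd > 0) rnorm(n, 0, model$noise_sd) else double(n)
    )
  })
  c_tot <- model$c_media + model$c_spec * sum(draws$areas)

  slope <- c(NA_real_, diff(v) / dt)
  slope[1] <- slope[2]

  if (model$r_series == 0) {
    i_cap <- c_tot * slope
  } else {
    tau <- model$r_series * c_tot
    alpha <- exp(-dt / tau)
    # v_c[k] = (1 - alpha) v[k] + alpha v_c[k-1], v_c[1] = v[1]
    v_c <- c(v[1], stats::filter((1 - alpha) * v[-1],
      filter = alpha,
      method = "recursive", init = v[1]
    ))
    i_cap <- c_tot * c(NA_real_, diff(v_c)) / dt
    i_cap[1] <- i_cap[2]
  }

  i_far <- -model$faradaic_peak_i *
    exp(-0.5 * ((v - model$faradaic_peak_v) / model$faradaic_width)^2) *
    (slope < 0)

  meta_full <- utils::modifyList(
    list(
      sample_id = "sim",
      cell_type = if (model$n_cells == 0) "MEDIA" else "UNKNOWN",
      concentration = model$n_cells,
      replicate = 1,
      c_tot_F = c_tot,
      seed = model$seed
    ),
    meta
  )

  cv_trace(
    time_s = t, voltage_V = v,
    current_A = i_cap + i_far + draws$noise,
    meta = meta_full, program = program
  )
}

#' Simulate a concentration series of CV traces
#'
#' One trace per requested concentration (cells per 500 uL), each with its
#' own deterministic sub-seed derived from the model's master seed and the
#' trace index. A 0-cell entry is the cells-free media trace and is labelled
#' `cell_type = "MEDIA"`.
#'
#' @param model A [suspension_model()]; its `n_cells` is overridden per trace.
#' @param program A [cv_program()].
#' @param concentrations Non-negative cell counts per 500 uL; default is the
#'   dilution series 0 (media) and 10 to 1e5.
#' @param cell_type Label applied to the non-media traces.
#' @param sample_id_prefix Prefix for per-trace sample ids.
#' @return A named list of [cv_trace()] (names = concentrations).
#' @examples
#' series <- simulate_concentration_series(
#'   suspension_model(noise_sd = 0), cv_program(),
#'   concentrations = c(0, 10, 100)
#' )
#' names(series)
#' @export
simulate_concentration_series <- function(model, program,
                                          concentrations = c(0, 10, 1e2, 1e3, 1e4, 1e5),
                                          cell_type = "THP1",
                                          sample_id_prefix = cell_type) {
  if (length(concentrations) == 0) stop_voltphen("`concentrations` must be non-empty.")
  if (any(concentrations < 0)) stop_voltphen("`concentrations` must be non-negative.")
  traces <- imap(as.list(concentrations), function(conc, i) {
    m <- model
    m$n_cells <- as.double(conc)
    m$seed <- derive_seed(model$seed, i)
    simulate_trace(m, program, meta = list(
      sample_id = sprintf("%s_c%g", sample_id_prefix, conc),
      cell_type = if (conc == 0) "MEDIA" else cell_type,
      concentration = conc
    ))
  })
  setNames(traces, as.character(concentrations))
}
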