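# shared fixtures: everything is generated in code, nothing is read from disk

# the canonical measurement program: 0.9 -> -0.9 V, E_step 2 mV, 0.04 V/s
paper_program <- function(...) cv_program(-0.9, 0.9, 0.002, 0.04, ...)

# a short program for cheap tests: 20 steps per half-sweep, 0.05 s/step
small_program <- function(...) cv_program(0, 1, e_step = 0.05, s_rate = 1, ...)

# an ideal capacitor of total capacitance C (no cells, no peak, no noise)
pure_capacitor <- function(C, r_series = 0, noise_sd = 0, seed = 1L) {
  suspension_model(
    c_media = C, n_cells = 0, noise_sd = noise_sd,
    faradaic_peak_i = 0, r_series = r_series, seed = seed
  )
}

# hand-assembled capacitance trace (for readout/peak helpers)
make_cap_trace <- function(time_s, capacitance_F, valid = rep(TRUE, length(time_s)),
                           meta = list()) {
  out <- tibble::tibble(
    time_s = time_s,
    voltage_V = rep(0, length(time_s)),
    capacitance_F = capacitance_F,
    capacitance_raw_F = capacitance_F,
    valid = valid
  )
  attr(out, "meta") <- meta
  class(out) <- c("cap_trace", class(tibble::tibble()))
  out
}

make_response <- function(cell_type, concentration, capacitance_F, reference_time = 27.5) {
  out <- tibble::tibble(
    cell_type = cell_type,
    concentration = concentration,
    capacitance_F = capacitance_F
  )
  attr(out, "reference_time") <- reference_time
  class(out) <- c("concentration_response", class(tibble::tibble()))
  out
}
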