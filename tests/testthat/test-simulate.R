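test_that("an ideal capacitor draws i = C * S_rate on every non-vertex sample", {
  prog <- paper_program()
  tr <- simulate_trace(pure_capacitor(1e-6), prog)
  expect_true(all(abs(abs(tr$current_A) - 1e-6 * 0.04) < 1e-19)) # 40 nA everywhere

  tr2 <- simulate_trace(pure_capacitor(0.8e-6), prog)
  expect_true(all(abs(abs(tr2$current_A) - 3.2e-8) < 1e-19))

  # sign follows the sweep direction: cathodic (negative) on the descent
  expect_true(all(tr$current_A[2:900] < 0))
  expect_true(all(tr$current_A[902:1801] > 0))
})

test_that("capacitive current is linear in C_tot and s_rate", {
  for (sr in c(0.02, 0.2)) {
    prog <- cv_program(0, 1, 0.05, sr)
    i1 <- simulate_trace(pure_capacitor(1e-6), prog)$current_A
    i2 <- simulate_trace(pure_capacitor(3e-6), prog)$current_A
    expect_equal(i2, 3 * i1, tolerance = 1e-12)
    expect_equal(max(abs(i1)), 1e-6 * sr, tolerance = 1e-12)
  }
})

test_that("series resistance produces the closed-form staircase RC response", {
  # tau comparable to the step duration so relaxation spans many samples
  prog <- cv_program(0, 1, e_step = 0.01, s_rate = 1) # dt = 0.01 s
  C <- 1e-6
  R <- 1e4 # tau = 10 ms = dt
  tr <- simulate_trace(pure_capacitor(C, r_series = R), prog)

  # independent oracle: exact capacitor voltage under a staircase input,
  # stepped sample by sample with the analytic exponential solution
  v <- build_waveform(prog)$voltage_V
  dt <- prog$step_duration
  a <- exp(-dt / (R * C))
  vc <- numeric(length(v))
  vc[1] <- v[1]
  for (k in 2:length(v)) vc[k] <- v[k] + (vc[k - 1] - v[k]) * a
  i_oracle <- C * c(NA, diff(vc)) / dt
  i_oracle[1] <- i_oracle[2]

  expect_equal(tr$current_A, i_oracle, tolerance = 1e-12)

  # after the vertex the current relaxes toward the new branch value with
  # time constant R*C: check the normalized residual decays as exp(-k dt/tau)
  vertex <- prog$n_steps_half + 1
  i_inf <- C * prog$s_rate # asymptotic ascending-branch current
  resid <- i_inf - tr$current_A[(vertex + 1):(vertex + 8)]
  ratios <- resid[-1] / resid[-length(resid)]
  expect_equal(ratios, rep(a, 7), tolerance = 1e-9)
})

test_that("traces are deterministic in the seed and noise superposes exactly", {
  prog <- small_program()
  m <- suspension_model(n_cells = 200, noise_sd = 1e-10, seed = 7)
  expect_identical(
    simulate_trace(m, prog)$current_A,
    simulate_trace(m, prog)$current_A
  )
  m2 <- m
  m2$seed <- 8L
  expect_false(identical(simulate_trace(m, prog)$current_A, simulate_trace(m2, prog)$current_A))

  # superposition: adding the Faradaic peak changes the current by exactly
  # the Gaussian peak shape, leaving cell-area draws and noise untouched
  m_no_peak <- suspension_model(n_cells = 200, noise_sd = 1e-10, faradaic_peak_i = 0, seed = 7)
  t_peak <- simulate_trace(m, prog)
  t_flat <- simulate_trace(m_no_peak, prog)
  diff_i <- t_peak$current_A - t_flat$current_A
  slope <- c(NA, diff(t_peak$voltage_V)) / prog$step_duration
  slope[1] <- slope[2]
  i_f <- -m$faradaic_peak_i *
    exp(-0.5 * ((t_peak$voltage_V - m$faradaic_peak_v) / m$faradaic_width)^2) *
    (slope < 0)
  expect_true(all(abs(diff_i - i_f) < 1e-18))
})

test_that("concentration series have closed-form amplitudes and media labelling", {
  prog <- small_program()
  m <- suspension_model(
    c_media = 0.8e-6, c_spec = 0.01, a_cell = 1e-9, area_cv = 0,
    noise_sd = 0, faradaic_peak_i = 0, r_series = 0, seed = 3
  )
  concs <- c(0, 10, 100, 1000, 10000, 100000)
  series <- simulate_concentration_series(m, prog, concs, cell_type = "MAC")
  expect_length(series, 6)
  expect_equal(trace_meta(series[["0"]])$cell_type, "MEDIA")
  expect_equal(trace_meta(series[["1000"]])$cell_type, "MAC")

  # amplitude oracle: (c_media + n * c_spec * a_cell) * s_rate
  amp <- vapply(series, function(tr) max(abs(tr$current_A)), numeric(1))
  expected <- (0.8e-6 + concs * 0.01 * 1e-9) * prog$s_rate
  expect_equal(unname(amp), expected, tolerance = 1e-12)
  expect_true(all(diff(amp) > 0)) # strictly increasing with count

  expect_error(simulate_concentration_series(m, prog, numeric(0)), "non-empty")
  expect_error(simulate_concentration_series(m, prog, c(-5, 10)), "non-negative")
})

test_that("model invariants are enforced at construction", {
  expect_error(suspension_model(c_media = 0), "c_media")
  expect_error(suspension_model(n_cells = -1), "n_cells")
  expect_error(suspension_model(n_cells = 2.5), "whole number")
  expect_error(suspension_model(faradaic_width = 0), "faradaic_width")
  expect_error(suspension_model(noise_sd = -1), "noise_sd")
})
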