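test_that("dv/dt recovers the staircase slope and analytic derivatives", {
  prog <- paper_program()
  wf <- build_waveform(prog)
  tr <- cv_trace(wf$time_s, wf$voltage_V, rep(0, nrow(wf)))
  dvdt <- estimate_dvdt(tr)
  expect_equal(dvdt[500], -0.04) # mid descending branch
  expect_equal(dvdt[1400], 0.04) # mid ascending branch
  expect_equal(dvdt[901], 0) # vertex

  flat <- cv_trace(seq(0, 1, by = 0.1), rep(0.3, 11), rep(0, 11))
  expect_equal(estimate_dvdt(flat), rep(0, 11))

  # central differences are exact for quadratic voltage profiles
  t <- seq(0, 2, by = 0.05)
  v <- 0.3 * t^2 - 0.2 * t + 0.1
  quad <- cv_trace(t, v, rep(0, length(t)))
  analytic <- 0.6 * t - 0.2
  d <- estimate_dvdt(quad)
  expect_equal(d[-c(1, length(d))], analytic[-c(1, length(d))], tolerance = 1e-10)

  expect_error(estimate_dvdt(flat[1:2, ]), "at least 3")
})

test_that("extraction inverts the simulator exactly for an ideal capacitor", {
  prog <- paper_program()
  ct <- extract_capacitance(simulate_trace(pure_capacitor(1e-6), prog))
  vals <- ct$capacitance_F[ct$valid]
  expect_true(all(abs(vals - 1e-6) < 1e-9 * 1e-6)) # far below 0.1%
  expect_gt(sum(ct$valid), 1700)

  # zero current -> zero capacitance at all valid samples
  wf <- build_waveform(prog)
  z <- extract_capacitance(cv_trace(wf$time_s, wf$voltage_V, rep(0, nrow(wf))))
  expect_true(all(z$capacitance_F[z$valid] == 0))
})

test_that("extracted capacitance is scan-rate invariant for a pure capacitor", {
  for (sr in c(0.004, 0.04, 0.4)) {
    prog <- cv_program(-0.9, 0.9, 0.002, sr)
    ct <- extract_capacitance(simulate_trace(pure_capacitor(1e-6), prog))
    expect_equal(median(ct$capacitance_F[ct$valid]), 1e-6, tolerance = 1e-3)
  }
})

test_that("the Faradaic peak biases the cathodic branch by at most i_f / s_rate", {
  prog <- paper_program()
  C <- 0.9e-6
  m <- suspension_model(
    c_media = C, n_cells = 0, noise_sd = 0, r_series = 0,
    faradaic_peak_i = 3e-9, faradaic_peak_v = -0.2, faradaic_width = 0.05
  )
  ct <- extract_capacitance(simulate_trace(m, prog), smooth_window = 1)
  v <- ct$voltage_V
  # on the descending branch dv/dt < 0 and the cathodic peak adds i_f/s_rate
  offset <- 3e-9 / 0.04 * exp(-0.5 * ((v - (-0.2)) / 0.05)^2)
  desc <- ct$valid & seq_len(nrow(ct)) <= 901
  asc <- ct$valid & seq_len(nrow(ct)) > 901
  expect_true(all(abs(ct$capacitance_raw_F[desc] - C - offset[desc]) < 1e-15))
  expect_true(all(abs(ct$capacitance_raw_F[desc] - C) <= offset[desc] + 1e-15))
  # anodic branch is unbiased
  expect_true(all(abs(ct$capacitance_raw_F[asc] - C) < 1e-12 * C))
  # equality at the peak centre
  centre <- which(ct$valid & abs(v + 0.2) < 1e-9 & seq_len(nrow(ct)) <= 901)
  expect_equal(ct$capacitance_raw_F[centre], C + 3e-9 / 0.04, tolerance = 1e-9)
})

test_that("extraction is positive for passive noise-free suspensions", {
  prog <- paper_program()
  for (n in c(0, 100, 1e4)) {
    m <- suspension_model(n_cells = n, noise_sd = 0, seed = 5)
    ct <- extract_capacitance(simulate_trace(m, prog))
    expect_true(all(ct$capacitance_F[ct$valid] > 0))
  }
})

test_that("masking failures and bad parameters are reported explicitly", {
  flat <- cv_trace(seq(0, 1, by = 0.1), rep(0.3, 11), rep(1e-9, 11))
  expect_error(extract_capacitance(flat), "no valid samples")
  tr <- simulate_trace(pure_capacitor(1e-6), small_program())
  expect_error(extract_capacitance(tr, min_slope_frac = 1), "min_slope_frac")
  expect_error(extract_capacitance(tr, vertex_exclusion = -1), "vertex_exclusion")
})

test_that("peak time takes the earliest global maximum over valid samples", {
  # single injected maximum at the canonical 29.2 s reference
  t <- seq(0, 90, by = 0.05)
  cap <- 0.8e-6 + 0.1e-6 * exp(-0.5 * ((t - 29.2) / 2)^2)
  ct <- make_cap_trace(t, cap)
  expect_equal(find_peak_time(ct), 29.2)

  # constant capacitance -> earliest valid time (tie rule)
  flat <- make_cap_trace(t, rep(1e-6, length(t)), valid = t >= 10)
  expect_equal(find_peak_time(flat), 10)

  # random series agree with a brute-force scan
  set.seed(99)
  for (rep in 1:20) {
    vals <- runif(50)
    valid <- runif(50) > 0.3
    valid[1] <- TRUE
    ct <- make_cap_trace(seq(0, 4.9, by = 0.1), vals, valid)
    idx <- which(valid)
    oracle <- idx[which.max(vals[idx])]
    expect_equal(find_peak_time(ct), ct$time_s[oracle])
  }
})

test_that("capacitance_at reads the nearest valid sample within tolerance", {
  t <- seq(0, 10, by = 0.5)
  vals <- seq_along(t) * 1e-8
  ct <- make_cap_trace(t, vals)
  expect_equal(capacitance_at(ct, 2.0), vals[5]) # exact grid time
  expect_equal(capacitance_at(ct, 2.2), vals[5]) # nearer neighbour
  expect_equal(capacitance_at(ct, 2.3), vals[6])

  # randomized queries agree with a brute-force nearest-valid search
  set.seed(7)
  valid <- runif(length(t)) > 0.4
  valid[3] <- TRUE
  ctv <- make_cap_trace(t, vals, valid)
  for (q in runif(20, 0, 10)) {
    idx <- which(valid)
    oracle <- idx[which.min(abs(t[idx] - q))]
    expect_equal(capacitance_at(ctv, q, tolerance = Inf), vals[oracle])
  }
  expect_error(capacitance_at(ctv, 100, tolerance = 0.5), "no valid sample within")
})
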