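test_that("noise-free concentration responses equal the closed-form C_tot values", {
  prog <- paper_program()
  base <- suspension_model(
    c_media = 0.8e-6, c_spec = 0.01, a_cell = 2e-9, area_cv = 0,
    noise_sd = 0, faradaic_peak_i = 0, r_series = 0, seed = 1
  )
  concs <- c(10, 100, 1000)
  series <- simulate_concentration_series(base, prog, concs, cell_type = "DC")
  cts <- lapply(series, extract_capacitance)
  resp <- build_concentration_response(cts)
  expected <- 0.8e-6 + concs * 0.01 * 2e-9
  expect_equal(resp$capacitance_F, expected, tolerance = 1e-9)
  expect_equal(resp$concentration, concs)
  expect_equal(resp$cell_type, rep("DC", 3))
})

test_that("reference-time policies behave as specified", {
  t <- seq(0, 90, by = 0.05)
  bump <- function(center) 0.8e-6 + 1e-7 * exp(-0.5 * ((t - center) / 1)^2)
  tr1 <- make_cap_trace(t, bump(29.2), meta = list(cell_type = "THP1", concentration = 10))
  tr2 <- make_cap_trace(t, bump(29.2), meta = list(cell_type = "THP1", concentration = 100))

  # single trace: response of length 1 at its own peak time
  r1 <- build_concentration_response(list(tr1))
  expect_equal(nrow(r1), 1)
  expect_equal(attr(r1, "reference_time"), 29.2)

  # fixed reference time 29.2 s: readings at the nearest valid samples
  r2 <- build_concentration_response(list(tr1, tr2),
    peak_policy = "fixed", reference_time = 29.2
  )
  at_292 <- bump(29.2)[which.min(abs(t - 29.2))]
  expect_equal(r2$capacitance_F, c(at_292, at_292))

  # mixed cell types are refused
  tr3 <- make_cap_trace(t, bump(20), meta = list(cell_type = "MAC", concentration = 50))
  expect_error(build_concentration_response(list(tr1, tr3)), "mix cell types")
  expect_error(
    build_concentration_response(list(tr1, tr1)),
    "distinct"
  )
})

test_that("monotonicity checks match a brute-force pairwise comparison", {
  r <- make_response("THP1", c(10, 100, 1000), c(1, 2, 3) * 1e-6)
  chk <- check_monotonicity(r)
  expect_true(chk$monotone)
  expect_true(chk$strictly_increasing)

  r2 <- make_response("THP1", c(10, 100, 1000, 10000), c(1, 2, 1.5, 3) * 1e-6)
  chk2 <- check_monotonicity(r2)
  expect_false(chk2$monotone)
  bad <- chk2$steps[chk2$steps$delta_F < 0, ]
  expect_equal(bad$from_concentration, 100) # offending step identified
  expect_equal(bad$to_concentration, 1000)

  set.seed(42)
  for (k in 1:25) {
    vals <- sample(c(1, 2, 2, 3, 5)) * 1e-6
    r3 <- make_response("DC", c(1, 10, 100, 1000, 10000), vals)
    # brute-force O(n^2) oracle: every later reading at least as large
    pairs_ok <- outer(seq_along(vals), seq_along(vals), function(i, j) {
      vals[i] <= vals[j] | i >= j
    })
    oracle <- all(pairs_ok)
    expect_equal(check_monotonicity(r3)$monotone, oracle)
  }

  expect_error(check_monotonicity(make_response("X", 10, 1e-6)), "at least 2")
})

test_that("phenotype summaries compute means and SEM by the standard formulas", {
  r_flat <- make_response("THP1", c(10, 100, 1000), c(1, 1, 1) * 1e-6)
  s1 <- summarize_phenotype(list(r_flat))
  expect_equal(s1$mean_F, 1e-6)
  expect_equal(s1$sem_F, 0)

  r <- make_response("DC", c(10, 100, 1000), c(0.9, 1.0, 1.1) * 1e-6)
  s2 <- summarize_phenotype(list(r))
  expect_equal(s2$mean_F, 1.0e-6)
  expect_equal(s2$sem_F, sd(c(0.9, 1.0, 1.1) * 1e-6) / sqrt(3)) # hand formula

  # only the k_lowest smallest concentrations enter the average
  r4 <- make_response("MAC", c(10, 100, 1000, 1e5), c(1, 2, 3, 100) * 1e-6)
  s3 <- summarize_phenotype(list(r4), k_lowest = 3)
  expect_equal(s3$mean_F, 2e-6)
  expect_equal(attr(s3, "concentrations_used")$MAC, c(10, 100, 1000))

  expect_error(summarize_phenotype(list(r), k_lowest = 5), "k_lowest")

  # SEM conservation: sem^2 * k equals the sample variance of the readings
  set.seed(11)
  vals <- runif(3) * 1e-6
  s4 <- summarize_phenotype(list(make_response("THP1", c(1, 2, 3), vals)))
  expect_equal(s4$sem_F^2 * 3, var(vals))
})

test_that("summaries and classification are invariant to input order", {
  rs <- list(
    THP1 = make_response("THP1", c(10, 100, 1000), c(0.82, 0.83, 0.84) * 1e-6),
    DC = make_response("DC", c(10, 100, 1000), c(0.92, 0.93, 0.94) * 1e-6),
    MAC = make_response("MAC", c(10, 100, 1000), c(1.00, 1.01, 1.02) * 1e-6)
  )
  s_fwd <- summarize_phenotype(rs)
  s_rev <- summarize_phenotype(rev(rs))
  expect_equal(as.data.frame(s_fwd), as.data.frame(s_rev))
  expect_equal(s_fwd$cell_type, c("MAC", "DC", "THP1"))
  expect_equal(s_fwd$rank, 1:3)

  c_fwd <- classify_by_size_order(s_fwd)
  c_rev <- classify_by_size_order(s_rev)
  expect_equal(as.data.frame(c_fwd), as.data.frame(c_rev))
})

test_that("size-order classification assigns MAC > DC > THP1 and refuses ties", {
  mk <- function(means, names = c("A", "B", "C")) {
    out <- tibble::tibble(
      cell_type = names, mean_F = means,
      sem_F = 0, n_used = 3L, rank = rank(-means)
    )
    class(out) <- c("phenotype_summary", class(tibble::tibble()))
    out
  }
  # canonical means (1.01 / 0.93 / 0.83 uF) in every input order
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    means <- (c(1.01, 0.93, 0.83) * 1e-6)[perm]
    names <- c("s_mac", "s_dc", "s_thp")[perm]
    cls <- classify_by_size_order(mk(means, names))
    expect_equal(attr(cls, "status"), "ok")
    expect_equal(cls$assigned, c("MAC", "DC", "THP1")) # rows in descending order
    expect_equal(cls$sample[cls$assigned == "MAC"], "s_mac")
    expect_equal(cls$sample[cls$assigned == "DC"], "s_dc")
    expect_equal(cls$sample[cls$assigned == "THP1"], "s_thp")
  }

  tie <- classify_by_size_order(mk(c(1, 1, 1) * 1e-6))
  expect_equal(attr(tie, "status"), "inconclusive")
  expect_true(all(is.na(tie$assigned)))

  # random distinct triples match a sorting oracle
  set.seed(5)
  for (k in 1:25) {
    means <- sort(runif(3, 0.5, 2) * 1e-6, decreasing = TRUE)
    shuffled <- sample(means)
    cls <- classify_by_size_order(mk(shuffled))
    oracle <- c("MAC", "DC", "THP1")[rank(-shuffled)]
    got <- setNames(cls$assigned, cls$sample)[mk(shuffled)$cell_type]
    expect_equal(unname(got), oracle)
  }

  expect_error(classify_by_size_order(mk(c(1, 2) * 1e-6, c("A", "B"))), "exactly three")
})
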