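#' Build the concentration-response of one cell type
#'
#' Reduces a set of capacitance (or de-embedded) traces, one per
#' concentration, to one reading each at a common reference time: by default
#' the median of the per-trace capacitance peak times (each trace's maximum
#' falls at essentially the same time when the Faradaic peak dominates), or
#' a user-fixed time such as the 29.2 s reference used in the measurements
#' this package models.
#'
#' @param ctraces List of `cap_trace` or `deembedded_trace` objects sharing a
#'   cell type, each carrying a distinct `concentration` in its metadata.
#' @param peak_policy `"median"` (reference time = median of per-trace peak
#'   times) or `"fixed"` (use `reference_time`).
#' @param reference_time Required when `peak_policy = "fixed"` (s).
#' @param tolerance Readout tolerance passed to [capacitance_at()] (s).
#' @return A tibble of class `concentration_response` with columns
#'   `cell_type`, `concentration` (strictly increasing), `capacitance_F`;
#'   the reference time is in the `"reference_time"` attribute.
#' @export
build_concentration_response <- function(ctraces,
                                         peak_policy = c("median", "fixed"),
                                         reference_time = NULL,
                                         tolerance = 0.5) {
  peak_policy <- match.arg(peak_policy)
  if (!length(ctraces)) stop_voltphen("`ctraces` must be a non-empty list.")

  meta <- map(ctraces, ~ attr(.x, "meta") %||% list())
  types <- map_chr(meta, ~ as.character(.x$cell_type %||% NA_character_))
  concs <- map_dbl(meta, ~ as.double(.x$concentration %||% NA_real_))
  if (anyNA(concs)) stop_voltphen("every trace needs a `concentration` in its metadata.")
  utypes <- unique(types[!is.na(types)])
  if (length(utypes) > 1) {
    stop_voltphen(sprintf(
      "traces mix cell types (%s); build one response per type.",
      paste(utypes, collapse = ", ")
    ))
  }
  if (anyDuplicated(concs)) stop_voltphen("concentrations must be distinct.")

  ref <- if (peak_policy == "median") {
    median(map_dbl(ctraces, find_peak_time))
  } else {
    if (is.null(reference_time)) {
      stop_voltphen("`reference_time` is required with peak_policy = \"fixed\".")
    }
    reference_time
  }

  readings <- map_dbl(ctraces, capacitance_at, t = ref, tolerance = tolerance)

  ord <- order(concs)
  out <- tibble(
    cell_type = if (length(utypes)) utypes else NA_character_,
    concentration = unname(concs[ord]),
    capacitance_F = unname(readings[ord])
  )
  attr(out, "reference_time") <- ref
  class(out) <- c("concentration_response", class(tibble()))
  out
}

#' Check that capacitance increases with concentration
#'
#' More cells mean more total membrane area, and capacitance is proportional
#' to area, so readings should not decrease across an ordered concentration
#' series. Returns the verdict together with the per-step differences for
#' diagnostics (a non-monotone step at high concentration typically signals
#' a sample-preparation problem, not a method failure).
#'
#' @param response A [build_concentration_response()] result (>= 2 rows).
#' @return A list of class `monotonicity_check`: `monotone` (non-decreasing),
#'   `strictly_increasing`, and a `steps` tibble (`from_concentration`,
#'   `to_concentration`, `delta_F`, `increase`).
#' @export
check_monotonicity <- function(response) {
  if (nrow(response) < 2) stop_voltphen("a response needs at least 2 concentrations.")
  delta <- diff(response$capacitance_F)
  steps <- tibble(
    from_concentration = head(response$concentration, -1),
    to_concentration = tail(response$concentration, -1),
    delta_F = delta,
    increase = delta > 0
  )
  structure(
    list(
      monotone = all(delta >= 0),
      strictly_increasing = all(delta > 0),
      steps = steps
    ),
    class = "monotonicity_check"
  )
}

#' @export
print.monotonicity_check <- function(x, ...) {
  cat(sprintf(
    "<monotonicity_check> monotone: %s (strictly increasing: %s)\n",
    x$monotone, x$strictly_increasing
  ))
  if (!x$monotone) {
    bad <- x$steps[!x$steps$increase & x$steps$delta_F < 0, ]
    cat(sprintf(
      "  decreasing step(s): %s\n",
      paste(sprintf("%g -> %g", bad$from_concentration, bad$to_concentration),
        collapse = ", "
      )
    ))
  }
  invisible(x)
}

#' Summarize per-type capacitance over the lowest concentrations
#'
#' Averages each cell type's readings over its `k_lowest` smallest
#' concentrations (the recommended subset for classification: the highest
#' concentration is the one most easily corrupted by pipetting error) and
#' ranks the types by descending mean.
#'
#' @param responses List of [build_concentration_response()] results, one
#'   per cell type (order irrelevant).
#' @param k_lowest Number of smallest concentrations to average (default 3).
#' @return A tibble of class `phenotype_summary`: `cell_type`, `mean_F`,
#'   `sem_F`, `n_used`, `rank` (1 = largest mean). The concentration subset
#'   used per type is recorded in the `"concentrations_used"` attribute.
#' @export
summarize_phenotype <- function(responses, k_lowest = 3) {
  check_number(k_lowest, "k_lowest", min = 1)
  if (!length(responses)) stop_voltphen("`responses` must be non-empty.")
  rows <- map(responses, function(r) {
    if (nrow(r) < k_lowest) {
      stop_voltphen(sprintf(
        "response for %s has %d concentration(s); k_lowest = %d needs at least that many.",
        r$cell_type[1], nrow(r), k_lowest
      ))
    }
    sub <- head(arrange(r, .data$concentration), k_lowest)
    tibble(
      cell_type = sub$cell_type[1],
      mean_F = mean(sub$capacitance_F),
      sem_F = sd(sub$capacitance_F) / sqrt(k_lowest),
      n_used = as.integer(k_lowest),
      concentrations = list(sub$concentration),
      readings = list(sub$capacitance_F)
    )
  })
  out <- bind_rows(rows)
  used <- setNames(out$concentrations, out$cell_type)
  readings <- setNames(out$readings, out$cell_type)
  out <- arrange(select(out, -"concentrations", -"readings"),
                 desc(.data$mean_F), .data$cell_type)
  out$rank <- seq_len(nrow(out))
  # attributes follow the ranked row order, so the result is independent of
  # the input ordering
  used <- used[out$cell_type]
  readings <- readings[out$cell_type]
  attr(out, "concentrations_used") <- used
  attr(out, "readings") <- readings
  class(out) <- c("phenotype_summary", class(tibble()))
  out
}

#' Classify three unlabeled samples by capacitance ordering
#'
#' Capacitance is proportional to membrane area, so the three innate immune
#' types order by size: the largest mean capacitance is assigned MAC, the
#' middle DC, and the smallest THP1. If any two means agree within the
#' relative tolerance the classification is refused as inconclusive rather
#' than guessed.
#'
#' @param summary A [summarize_phenotype()] result with exactly three rows.
#' @param tol Relative tolerance under which two means count as tied.
#' @return A tibble of class `size_classification`: `sample` (the input
#'   label), `mean_F`, `rank`, `assigned` (`MAC`/`DC`/`THP1`, or `NA` when
#'   inconclusive); the `"status"` attribute is `"ok"` or `"inconclusive"`.
#' @export
classify_by_size_order <- function(summary, tol = 1e-9) {
  if (nrow(summary) != 3) {
    stop_voltphen("size-order classification needs exactly three summarized samples.")
  }
  ord <- arrange(summary, desc(.data$mean_F))
  gaps <- abs(diff(ord$mean_F))
  scale <- max(abs(ord$mean_F))
  inconclusive <- any(gaps <= tol * scale)
  assigned <- if (inconclusive) rep(NA_character_, 3) else c("MAC", "DC", "THP1")
  out <- tibble(
    sample = ord$cell_type,
    mean_F = ord$mean_F,
    rank = seq_len(3),
    assigned = assigned
  )
  attr(out, "status") <- if (inconclusive) "inconclusive" else "ok"
  class(out) <- c("size_classification", class(tibble()))
  out
}
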