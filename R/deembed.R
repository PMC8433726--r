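#' De-embed a capacitance trace against the cells-free media trace
#'
#' Removes the background (electrode/media) contribution by pointwise
#' division: each sample-trace capacitance value is divided by the
#' corresponding media value. The media trace is linearly interpolated
#' between its valid samples when the two time grids differ. Two outputs are
#' reported side by side: the dimensionless `ratio`, and `rescaled_F` — the
#' ratio multiplied by the media capacitance at `reference_time`, which puts
#' the de-embedded curve back on a farad scale for plotting and readout.
#' De-embedding a trace against itself gives ratio 1 at every valid sample.
#'
#' @param sample A `cap_trace` from [extract_capacitance()].
#' @param media The media (cells-free) `cap_trace`.
#' @param reference_time Time (s) at which the media reference capacitance is
#'   taken for rescaling; defaults to the media trace's own capacitance peak.
#' @param floor Smallest admissible |media capacitance| (F) at any needed
#'   point; values below it raise an error.
#' @return A tibble of class `deembedded_trace` with columns `time_s`,
#'   `ratio`, `rescaled_F`, `valid`.
#' @examples
#' prog <- cv_program()
#' media <- extract_capacitance(simulate_trace(suspension_model(seed = 3), prog))
#' d <- deembed(media, media)
#' range(d$ratio[d$valid]) # exactly 1
#' @export
deembed <- function(sample, media, reference_time = NULL, floor = 1e-15) {
  if (!inherits(sample, "cap_trace") || !inherits(media, "cap_trace")) {
    stop_voltphen("`sample` and `media` must be capacitance traces.")
  }
  m_ok <- media$valid
  s_ok <- sample$valid
  if (!any(m_ok) || !any(s_ok)) stop_voltphen("a trace has no valid samples.")

  m_interp <- approx(
    x = media$time_s[m_ok], y = media$capacitance_F[m_ok],
    xout = sample$time_s, method = "linear", rule = 1, ties = "ordered"
  )$y

  valid <- s_ok & !is.na(m_interp)
  if (!any(valid)) {
    stop_voltphen("sample and media traces have disjoint valid time support.")
  }
  if (any(abs(m_interp[valid]) < floor)) {
    stop_voltphen(sprintf(
      "media capacitance below the %g F floor at %d needed sample(s); cannot divide.",
      floor, sum(abs(m_interp[valid]) < floor)
    ))
  }

  if (is.null(reference_time)) reference_time <- find_peak_time(media)
  c_ref <- capacitance_at(media, reference_time)

  ratio <- rep(NA_real_, nrow(sample))
  ratio[valid] <- sample$capacitance_F[valid] / m_interp[valid]

  out <- tibble(
    time_s = sample$time_s,
    ratio = ratio,
    rescaled_F = ratio * c_ref,
    valid = valid
  )
  attr(out, "meta") <- c(
    attr(sample, "meta") %||% list(),
    list(
      media_sample_id = (attr(media, "meta") %||% list())$sample_id,
      reference_time_s = reference_time,
      media_reference_F = c_ref
    )
  )
  attr(out, "program") <- attr(sample, "program")
  class(out) <- c("deembedded_trace", class(tibble()))
  out
}
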