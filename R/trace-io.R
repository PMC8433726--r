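#' Construct a CV trace
#'
#' A CV trace is a tibble of simultaneously sampled time (s), applied voltage
#' (V) and measured current (A) on a uniform time grid, with sample metadata
#' (`sample_id`, `cell_type`, `concentration` in cells per 500 uL, `replicate`)
#' carried in the `"meta"` attribute and, when known, the excitation program in
#' the `"program"` attribute.
#'
#' @param time_s,voltage_V,current_A Equal-length numeric vectors (length >= 3);
#'   `time_s` strictly increasing on a uniform grid (relative tolerance 1e-9).
#' @param meta Named list of sample metadata.
#' @param program Optional [cv_program()]; when present the voltage must stay
#'   within `[v_min, v_max]`.
#' @return A tibble of class `cv_trace`.
#' @export
cv_trace <- function(time_s, voltage_V, current_A, meta = list(), program = NULL) {
  out <- tibble(
    time_s = as.double(time_s),
    voltage_V = as.double(voltage_V),
    current_A = as.double(current_A)
  )
  attr(out, "meta") <- meta
  attr(out, "program") <- program
  class(out) <- c("cv_trace", class(tibble()))
  validate_cv_trace(out)
}

#' @rdname cv_trace
#' @param x Object to validate.
#' @export
validate_cv_trace <- function(x) {
  for (col in c("time_s", "voltage_V", "current_A")) {
    if (!col %in% names(x)) stop_voltphen(sprintf("trace is missing column `%s`.", col))
    if (anyNA(x[[col]]) || any(!is.finite(x[[col]]))) {
      stop_voltphen(sprintf("trace column `%s` contains non-finite values.", col))
    }
  }
  if (nrow(x) < 3) stop_voltphen("a CV trace needs at least 3 samples.")
  dt <- diff(x$time_s)
  if (any(dt <= 0)) {
    stop_voltphen(sprintf(
      "trace time must be strictly increasing (first violation after row %d).",
      which(dt <= 0)[1]
    ))
  }
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop_voltphen("trace time grid is not uniform (relative tolerance 1e-9).")
  }
  program <- attr(x, "program")
  if (!is.null(program)) {
    eps <- 1e-9 * (program$v_max - program$v_min)
    if (any(x$voltage_V < program$v_min - eps) || any(x$voltage_V > program$v_max + eps)) {
      stop_voltphen("trace voltage leaves the program's [v_min, v_max] range.")
    }
  }
  x
}

#' @rdname cv_trace
#' @export
trace_meta <- function(x) attr(x, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_factor <- function(quantity, unit) {
  tab <- list(
    time = c(s = 1, ms = 1e-3, us = 1e-6),
    voltage = c(V = 1, mV = 1e-3, uV = 1e-6),
    current = c(A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, pA = 1e-12),
    capacitance = c(F = 1, uF = 1e-6, nF = 1e-9, pF = 1e-12)
  )
  f <- tab[[quantity]][unit]
  if (is.na(f)) {
    stop_voltphen(sprintf("unknown %s unit `%s` in header.", quantity, unit))
  }
  unname(f)
}

format_num <- function(x) sprintf("%.15g", x)

#' Read and write CV traces as delimited text
#'
#' The on-disk dialect is UTF-8 comma-separated text with a `'.'` decimal
#' mark: optional `# key: value` metadata lines, then a header naming the
#' three channels with a unit suffix (`time_s`, `voltage_V`, `current_A`;
#' also accepted on read: `ms`/`us`, `mV`, `mA`/`uA`/`nA`/`pA`, converted to
#' SI on ingest). Writing is deterministic: identical traces produce
#' byte-identical files.
#'
#' @param source Path to a trace file.
#' @return `read_cv_csv()` returns a [cv_trace()]; `write_cv_csv()` returns
#'   `sink`, invisibly.
#' @examples
#' tr <- simulate_trace(suspension_model(seed = 1), cv_program(0, 1, 0.25, 1))
#' f <- tempfile(fileext = ".csv")
#' write_cv_csv(tr, f)
#' all.equal(read_cv_csv(f)$current_A, tr$current_A)
#' @export
read_cv_csv <- function(source) {
  lines <- readLines(source, encoding = "UTF-8")
  is_meta <- grepl("^\\s*#", lines)
  body <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body) < 2) stop_voltphen("file has no data rows.")

  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }

  header <- strsplit(trimws(lines[body[1]]), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  want <- c(time = "^time_(.+)$", voltage = "^voltage_(.+)$", current = "^current_(.+)$")
  idx <- integer(0)
  fac <- double(0)
  for (q in names(want)) {
    hit <- grep(want[[q]], header)
    if (length(hit) != 1) {
      stop_voltphen(sprintf("header must name exactly one `%s_<unit>` column.", q))
    }
    unit <- sub(want[[q]], "\\1", header[hit])
    idx[q] <- hit
    fac[q] <- unit_factor(q, unit)
  }

  rows <- lines[body[-1]]
  parts <- strsplit(rows, ",", fixed = TRUE)
  len <- lengths(parts)
  if (any(len != length(header))) {
    bad <- which(len != length(header))[1]
    stop_voltphen(sprintf(
      "ragged row: data row %d has %d fields, expected %d.",
      bad, len[bad], length(header)
    ))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
    nrow = length(rows), byrow = TRUE
  )
  if (anyNA(mat[, idx])) {
    bad <- which(apply(is.na(mat[, idx, drop = FALSE]), 1, any))[1]
    stop_voltphen(sprintf("non-numeric value in data row %d.", bad))
  }

  program <- NULL
  pk <- c("program_v_min", "program_v_max", "program_e_step", "program_s_rate")
  if (all(pk %in% names(meta))) {
    program <- cv_program(
      v_min = meta$program_v_min, v_max = meta$program_v_max,
      e_step = meta$program_e_step, s_rate = meta$program_s_rate,
      start_vertex = meta$program_start_vertex %||% "high",
      n_cycles = meta$program_n_cycles %||% 1
    )
  }
  meta <- meta[!grepl("^program_", names(meta))]

  cv_trace(
    time_s = mat[, idx["time"]] * fac["time"],
    voltage_V = mat[, idx["voltage"]] * fac["voltage"],
    current_A = mat[, idx["current"]] * fac["current"],
    meta = meta, program = program
  )
}

#' @rdname read_cv_csv
#' @param trace A [cv_trace()].
#' @param sink Path to write to.
#' @export
write_cv_csv <- function(trace, sink) {
  validate_cv_trace(trace)
  meta <- trace_meta(trace)
  program <- attr(trace, "program")
  hdr <- character(0)
  for (key in names(meta)) {
    if (!is.null(meta[[key]]) && length(meta[[key]]) == 1 && !is.na(meta[[key]])) {
      val <- if (is.numeric(meta[[key]])) format_num(meta[[key]]) else as.character(meta[[key]])
      hdr <- c(hdr, sprintf("# %s: %s", key, val))
    }
  }
  if (!is.null(program)) {
    hdr <- c(
      hdr,
      sprintf("# program_v_min: %s", format_num(program$v_min)),
      sprintf("# program_v_max: %s", format_num(program$v_max)),
      sprintf("# program_e_step: %s", format_num(program$e_step)),
      sprintf("# program_s_rate: %s", format_num(program$s_rate)),
      sprintf("# program_start_vertex: %s", program$start_vertex),
      sprintf("# program_n_cycles: %d", program$n_cycles)
    )
  }
  rows <- paste(
    format_num(trace$time_s), format_num(trace$voltage_V),
    format_num(trace$current_A),
    sep = ","
  )
  writeLines(c(hdr, "time_s,voltage_V,current_A", rows), con = sink, useBytes = TRUE)
  invisible(sink)
}

#' Write a capacitance or de-embedded trace as delimited text
#'
#' Same dialect as [write_cv_csv()]: `# key: value` metadata lines (including
#' the extraction settings) followed by `time_s,capacitance_F,valid` for
#' capacitance traces or `time_s,ratio,rescaled_F,valid` for de-embedded
#' traces.
#'
#' @param ctrace A capacitance trace from [extract_capacitance()] or a
#'   de-embedded trace from [deembed()].
#' @param sink Path to write to.
#' @return `sink`, invisibly.
#' @export
write_capacitance_csv <- function(ctrace, sink) {
  meta <- attr(ctrace, "meta") %||% list()
  hdr <- character(0)
  for (key in names(meta)) {
    v <- meta[[key]]
    if (!is.null(v) && length(v) == 1 && !is.na(v)) {
      val <- if (is.numeric(v)) format_num(v) else as.character(v)
      hdr <- c(hdr, sprintf("# %s: %s", key, val))
    }
  }
  if (inherits(ctrace, "deembedded_trace")) {
    cols <- "time_s,ratio,rescaled_F,valid"
    rows <- paste(
      format_num(ctrace$time_s),
      ifelse(ctrace$valid, format_num(ctrace$ratio), "NA"),
      ifelse(ctrace$valid, format_num(ctrace$rescaled_F), "NA"),
      as.integer(ctrace$valid),
      sep = ","
    )
  } else {
    cols <- "time_s,capacitance_F,valid"
    rows <- paste(
      format_num(ctrace$time_s),
      ifelse(ctrace$valid, format_num(ctrace$capacitance_F), "NA"),
      as.integer(ctrace$valid),
      sep = ","
    )
  }
  writeLines(c(hdr, cols, rows), con = sink, useBytes = TRUE)
  invisible(sink)
}
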