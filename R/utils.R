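# internal helpers shared across modules

# Deterministic sub-seed from a master seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + 7919 * as.double(index)) %% 2147483647)
}

stop_voltphen <- function(msg, class = "voltphen_error", ...) {
  abort(msg, class = c(class, "voltphen_error"), ...)
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE, len = 1) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    stop_voltphen(sprintf("`%s` must be a finite numeric of length %d.", name, len))
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    op <- if (strict_min) ">" else ">="
    stop_voltphen(sprintf("`%s` must be %s %g (got %g).", name, op, min, x[1]))
  }
  invisible(x)
}

# Centered moving average with the window truncated at the ends, so every
# input sample keeps an output value. w = 1 is the identity.
moving_average_truncated <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n <= 1) return(x)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Apply a function to each maximal run of TRUEs in `valid`, over x.
apply_over_valid_runs <- function(x, valid, fn) {
  out <- x
  if (!any(valid)) return(out)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      idx <- starts[k]:ends[k]
      out[idx] <- fn(x[idx])
    }
  }
  out
}

farads_to_uF <- function(x) x * 1e6
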