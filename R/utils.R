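# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Analytic signal via the frequency-domain Hilbert transformer.
# Returns a complex vector whose modulus is the amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  assert_that(n > 1L, "signal must have length > 1")
  assert_that(all(is.finite(x)), "signal contains non-finite samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Merge possibly-overlapping [start, end) intervals; returns a two-column
# matrix sorted by start. Empty input -> 0-row matrix.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out <- list()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Complement of a set of [start, end) intervals within [0, total).
complement_intervals <- function(intervals, total) {
  if (nrow(intervals) == 0L) {
    return(matrix(c(0, total), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  starts <- c(0, intervals[, "end"])
  ends <- c(intervals[, "start"], total)
  keep <- ends - starts > 1e-12
  m <- cbind(start = starts[keep], end = ends[keep])
  m[m[, "end"] > m[, "start"], , drop = FALSE]
}

# Deterministic per-subject seed derived from a master seed; kept inside
# the 32-bit integer range R requires.
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 104729 * as.double(i)) %% 2147483647)
}
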