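#' Gaze trace container
#'
#' A `gaze_trace` holds one fixed-rate monocular gaze recording: ordered
#' horizontal and vertical eye positions in degrees of visual angle, sampled
#' at `rate_hz` (1000 Hz for the recordings this package targets).
#'
#' @param x,y Numeric vectors of equal length (>= 2), gaze position in degrees.
#' @param rate_hz Sampling rate in Hz.
#' @param meta Optional named list of labels (e.g. `person_id`, `fixation_id`).
#' @return An object of class `gaze_trace`: a list with elements `x`, `y`,
#'   `rate_hz`, `meta`.
#' @examples
#' tr <- gaze_trace(sin(1:100 / 20), cos(1:100 / 20))
#' length(tr$x)
#' @export
gaze_trace <- function(x, y, rate_hz = 1000, meta = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("a gaze trace needs at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("gaze trace values must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar")
  structure(list(x = x, y = y, rate_hz = rate_hz, meta = meta),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$x), x$rate_hz, length(x$x) / x$rate_hz))
  invisible(x)
}

#' @export
length.gaze_trace <- function(x) length(x$x)

as_trace_like <- function(trace) {
  if (!inherits(trace, "gaze_trace")) stop("expected a gaze_trace")
  trace
}

# ---- interval helpers ------------------------------------------------------
# Intervals are 0-based, half-open [start, end): the convention used in all
# on-disk artifacts. A set of intervals is an integer matrix with columns
# `start`, `end`.

intervals_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) > 0L && any(m[, "end"] <= m[, "start"]))
    stop("intervals must satisfy end > start")
  m
}

empty_intervals <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

validate_intervals <- function(intervals, n) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(empty_intervals())
  iv <- intervals_matrix(intervals[, 1L], intervals[, 2L])
  if (any(iv[, 1L] < 0L) || any(iv[, 2L] > n))
    stop("interval out of trace bounds")
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
    stop("intervals overlap")
  iv
}

# Convert runs of TRUE in a logical vector to 0-based half-open intervals.
runs_to_intervals <- function(flag, min_len = 1L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty_intervals())
  intervals_matrix(starts[keep] - 1L, ends[keep])
}

# Restore RNG state on exit; run `expr` under `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
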