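# Denoising, microsaccade detection and drift/tremor separation.
#
# All spectral operations are plain DFT bin masks over the full trace with no
# tapering: traces are long (15,000 samples at 1 kHz) and edge effects are
# accepted. Masks are symmetric in +/- frequency so the inverse transform is
# real up to rounding; the imaginary residue is dropped.

# Keep only DFT bins with |f| in [lo, hi] Hz (inclusive). lo = 0 keeps DC.
fft_band_keep <- function(x, fs, lo, hi) {
  n <- length(x)
  # bin frequencies folded to [0, fs/2]
  k <- seq_len(n) - 1L
  f <- k * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Zero DFT bins with |f| within half_width of any listed frequency.
fft_notch <- function(x, fs, freqs, half_width) {
  n <- length(x)
  k <- seq_len(n) - 1L
  f <- k * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  for (f0 in freqs) X[abs(f - f0) <= half_width] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Spectral low-pass denoising
#'
#' Per-axis discrete Fourier transform; all bins above `cutoff_hz` (the
#' maximum frequency of fixational eye movements, about 104 Hz) are zeroed;
#' the inverse transform returns the filtered trace.
#'
#' @param trace A [gaze_trace()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @return A filtered `gaze_trace` of the same length.
#' @export
spectral_denoise <- function(trace, cutoff_hz = 104) {
  trace <- as_trace_like(trace)
  if (cutoff_hz >= trace$rate_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency")
  gaze_trace(fft_band_keep(trace$x, trace$rate_hz, 0, cutoff_hz),
             fft_band_keep(trace$y, trace$rate_hz, 0, cutoff_hz),
             rate_hz = trace$rate_hz, meta = trace$meta)
}

#' Mains-harmonic notch rejection
#'
#' Zeroes DFT bins within `half_width_hz` of each listed frequency (power
#' supply harmonics at 50 and 100 Hz by default).
#'
#' @param trace A [gaze_trace()].
#' @param freqs Frequencies to reject, Hz; must be below Nyquist.
#' @param half_width_hz Half-width of each notch, Hz.
#' @return A filtered `gaze_trace`.
#' @export
notch_harmonics <- function(trace, freqs = c(50, 100), half_width_hz = 1) {
  trace <- as_trace_like(trace)
  if (any(freqs >= trace$rate_hz / 2)) stop("notch frequency above Nyquist")
  if (half_width_hz <= 0) stop("half_width_hz must be > 0")
  gaze_trace(fft_notch(trace$x, trace$rate_hz, freqs, half_width_hz),
             fft_notch(trace$y, trace$rate_hz, freqs, half_width_hz),
             rate_hz = trace$rate_hz, meta = trace$meta)
}

#' Kalman denoising with a constant-velocity eye model
#'
#' Per-axis linear Kalman filter whose state holds eye position and velocity
#' with a constant-velocity transition over dt = 1/rate. `q` scales the
#' white-acceleration process noise (deg^2/s^3), `r` the measurement noise
#' variance (deg^2).
#'
#' @param trace A [gaze_trace()].
#' @param q Process-noise intensity, > 0.
#' @param r Measurement-noise variance, > 0.
#' @return A filtered `gaze_trace` (positions only).
#' @export
kalman_denoise <- function(trace, q = 1000, r = 1e-5) {
  trace <- as_trace_like(trace)
  if (q <= 0 || r <= 0) stop("q and r must be > 0")
  dt <- 1 / trace$rate_hz
  gaze_trace(kalman_axis(trace$x, dt, q, r),
             kalman_axis(trace$y, dt, q, r),
             rate_hz = trace$rate_hz, meta = trace$meta)
}

kalman_axis <- function(z, dt, q, r) {
  n <- length(z)
  # state (pos, vel); F = [1 dt; 0 1]; Q = q * [dt^3/3 dt^2/2; dt^2/2 dt]
  q11 <- q * dt^3 / 3; q12 <- q * dt^2 / 2; q22 <- q * dt
  xp <- z[1L]; xv <- 0
  p11 <- r; p12 <- 0; p22 <- 1
  out <- numeric(n)
  out[1L] <- xp
  for (i in 2:n) {
    # predict
    xp <- xp + dt * xv
    a11 <- p11 + 2 * dt * p12 + dt^2 * p22 + q11
    a12 <- p12 + dt * p22 + q12
    a22 <- p22 + q22
    # update
    s <- a11 + r
    k1 <- a11 / s; k2 <- a12 / s
    innov <- z[i] - xp
    xp <- xp + k1 * innov
    xv <- xv + k2 * innov
    p11 <- (1 - k1) * a11
    p12 <- (1 - k1) * a12
    p22 <- a22 - k2 * a12
    out[i] <- xp
  }
  out
}

#' Velocity-threshold microsaccade detection
#'
#' Variant of the classical velocity-ellipse detector: the two-dimensional
#' velocity is smoothed with a centred moving average of width `win`; a
#' median-based robust SD is estimated per axis; samples where
#' `(vx/etax)^2 + (vy/etay)^2 > 1` with `eta = lam * SD` are flagged, and
#' supra-threshold runs at least `min_dur_ms` long become event intervals
#' (0-based, half-open).
#'
#' Supra-threshold runs separated by gaps shorter than `merge_gap_ms` are
#' merged into one event (double, out-and-back, microsaccades pass through a
#' brief velocity dip at the turning point). Events overlapping the first or
#' last `edge_margin_ms` of the trace are discarded: the spectral filters
#' treat the trace as periodic, and the resulting wrap-around ringing makes
#' boundary detections unreliable.
#'
#' @param trace A (denoised) [gaze_trace()].
#' @param win Moving-average window in samples; odd, >= 3.
#' @param lam Threshold multiplier.
#' @param min_dur_ms Minimum event duration in ms.
#' @param merge_gap_ms Runs closer than this are merged.
#' @param edge_margin_ms Guard margin at both trace ends.
#' @return Interval matrix with columns `start`, `end`.
#' @export
detect_velocity <- function(trace, win = 11, lam = 6, min_dur_ms = 6,
                            merge_gap_ms = 10, edge_margin_ms = 300) {
  trace <- as_trace_like(trace)
  if (win < 3L || win %% 2L == 0L) stop("win must be odd and >= 3")
  n <- length(trace$x)
  if (n <= win) stop("trace shorter than the smoothing window")
  vx <- moving_average(diff(trace$x) * trace$rate_hz, win)
  vy <- moving_average(diff(trace$y) * trace$rate_hz, win)
  ex <- lam * robust_sd(vx)
  ey <- lam * robust_sd(vy)
  if (ex <= 0 || ey <= 0) return(empty_intervals())
  flag <- (vx / ex)^2 + (vy / ey)^2 > 1
  to_samples <- function(ms) max(0L, as.integer(round(ms * trace$rate_hz / 1000)))
  iv <- runs_to_intervals(flag, 1L)
  iv <- merge_close_intervals(iv, to_samples(merge_gap_ms))
  min_len <- max(1L, to_samples(min_dur_ms))
  iv <- iv[iv[, "end"] - iv[, "start"] >= min_len, , drop = FALSE]
  if (nrow(iv) > 0L) iv[, "end"] <- pmin(iv[, "end"] + 1L, n)  # steps -> samples
  drop_edge_intervals(iv, n, to_samples(edge_margin_ms))
}

merge_close_intervals <- function(iv, gap) {
  if (nrow(iv) < 2L || gap <= 0L) return(iv)
  keep_s <- iv[1L, 1L]; out_s <- integer(0); out_e <- integer(0)
  cur_e <- iv[1L, 2L]
  for (r in 2:nrow(iv)) {
    if (iv[r, 1L] - cur_e < gap) cur_e <- iv[r, 2L]
    else { out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
           keep_s <- iv[r, 1L]; cur_e <- iv[r, 2L] }
  }
  intervals_matrix(c(out_s, keep_s), c(out_e, cur_e))
}

drop_edge_intervals <- function(iv, n, margin) {
  if (nrow(iv) == 0L || margin <= 0L) return(iv)
  keep <- iv[, "start"] >= margin & iv[, "end"] <= n - margin
  iv[keep, , drop = FALSE]
}

moving_average <- function(v, win) {
  sm <- as.numeric(stats::filter(v, rep(1 / win, win), sides = 2))
  # centred filter leaves NAs at the edges; fall back to the raw values there
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

# Median-estimator SD: sqrt(median(v^2) - median(v)^2), robust to the events
# themselves inflating the spread.
robust_sd <- function(v) {
  s2 <- stats::median(v^2) - stats::median(v)^2
  sqrt(max(s2, 0))
}

#' Chi-square change detection of microsaccades
#'
#' Statistical detector: within each sliding window of `win = 11` samples the
#' 10 per-step displacements of each axis are squared, normalized by a robust
#' baseline step SD (median absolute deviation over the whole trace), and
#' summed, giving a chi-square statistic with `win - 1 = 10` degrees of
#' freedom per axis. A window is flagged when either axis exceeds the upper
#' `alpha/2` chi-square quantile (so the two-axis false-alarm rate is
#' approximately `alpha`); overlapping flagged windows are merged.
#'
#' Events overlapping the first or last `edge_margin_ms` of the trace are
#' discarded (see [detect_velocity()]).
#'
#' @param trace A (denoised) [gaze_trace()].
#' @param win Window length in samples (degrees of freedom + 1).
#' @param alpha Per-window false-alarm probability.
#' @param edge_margin_ms Guard margin at both trace ends.
#' @return Interval matrix with columns `start`, `end`.
#' @export
detect_chi2 <- function(trace, win = 11, alpha = 0.01, edge_margin_ms = 0) {
  trace <- as_trace_like(trace)
  if (win < 3L) stop("win must be >= 3")
  dx <- diff(trace$x); dy <- diff(trace$y)
  sx <- stats::mad(dx); sy <- stats::mad(dy)
  if (sx <= 0 || sy <= 0) stop("degenerate (zero-variance) baseline")
  dof <- win - 1L
  n_steps <- length(dx)
  if (n_steps < dof) stop("trace shorter than the detection window")
  cum_x <- c(0, cumsum((dx / sx)^2))
  cum_y <- c(0, cumsum((dy / sy)^2))
  i <- seq_len(n_steps - dof + 1L)          # window start (step index, 1-based)
  tx <- cum_x[i + dof] - cum_x[i]
  ty <- cum_y[i + dof] - cum_y[i]
  thr <- stats::qchisq(1 - alpha / 2, df = dof)
  hit <- tx > thr | ty > thr
  if (!any(hit)) return(empty_intervals())
  # flagged window starting at step i covers samples [i-1, i-1+win) 0-based
  covered <- logical(n_steps + 1L)
  for (s in which(hit)) covered[s:(s + dof)] <- TRUE
  iv <- runs_to_intervals(covered, 1L)
  margin <- max(0L, as.integer(round(edge_margin_ms * trace$rate_hz / 1000)))
  drop_edge_intervals(iv, n_steps + 1L, margin)
}

#' Drift/tremor band separation
#'
#' Splits a residual trace (microsaccades already excised) into its drift
#' component (DFT restriction to 0--40 Hz) and tremor component (70--103 Hz).
#' The two outputs plus the discarded bands reconstruct the input exactly.
#'
#' @param residual A [gaze_trace()] with events removed/interpolated.
#' @param drift_band,tremor_band Frequency bands in Hz.
#' @return List with `gaze_trace` elements `drift` and `tremor`.
#' @export
split_bands <- function(residual, drift_band = c(0, 40), tremor_band = c(70, 103)) {
  residual <- as_trace_like(residual)
  fs <- residual$rate_hz
  drift <- gaze_trace(fft_band_keep(residual$x, fs, drift_band[1], drift_band[2]),
                      fft_band_keep(residual$y, fs, drift_band[1], drift_band[2]),
                      rate_hz = fs, meta = residual$meta)
  tremor <- gaze_trace(fft_band_keep(residual$x, fs, tremor_band[1], tremor_band[2]),
                       fft_band_keep(residual$y, fs, tremor_band[1], tremor_band[2]),
                       rate_hz = fs, meta = residual$meta)
  list(drift = drift, tremor = tremor)
}

#' Excise event intervals by linear interpolation
#'
#' Replaces samples inside each interval with a linear ramp between the
#' samples just outside it, so the residual can be band-split without the
#' broadband energy of the events.
#'
#' @param trace A [gaze_trace()].
#' @param intervals Interval matrix (0-based half-open).
#' @return A `gaze_trace` with events interpolated away.
#' @export
excise_intervals <- function(trace, intervals) {
  trace <- as_trace_like(trace)
  n <- length(trace$x)
  iv <- validate_intervals(intervals, n)
  x <- trace$x; y <- trace$y
  for (r in seq_len(nrow(iv))) {
    s <- iv[r, 1L] + 1L; e <- iv[r, 2L]     # 1-based inclusive sample range
    a <- max(1L, s - 1L); b <- min(n, e + 1L)
    idx <- s:e
    x[idx] <- x[a] + (x[b] - x[a]) * (idx - a) / (b - a)
    y[idx] <- y[a] + (y[b] - y[a]) * (idx - a) / (b - a)
  }
  gaze_trace(x, y, rate_hz = trace$rate_hz, meta = trace$meta)
}

#' Cut detected events out of a trace as a segment
#'
#' A segment is the set of microsaccades extracted from one fixation: one
#' event (an ordered point matrix) per interval, points copied from the
#' (denoised) trace.
#'
#' @param trace A [gaze_trace()].
#' @param intervals Interval matrix (0-based half-open), all of length >= 2.
#' @return A list of class `msacc_segment`: `microsaccades` (list of n x 2
#'   matrices), `person_id`, `fixation_id`, `rate_hz`.
#' @export
build_segments <- function(trace, intervals) {
  trace <- as_trace_like(trace)
  n <- length(trace$x)
  iv <- validate_intervals(intervals, n)
  if (nrow(iv) == 0L) stop("no intervals: cannot build an empty segment")
  events <- lapply(seq_len(nrow(iv)), function(r) {
    idx <- (iv[r, 1L] + 1L):iv[r, 2L]
    cbind(x = trace$x[idx], y = trace$y[idx])
  })
  structure(list(microsaccades = events,
                 person_id = trace$meta$person_id %||% NA_character_,
                 fixation_id = trace$meta$fixation_id %||% NA_character_,
                 rate_hz = trace$rate_hz),
            class = "msacc_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call preprocessing pipeline
#'
#' Spectral low-pass at 104 Hz, mains notches at 50/100 Hz, microsaccade
#' detection, event excision and drift/tremor band separation.
#'
#' @param trace A raw [gaze_trace()].
#' @param detector `"velocity"` or `"chi2"`.
#' @param cutoff_hz,notch_freqs Filter parameters.
#' @param ... Passed to the chosen detector.
#' @return List: `denoised`, `intervals`, `segment` (NULL when no events),
#'   `drift`, `tremor`.
#' @export
preprocess_trace <- function(trace, detector = c("velocity", "chi2"),
                             cutoff_hz = 104, notch_freqs = c(50, 100), ...) {
  detector <- match.arg(detector)
  den <- spectral_denoise(trace, cutoff_hz)
  den <- notch_harmonics(den, notch_freqs)
  iv <- if (detector == "velocity") detect_velocity(den, ...)
        else detect_chi2(den, edge_margin_ms = 300, ...)
  seg <- if (nrow(iv) > 0L) build_segments(den, iv) else NULL
  resid <- excise_intervals(den, iv)
  bands <- split_bands(resid)
  list(denoised = den, intervals = iv, segment = seg,
       drift = bands$drift, tremor = bands$tremor)
}
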