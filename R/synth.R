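#' Simulator configuration
#'
#' Ranges from which per-person profile parameters are drawn. Defaults emulate
#' the magnitudes reported for human fixational eye movements: microsaccade
#' amplitudes on the order of 12 arcmin (0.2 deg), drift at an average speed
#' of about 4 arcmin/s confined to 0--40 Hz, tremor confined to 70--103 Hz,
#' and additive Gaussian sensor noise. Microsaccade rates of 1--2 events/s are
#' a literature-typical choice for point fixation.
#'
#' @param msacc_rate Microsaccade rate range, events/s.
#' @param amp_mean Range of per-person mean microsaccade amplitude, degrees.
#' @param amp_sd Range of per-person amplitude SD, degrees.
#' @param peak_vel_scale Range of characteristic peak velocity, deg/s
#'   (sets event durations through the bell-shaped speed profile).
#' @param double_fraction Range of the probability that an event is a double
#'   (out-and-back) microsaccade.
#' @param drift_speed Range of mean drift speed, arcmin/s.
#' @param tremor_rms Range of tremor RMS amplitude, degrees.
#' @param noise_sd Range of sensor noise SD, degrees.
#' @return A named list of 2-element numeric ranges, class `sim_config`.
#' @export
sim_config <- function(msacc_rate = c(1, 2),
                       amp_mean = c(0.1, 0.3),
                       amp_sd = c(0.02, 0.06),
                       peak_vel_scale = c(12, 35),
                       double_fraction = c(0, 0.3),
                       drift_speed = c(2, 6),
                       tremor_rms = c(0.002, 0.006),
                       noise_sd = c(0.001, 0.004)) {
  cfg <- list(msacc_rate = msacc_rate, amp_mean = amp_mean, amp_sd = amp_sd,
              peak_vel_scale = peak_vel_scale, double_fraction = double_fraction,
              drift_speed = drift_speed, tremor_rms = tremor_rms,
              noise_sd = noise_sd)
  for (nm in names(cfg)) {
    r <- cfg[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)))
      stop("config field '", nm, "' must be a finite numeric range")
    if (r[1L] > r[2L])
      stop("config field '", nm, "' has min > max")
  }
  if (any(cfg$double_fraction < 0) || any(cfg$double_fraction > 1))
    stop("double_fraction range must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Draw a person profile
#'
#' Draws one synthetic "person": a set of oculomotor parameters held fixed
#' across that person's fixations. Fields are drawn uniformly from the config
#' ranges; the draw is a pure function of `seed`.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param person_id Label for the person.
#' @return A list of class `person_profile`.
#' @examples
#' p <- person_profile(1)
#' p$amp_mean
#' @export
person_profile <- function(seed, config = sim_config(), person_id = paste0("P", seed)) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  draw <- with_seed(seed, {
    vapply(unclass(config), function(r) stats::runif(1, r[1L], r[2L]), numeric(1))
  })
  prof <- c(as.list(draw), list(person_id = person_id, seed = as.integer(seed)))
  class(prof) <- "person_profile"
  validate_profile(prof)
  prof
}

validate_profile <- function(p) {
  scales <- c("msacc_rate", "amp_mean", "amp_sd", "peak_vel_scale")
  for (nm in scales) if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
    stop("profile field '", nm, "' must be > 0")
  for (nm in c("drift_speed", "tremor_rms", "noise_sd"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop("profile field '", nm, "' must be >= 0")
  if (p$double_fraction < 0 || p$double_fraction > 1)
    stop("double_fraction must lie in [0, 1]")
  invisible(p)
}

# Event duration (ms) implied by amplitude and characteristic peak velocity
# for a Gaussian speed profile with sigma = duration/6:
# v_peak = amp / (sigma * sqrt(2*pi))  =>  duration = 6*amp / (v_peak*sqrt(2*pi)).
event_duration_ms <- function(amplitude, peak_vel_scale) {
  dur <- 1000 * 6 * amplitude / (peak_vel_scale * sqrt(2 * pi))
  max(8L, min(120L, as.integer(round(dur))))
}

# Displacement steps (per ms) of a straight event: Gaussian (bell-shaped)
# speed profile along `direction`, total displacement = amplitude.
bell_steps <- function(amplitude, duration_ms, direction) {
  t <- seq_len(duration_ms) - 0.5
  sigma <- duration_ms / 6
  w <- exp(-0.5 * ((t - duration_ms / 2) / sigma)^2)
  w <- w / sum(w) * amplitude
  cbind(x = w * cos(direction), y = w * sin(direction))
}

#' Generate one synthetic microsaccade trajectory
#'
#' Produces the noiseless trajectory of a single microsaccade: points at 1 ms
#' spacing following a smooth unimodal (bell-shaped) speed profile along a
#' straight direction. With probability `double_fraction` an immediate return
#' stroke is appended, producing a "double" microsaccade whose start and end
#' points coincide (base-length/duration ratio below the 0.01 threshold).
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param profile A [person_profile()] (or compatible list).
#' @param direction Direction of the event in radians.
#' @param amplitude Optional fixed amplitude in degrees; default draws from
#'   `Normal(amp_mean, amp_sd)` truncated positive.
#' @param duration_ms Optional fixed duration of the outgoing stroke in ms;
#'   default derives from amplitude and `peak_vel_scale`.
#' @return Numeric matrix with columns `x`, `y`: the event's points (degrees),
#'   starting at the origin.
#' @examples
#' set.seed(1)
#' ev <- synth_microsaccade(person_profile(1), direction = 0)
#' nrow(ev)
#' @export
synth_microsaccade <- function(profile, direction = stats::runif(1, 0, 2 * pi),
                               amplitude = NULL, duration_ms = NULL) {
  if (is.null(amplitude)) {
    amplitude <- -1
    while (amplitude <= 0)
      amplitude <- stats::rnorm(1, profile$amp_mean, profile$amp_sd)
  }
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (is.null(duration_ms))
    duration_ms <- event_duration_ms(max(amplitude, 1e-6), profile$peak_vel_scale)
  steps <- bell_steps(amplitude, duration_ms, direction)
  if (stats::runif(1) < profile$double_fraction) {
    steps <- rbind(steps, bell_steps(amplitude, duration_ms, direction + pi))
  }
  pts <- rbind(c(0, 0), apply(steps, 2L, cumsum))
  colnames(pts) <- c("x", "y")
  pts
}

#' Simulate one labelled fixation trace
#'
#' Builds a fixational eye-movement trace by additive superposition of a
#' microsaccade train (Poisson arrivals, overlapping candidates rejected),
#' band-limited drift (0--40 Hz, rescaled to the profile's mean speed),
#' band-limited tremor (70--103 Hz, rescaled to the profile's RMS) and i.i.d.
#' Gaussian sensor noise. Ground-truth event intervals (0-based half-open
#' sample ranges) are recorded.
#'
#' @param profile A [person_profile()].
#' @param duration_s Trace duration in seconds.
#' @param fs Sampling rate in Hz (the simulator assumes 1 kHz event spacing).
#' @param seed Optional integer seed; default uses the profile's seed.
#' @param fixation_id Label stored in the trace metadata.
#' @return A list of class `labeled_trace`: `trace` (a [gaze_trace()]),
#'   `truth` (interval matrix) and `profile`.
#' @export
synth_fixation_trace <- function(profile, duration_s = 15, fs = 1000,
                                 seed = profile$seed, fixation_id = "F1") {
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- as.integer(round(duration_s * fs))
  typical_dur <- event_duration_ms(profile$amp_mean, profile$peak_vel_scale) / 1000
  if (profile$msacc_rate * (2 * typical_dur + 0.02) > 0.9)
    stop("microsaccade rate too high to place non-overlapping events")
  with_seed(seed, {
    vx <- numeric(n - 1L)
    vy <- numeric(n - 1L)
    truth <- empty_intervals()
    # Poisson arrivals; candidates overlapping an accepted event (or the
    # trace end) are rejected, with a 20 ms refractory margin.
    t_arr <- 0
    last_end <- -20L
    starts <- integer(0); ends <- integer(0)
    repeat {
      t_arr <- t_arr + stats::rexp(1, rate = profile$msacc_rate)
      if (t_arr * fs >= n) break
      s <- as.integer(floor(t_arr * fs))
      ev <- synth_microsaccade(profile)
      m <- nrow(ev)                      # points; m-1 steps
      if (s < last_end + 20L || s + m > n) next
      idx <- s + seq_len(m - 1L)         # 1-based step indices s+1 .. s+m-1
      vx[idx] <- vx[idx] + diff(ev[, "x"])
      vy[idx] <- vy[idx] + diff(ev[, "y"])
      starts <- c(starts, s); ends <- c(ends, s + m)
      last_end <- s + m
    }
    if (length(starts)) truth <- intervals_matrix(starts, ends)
    ms_x <- c(0, cumsum(vx))
    ms_y <- c(0, cumsum(vy))

    drift <- synth_band_component(n, fs, 0, 40)
    if (profile$drift_speed > 0) {
      spd <- mean(sqrt(diff(drift$x)^2 + diff(drift$y)^2)) * fs   # deg/s
      target <- profile$drift_speed / 60                          # arcmin/s -> deg/s
      f <- if (spd > 0) target / spd else 0
      drift$x <- drift$x * f; drift$y <- drift$y * f
    } else drift <- list(x = numeric(n), y = numeric(n))

    tremor <- synth_band_component(n, fs, 70, 103)
    if (profile$tremor_rms > 0) {
      rms <- sqrt(mean(tremor$x^2 + tremor$y^2) / 2)
      f <- if (rms > 0) profile$tremor_rms / rms else 0
      tremor$x <- tremor$x * f; tremor$y <- tremor$y * f
    } else tremor <- list(x = numeric(n), y = numeric(n))

    x <- ms_x + drift$x + tremor$x + stats::rnorm(n, 0, profile$noise_sd)
    y <- ms_y + drift$y + tremor$y + stats::rnorm(n, 0, profile$noise_sd)
    trace <- gaze_trace(x, y, rate_hz = fs,
                        meta = list(person_id = profile$person_id,
                                    fixation_id = fixation_id))
    structure(list(trace = trace, truth = truth, profile = profile),
              class = "labeled_trace")
  })
}

# White Gaussian noise restricted (via DFT masking) to [lo, hi] Hz per axis.
synth_band_component <- function(n, fs, lo, hi) {
  list(x = fft_band_keep(stats::rnorm(n), fs, lo, hi),
       y = fft_band_keep(stats::rnorm(n), fs, lo, hi))
}

#' Simulate a cohort of persons
#'
#' Generates `n_persons` profiles, each observed over `n_fixations` fixation
#' traces (the identification protocol uses 5 fixation points of 15 s each).
#' By default profile parameters are placed at evenly spaced quantiles of each
#' config range with a per-field seeded permutation (Latin-hypercube style),
#' so every pair of persons differs on every field -- the "distinct
#' individuals" study condition. `spread = "random"` draws profiles uniformly
#' instead.
#'
#' @param n_persons Number of persons (>= 2).
#' @param n_fixations Fixation traces per person (>= 2).
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @param config A [sim_config()].
#' @param spread `"spaced"` (default) or `"random"` profile placement.
#' @param duration_s,fs Passed to [synth_fixation_trace()].
#' @return A list of class `msacc_cohort`; each element is a person record:
#'   `person_id`, `profile`, `fixations` (list of `labeled_trace`).
#' @export
synth_cohort <- function(n_persons, n_fixations = 5, seed = 1,
                         config = sim_config(), spread = c("spaced", "random"),
                         duration_s = 15, fs = 1000) {
  spread <- match.arg(spread)
  if (n_persons < 2L) stop("n_persons must be >= 2")
  if (n_fixations < 2L) stop("n_fixations must be >= 2")
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)

  profiles <- if (spread == "spaced") {
    qs <- (seq_len(n_persons) - 0.5) / n_persons
    cols <- with_seed(seed, {
      lapply(unclass(config), function(r) {
        r[1L] + (r[2L] - r[1L]) * sample(qs)
      })
    })
    lapply(seq_len(n_persons), function(p) {
      prof <- c(lapply(cols, `[[`, p),
                list(person_id = paste0("P", p),
                     seed = as.integer(seed + 7919L * p)))
      class(prof) <- "person_profile"
      validate_profile(prof)
      prof
    })
  } else {
    lapply(seq_len(n_persons), function(p)
      person_profile(seed + 7919L * p, config, person_id = paste0("P", p)))
  }

  cohort <- lapply(seq_len(n_persons), function(p) {
    fixations <- lapply(seq_len(n_fixations), function(f) {
      synth_fixation_trace(profiles[[p]], duration_s = duration_s, fs = fs,
                           seed = profiles[[p]]$seed + f,
                           fixation_id = paste0("F", f))
    })
    list(person_id = profiles[[p]]$person_id, profile = profiles[[p]],
         fixations = fixations)
  })
  class(cohort) <- "msacc_cohort"
  cohort
}
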