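# The 13 per-microsaccade trajectory features.
#
# A microsaccade is an ordered n x 2 matrix of (x, y) points in degrees at
# 1 ms spacing (n >= 2). The canonical feature order is:
#   P1  duration (ms)           P8  average speed v_av (deg/ms)
#   P2  height H (deg)          P9  windowed max speed v_max11 (deg/ms)
#   P3  area S (deg^2)          P10 windowed max speed v_max21 (deg/ms)
#   P4  sharpness Sr = H/S      P11 average pseudo acceleration (deg/ms^2)
#   P5  base length (deg)       P12 top-10 max pseudo acceleration (deg/ms^2)
#   P6  double ratio (deg/ms)   P13 maximal diameter D_max (deg)
#   P7  double flag (0/1)

#' Canonical feature names
#'
#' @return Character vector of the 13 feature names in canonical order.
#' @export
feature_names <- function() {
  c("duration", "height", "area", "sharpness", "base_length",
    "double_ratio", "double_flag", "v_av", "v_max11", "v_max21",
    "accel_av", "accel_max10", "max_diameter")
}

check_event <- function(ms) {
  if (!is.matrix(ms) || ncol(ms) != 2L) stop("a microsaccade must be an n x 2 matrix")
  if (nrow(ms) < 2L) stop("a microsaccade needs at least 2 points")
  if (!all(is.finite(ms))) stop("microsaccade coordinates must be finite")
  ms
}

#' Microsaccade duration
#'
#' Number of samples minus one, in milliseconds at the stated rate: a
#' 50-sample event at 1 kHz lasts 49 ms.
#'
#' @param ms An n x 2 point matrix.
#' @param rate_hz Sampling rate in Hz.
#' @return Duration in ms.
#' @export
msac_duration <- function(ms, rate_hz = 1000) {
  check_event(ms)
  (nrow(ms) - 1L) * (1000 / rate_hz)
}

#' Microsaccade base length
#'
#' Euclidean distance between the first and last points.
#' @inheritParams msac_duration
#' @return Length in degrees.
#' @export
msac_base_length <- function(ms) {
  check_event(ms)
  sqrt(sum((ms[nrow(ms), ] - ms[1L, ])^2))
}

#' Microsaccade height
#'
#' Maximum distance from the interior points to the chord through the first
#' and last points (the perpendicular distance to the infinite line, equal to
#' twice the Heron triangle area over the base). When the trajectory is
#' closed (zero base) the maximum distance to the first point is used.
#'
#' @inheritParams msac_duration
#' @return Height in degrees (0 for a 2-point event).
#' @export
msac_height <- function(ms) {
  check_event(ms)
  n <- nrow(ms)
  if (n < 3L) return(0)
  a <- ms[1L, ]; b <- ms[n, ]
  base <- sqrt(sum((b - a)^2))
  interior <- ms[2:(n - 1L), , drop = FALSE]
  if (base > 0) {
    # |cross((b-a), (p-a))| / base
    cx <- (b[1L] - a[1L]) * (interior[, 2L] - a[2L]) -
          (b[2L] - a[2L]) * (interior[, 1L] - a[1L])
    max(abs(cx)) / base
  } else {
    max(sqrt((interior[, 1L] - a[1L])^2 + (interior[, 2L] - a[2L])^2))
  }
}

#' Self-intersections of a trajectory
#'
#' Finds all transversal crossings between non-adjacent edges of the open
#' polyline: for each pair of edges (k, l) with `l` outside `{k-1, k, k+1}`,
#' the 2x2 linear system for the intersection parameters (lambda, mu) is
#' solved; a crossing is reported iff the matrix is invertible and both
#' parameters lie in `[0, 1]`. Parallel (non-invertible) pairs never cross.
#'
#' @inheritParams msac_duration
#' @param closed If TRUE, the closing edge (last point to first) is included
#'   and adjacency is cyclic (used by the area computation).
#' @return Data frame with columns `k`, `l` (1-based edge indices),
#'   `lambda`, `mu`, `x`, `y`; zero rows when there is no crossing.
#' @export
msac_self_intersections <- function(ms, closed = FALSE) {
  check_event(ms)
  pts <- ms
  n <- nrow(pts)
  n_edges <- if (closed) n else n - 1L
  edge_a <- function(i) pts[i, ]
  edge_b <- function(i) pts[if (i == n) 1L else i + 1L, ]
  out <- list()
  if (n_edges >= 3L) {
    for (k in seq_len(n_edges - 2L)) {
      for (l in seq.int(k + 2L, n_edges)) {
        if (closed && k == 1L && l == n_edges) next  # cyclically adjacent
        a1 <- edge_a(k); a2 <- edge_b(k)
        b1 <- edge_a(l); b2 <- edge_b(l)
        # a1 + lambda*(a2-a1) = b1 + mu*(b2-b1)
        m11 <- a2[1L] - a1[1L]; m12 <- -(b2[1L] - b1[1L])
        m21 <- a2[2L] - a1[2L]; m22 <- -(b2[2L] - b1[2L])
        det <- m11 * m22 - m12 * m21
        if (abs(det) < 1e-14) next                   # parallel edges
        rhs1 <- b1[1L] - a1[1L]; rhs2 <- b1[2L] - a1[2L]
        lambda <- (rhs1 * m22 - m12 * rhs2) / det
        mu <- (m11 * rhs2 - rhs1 * m21) / det
        eps <- 1e-12
        if (lambda >= -eps && lambda <= 1 + eps && mu >= -eps && mu <= 1 + eps) {
          lambda <- min(max(lambda, 0), 1); mu <- min(max(mu, 0), 1)
          out[[length(out) + 1L]] <-
            c(k, l, lambda, mu,
              a1[1L] + lambda * m11, a1[2L] + lambda * m21)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(k = integer(0), l = integer(0), lambda = numeric(0),
                      mu = numeric(0), x = numeric(0), y = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(k = as.integer(m[, 1L]), l = as.integer(m[, 2L]),
             lambda = m[, 3L], mu = m[, 4L], x = m[, 5L], y = m[, 6L])
}

#' Microsaccade area
#'
#' Area enclosed by the trajectory, implicitly closed from the last point
#' back to the first. A simple (non-self-crossing) closed trajectory uses the
#' absolute shoelace (discretized Green's formula) value. A self-crossing
#' trajectory is split at its crossing points into simple sub-polygons and
#' the absolute sub-areas are summed.
#'
#' @inheritParams msac_duration
#' @return Area in squared degrees (0 for fewer than 3 points).
#' @export
msac_area <- function(ms) {
  check_event(ms)
  if (nrow(ms) < 3L) return(0)
  cross <- msac_self_intersections(ms, closed = TRUE)
  if (nrow(cross) == 0L) return(abs(shoelace(ms)))
  sum(vapply(split_at_crossings(ms, cross), function(p) abs(shoelace(p)),
             numeric(1)))
}

# Signed shoelace area of a closed polygon given as an open vertex list.
shoelace <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - y * xn) / 2
}

# Split a closed (implicitly) self-crossing polyline into simple loops.
# Crossing points are inserted as tagged junction vertices on both edges
# involved; a stack walk then pops a loop every time a junction reappears.
# Exact for well-nested crossing patterns; interleaved patterns are handled
# by the same walk and treated as an approximation.
split_at_crossings <- function(pts, cross) {
  n <- nrow(pts)
  key <- function(x, y) paste(round(x * 1e9), round(y * 1e9))
  jk <- key(cross$x, cross$y)
  # per-edge insertions: both edges of each crossing receive the junction
  ins <- data.frame(edge = c(cross$k, cross$l),
                    param = c(cross$lambda, cross$mu),
                    tag = c(jk, jk),
                    x = c(cross$x, cross$x), y = c(cross$y, cross$y))
  seq_x <- numeric(0); seq_y <- numeric(0); seq_tag <- character(0)
  for (i in seq_len(n)) {
    seq_x <- c(seq_x, pts[i, 1L]); seq_y <- c(seq_y, pts[i, 2L])
    seq_tag <- c(seq_tag, NA_character_)
    e <- ins[ins$edge == i, , drop = FALSE]
    if (nrow(e) > 0L) {
      e <- e[order(e$param), , drop = FALSE]
      seq_x <- c(seq_x, e$x); seq_y <- c(seq_y, e$y)
      seq_tag <- c(seq_tag, e$tag)
    }
  }
  # merge vertices coincident with a junction (crossing at param 0/1)
  m <- length(seq_x)
  vkey <- key(seq_x, seq_y)
  junction_keys <- unique(stats::na.omit(seq_tag))
  seq_tag[vkey %in% junction_keys] <- vkey[vkey %in% junction_keys]
  keep <- rep(TRUE, m)
  for (i in 2:m) if (vkey[i] == vkey[i - 1L]) keep[i] <- FALSE
  if (vkey[m] == vkey[1L] && m > 1L) keep[m] <- keep[m] && is.na(seq_tag[m])
  seq_x <- seq_x[keep]; seq_y <- seq_y[keep]; seq_tag <- seq_tag[keep]

  loops <- list()
  st_x <- numeric(0); st_y <- numeric(0); st_tag <- character(0)
  for (i in seq_along(seq_x)) {
    tg <- seq_tag[i]
    if (!is.na(tg) && tg %in% st_tag) {
      j <- max(which(st_tag == tg))
      loop_idx <- j:length(st_x)
      loops[[length(loops) + 1L]] <- cbind(st_x[loop_idx], st_y[loop_idx])
      st_x <- st_x[seq_len(j)]; st_y <- st_y[seq_len(j)]
      st_tag <- st_tag[seq_len(j)]
    } else {
      st_x <- c(st_x, seq_x[i]); st_y <- c(st_y, seq_y[i])
      st_tag <- c(st_tag, tg)
    }
  }
  if (length(st_x) >= 3L) loops[[length(loops) + 1L]] <- cbind(st_x, st_y)
  loops
}

#' Microsaccade sharpness
#'
#' Ratio of height to area, `Sr = H/S`; 0 when the area is (numerically)
#' zero, keeping the feature bounded for degenerate events.
#'
#' @param H Height in degrees.
#' @param S Area in squared degrees.
#' @return Sharpness in 1/degrees.
#' @export
msac_sharpness <- function(H, S) {
  if (H < 0 || S < 0) stop("height and area must be nonnegative")
  if (S < 1e-12) return(0)
  H / S
}

#' Mono/double classification of a microsaccade
#'
#' Doubles are out-and-back events whose endpoints nearly coincide. The
#' classifier thresholds the ratio of base length (deg) to duration (ms):
#' strictly below 0.01 is "double", otherwise "mono" (ties are mono).
#'
#' @param base Base length in degrees.
#' @param dur Duration in ms (> 0).
#' @param threshold Classification threshold in deg/ms.
#' @return List with `ratio` (deg/ms) and `flag` (1 = double, 0 = mono).
#' @export
double_classify <- function(base, dur, threshold = 0.01) {
  if (dur <= 0) stop("duration must be > 0")
  ratio <- base / dur
  list(ratio = ratio, flag = as.numeric(ratio < threshold))
}

#' Speed profile and windowed maximal speeds
#'
#' Per-step speeds `v_i` are successive point displacements (deg per sample,
#' i.e. deg/ms at 1 kHz). `v_av` is their mean. The windowed maximal speeds
#' `v_max11` / `v_max21` are the largest means over full sliding windows of
#' 11 / 21 speeds; events too short for a full window fall back to `v_av`.
#'
#' @inheritParams msac_duration
#' @return List: `v` (speed vector), `v_av`, `v_max11`, `v_max21`.
#' @export
msac_speed_profile <- function(ms) {
  check_event(ms)
  v <- sqrt(diff(ms[, 1L])^2 + diff(ms[, 2L])^2)
  list(v = v, v_av = mean(v),
       v_max11 = windowed_max_mean(v, 11L),
       v_max21 = windowed_max_mean(v, 21L))
}

windowed_max_mean <- function(v, w) {
  if (length(v) < w) return(mean(v))
  cs <- c(0, cumsum(v))
  i <- seq_len(length(v) - w + 1L)
  max((cs[i + w] - cs[i]) / w)
}

#' Pseudo-acceleration summaries
#'
#' Pseudo accelerations are first differences of the speed magnitudes,
#' `a_i = v_(i+1) - v_i`. Returns their signed mean and the mean of the 10
#' largest magnitudes (all magnitudes when fewer than 10 exist). A speed
#' vector shorter than 2 yields zeros with a warning.
#'
#' @param v Speed vector from [msac_speed_profile()].
#' @return List: `a` (signed accelerations), `accel_av`, `accel_max10`.
#' @export
msac_accel_profile <- function(v) {
  if (length(v) < 2L) {
    warning("fewer than 2 speeds: pseudo accelerations undefined, returning 0")
    return(list(a = numeric(0), accel_av = 0, accel_max10 = 0))
  }
  a <- diff(v)
  mags <- sort(abs(a), decreasing = TRUE)
  list(a = a, accel_av = mean(a),
       accel_max10 = mean(mags[seq_len(min(10L, length(mags)))]))
}

#' Maximal diameter
#'
#' Largest pairwise Euclidean distance between trajectory points.
#' @inheritParams msac_duration
#' @return Diameter in degrees.
#' @export
msac_max_diameter <- function(ms) {
  check_event(ms)
  max(stats::dist(ms))
}

#' Extract the 13-feature vector of one microsaccade
#'
#' @inheritParams msac_duration
#' @return Named numeric vector of length 13 in the canonical order
#'   (see [feature_names()] via the names).
#' @examples
#' ev <- cbind(x = seq(0, 0.2, length.out = 25), y = 0)
#' extract_features(ev)[["duration"]]
#' @export
extract_features <- function(ms, rate_hz = 1000) {
  check_event(ms)
  dur <- msac_duration(ms, rate_hz)
  H <- msac_height(ms)
  S <- msac_area(ms)
  base <- msac_base_length(ms)
  dbl <- double_classify(base, dur)
  sp <- msac_speed_profile(ms)
  ac <- if (length(sp$v) < 2L) list(accel_av = 0, accel_max10 = 0)
        else msac_accel_profile(sp$v)
  out <- c(dur, H, S, msac_sharpness(H, S), base, dbl$ratio, dbl$flag,
           sp$v_av, sp$v_max11, sp$v_max21, ac$accel_av, ac$accel_max10,
           msac_max_diameter(ms))
  names(out) <- feature_names()
  out
}

#' Feature matrix of a segment
#'
#' @param segment An `msacc_segment` from [build_segments()].
#' @return Numeric matrix, one row per microsaccade, 13 named columns.
#' @export
segment_features <- function(segment) {
  if (!inherits(segment, "msacc_segment")) stop("expected an msacc_segment")
  t(vapply(segment$microsaccades, extract_features, numeric(13),
           rate_hz = segment$rate_hz))
}

#' Unit-vector feature normalization
#'
#' Each of the 13 feature columns is divided by its Euclidean norm computed
#' over the training vectors only; the same scales are applied to any other
#' vectors (test data never influences the scales). All-zero columns keep
#' scale 1.
#'
#' @param train Numeric matrix (rows = events, 13 columns).
#' @param others Optional matrix to scale with the train-derived scales.
#' @return List: `train`, `others` (NULL if not given), `scales` (length 13).
#' @export
normalize_features <- function(train, others = NULL) {
  if (!is.matrix(train) || nrow(train) == 0L) stop("train must be a non-empty matrix")
  scales <- sqrt(colSums(train^2))
  scales[scales == 0] <- 1
  out_train <- sweep(train, 2L, scales, "/")
  out_others <- if (!is.null(others)) sweep(others, 2L, scales, "/")
  list(train = out_train, others = out_others, scales = scales)
}
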