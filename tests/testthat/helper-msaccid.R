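# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (brute force / closed form), independent of the
# package's implementation paths.

# random open polyline with coordinates in [-1, 1]
random_polyline <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(x = stats::runif(n, -1, 1), y = stats::runif(n, -1, 1))
}

# --- oracle: brute-force intersection of two closed segments -----------------
# Parametric solve written with explicit cross products (different route from
# the package's 2x2 linear system).
oracle_segment_intersection <- function(p1, p2, p3, p4) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-14) return(NULL)
  q <- p3 - p1
  t <- unname((q[1] * s[2] - q[2] * s[1]) / denom)
  u <- unname((q[1] * r[2] - q[2] * r[1]) / denom)
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NULL)
  list(t = t, u = u, point = unname(p1 + t * r))
}

# all non-adjacent edge crossings of an open polyline, brute force
oracle_self_intersections <- function(pts) {
  n <- nrow(pts)
  hits <- list()
  for (k in seq_len(n - 1L)) for (l in seq_len(n - 1L)) {
    if (l <= k + 1L) next
    hit <- oracle_segment_intersection(pts[k, ], pts[k + 1L, ],
                                       pts[l, ], pts[l + 1L, ])
    if (!is.null(hit))
      hits[[length(hits) + 1L]] <- c(k = k, l = l, lambda = hit$t, mu = hit$u,
                                     x = hit$point[1], y = hit$point[2])
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# plain shoelace on an open vertex list (implicit closure)
oracle_shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1])) / 2)
}

# random simple (star-shaped) polygon: vertices at sorted angles
random_simple_polygon <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.3, 1)
  cbind(x = r * cos(ang), y = r * sin(ang))
}

# --- oracle: Heron-formula height -------------------------------------------
oracle_heron_height <- function(pts) {
  n <- nrow(pts)
  dd <- function(a, b) sqrt(sum((a - b)^2))
  base <- dd(pts[1, ], pts[n, ])
  best <- 0
  for (i in 2:(n - 1L)) {
    a <- dd(pts[1, ], pts[i, ]); b <- dd(pts[n, ], pts[i, ])
    p <- (a + b + base) / 2
    rad <- max(p * (p - a) * (p - b) * (p - base), 0)
    h <- 2 * sqrt(rad) / base
    best <- max(best, h)
  }
  best
}

# --- oracle: sliding-window mean maximum ------------------------------------
oracle_windowed_max <- function(v, w) {
  if (length(v) < w) return(mean(v))
  max(vapply(seq_len(length(v) - w + 1L),
             function(i) mean(v[i:(i + w - 1L)]), numeric(1)))
}

# --- interval matching -------------------------------------------------------
interval_overlap <- function(a, b) {
  max(0, min(a[2], b[2]) - max(a[1], b[1]))
}

# one-to-one greedy matching by overlap; returns c(tp, n_det, n_truth)
match_intervals <- function(detected, truth) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(detected))) {
    for (j in seq_len(nrow(truth))) {
      if (!used[j] && interval_overlap(detected[i, ], truth[j, ]) > 0) {
        used[j] <- TRUE; tp <- tp + 1L; break
      }
    }
  }
  c(tp = tp, n_det = nrow(detected), n_truth = nrow(truth))
}

interval_f1 <- function(detected, truth) {
  m <- match_intervals(detected, truth)
  if (m["n_det"] == 0 || m["n_truth"] == 0) return(0)
  prec <- m["tp"] / m["n_det"]; rec <- m["tp"] / m["n_truth"]
  if (prec + rec == 0) return(0)
  unname(2 * prec * rec / (prec + rec))
}

# small deterministic feature cohort for metric/optimizer tests:
# persons with shifted feature distributions, no trace simulation involved
toy_feature_cohort <- function(n_persons = 3, n_segments = 3, n_events = 6,
                               sep = 2, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n_persons), function(p) {
    center <- stats::runif(13, 0, 1) + sep * p
    lapply(seq_len(n_segments), function(s) {
      matrix(stats::rnorm(n_events * 13, mean = rep(center, each = n_events),
                          sd = 0.1), n_events, 13)
    })
  })
}

# evaluate the package windowed max speed through an event built from speeds
windowed_max_mean_for_test <- function(v, w) {
  ev <- cbind(x = cumsum(c(0, v)), y = 0)
  msac_speed_profile(ev)[[if (w == 11) "v_max11" else "v_max21"]]
}

empty_intervals_for_test <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}
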