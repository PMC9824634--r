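# Linear and quasilinear feature-space distances, segment and person
# distances, the within/between-person error ratio and the between-person
# summary matrix.
#
# A weight vector has 91 nonnegative components: 13 single-feature weights
# followed by the 78 cross-term weights w_{i,j}, i < j, in lexicographic
# order ((1,2), (1,3), ..., (1,13), (2,3), ...). After projection the vector
# has unit Euclidean norm; the error ratio itself is scale-invariant.

N_FEATURES <- 13L
N_WEIGHTS <- 91L

# lexicographic i<j index pairs for the 78 cross terms
cross_index <- local({
  ij <- which(upper.tri(matrix(0, N_FEATURES, N_FEATURES)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  list(i = ij[, 1L], j = ij[, 2L])
})

#' Weight-vector layout
#'
#' @return Data frame with 91 rows and columns `index`, `i`, `j`, `kind`
#'   (`"single"` where `i == j`, `"cross"` for `i < j`).
#' @export
weight_layout <- function() {
  data.frame(index = seq_len(N_WEIGHTS),
             i = c(seq_len(N_FEATURES), cross_index$i),
             j = c(seq_len(N_FEATURES), cross_index$j),
             kind = rep(c("single", "cross"), c(N_FEATURES, 78L)))
}

check_weights <- function(w, n = N_WEIGHTS) {
  if (!is.numeric(w) || length(w) != n)
    stop("weight vector must have length ", n)
  if (any(!is.finite(w))) stop("weights must be finite")
  w
}

# Quadratic feature map of a difference vector: (delta_i^2, delta_i*delta_j).
phi_delta <- function(delta) {
  c(delta^2, delta[cross_index$i] * delta[cross_index$j])
}

# Rectifier turning the (possibly negative) raw quasilinear value into a
# usable distance. The indefinite cross terms can drive the raw form
# negative; clamping at zero would give the learning objective a degenerate
# optimum (any weight vector pushing all within-person values negative has a
# zero numerator regardless of the between-person geometry), so distances
# use the magnitude of the form instead.
rectify_rho <- function(v) abs(v)

#' Linear weighted distance between two feature vectors
#'
#' `rho(A, B) = sum_i w_i (P_i^A - P_i^B)^2`: nonnegative, symmetric, and
#' zero iff the features agree (for strictly positive weights).
#'
#' @param fa,fb Feature vectors of length 13 (same normalization).
#' @param w13 Nonnegative weights of length 13.
#' @return Nonnegative scalar.
#' @export
rho_linear <- function(fa, fb, w13) {
  check_weights(w13, N_FEATURES)
  if (length(fa) != N_FEATURES || length(fb) != N_FEATURES)
    stop("feature vectors must have length ", N_FEATURES)
  sum(w13 * (fa - fb)^2)
}

#' Quasilinear weighted distance between two feature vectors
#'
#' The linear part plus weighted products of pairs of feature differences:
#' `rho_ql = sum_i w_i d_i^2 + sum_{i<j} w_{i,j} d_i d_j` with
#' `d = fA - fB`. The raw value of the cross terms can be negative (the
#' weight form is indefinite); as a distance the magnitude of the form is
#' used (`signed = TRUE` exposes the raw value).
#'
#' @param fa,fb Feature vectors of length 13.
#' @param w Weight vector of length 91.
#' @param signed Return the raw signed value instead of the magnitude.
#' @return Scalar (nonnegative unless `signed`).
#' @export
rho_quasilinear <- function(fa, fb, w, signed = FALSE) {
  check_weights(w)
  if (length(fa) != N_FEATURES || length(fb) != N_FEATURES)
    stop("feature vectors must have length ", N_FEATURES)
  val <- sum(w * phi_delta(fa - fb))
  if (signed) val else rectify_rho(val)
}

as_feature_matrix <- function(T1) {
  if (inherits(T1, "msacc_segment")) T1 <- segment_features(T1)
  if (!is.matrix(T1) || ncol(T1) != N_FEATURES || nrow(T1) == 0L)
    stop("a segment must be a non-empty n x 13 feature matrix")
  T1
}

#' Minimum-pair segment distance (d1)
#'
#' Minimum quasilinear distance over all cross pairs of microsaccades from
#' the two segments: an optimistic estimate that ignores outliers, but it
#' does not satisfy the triangle inequality.
#'
#' @param T1,T2 Segments: n x 13 feature matrices (or `msacc_segment`s).
#' @param w Weight vector of length 91.
#' @return Nonnegative scalar.
#' @export
seg_dist_d1 <- function(T1, T2, w) {
  T1 <- as_feature_matrix(T1); T2 <- as_feature_matrix(T2)
  check_weights(w)
  best <- Inf
  for (a in seq_len(nrow(T1))) {
    d <- T2 - matrix(T1[a, ], nrow(T2), N_FEATURES, byrow = TRUE)
    vals <- d^2 %*% w[seq_len(N_FEATURES)] +
      (d[, cross_index$i, drop = FALSE] * d[, cross_index$j, drop = FALSE]) %*%
        w[(N_FEATURES + 1L):N_WEIGHTS]
    best <- min(best, min(rectify_rho(as.numeric(vals))))
  }
  best
}

#' Mass center of a segment
#'
#' Coordinate-wise mean of the segment's feature vectors. With `trim < 1`,
#' members are ranked by their quasilinear distance to the untrimmed mean and
#' only the `ceil(trim * n)` closest are averaged, discarding outliers.
#'
#' @param T1 Segment feature matrix.
#' @param trim Fraction of members kept (NULL or 1 = untrimmed).
#' @param w Weight vector (needed when trimming).
#' @return Feature vector of length 13.
#' @export
mass_center <- function(T1, trim = NULL, w = NULL) {
  T1 <- as_feature_matrix(T1)
  center <- colMeans(T1)
  if (is.null(trim) || trim >= 1) return(center)
  if (trim <= 0) stop("trim must be in (0, 1]")
  check_weights(w)
  d <- sweep(T1, 2L, center)
  vals <- d^2 %*% w[seq_len(N_FEATURES)] +
    (d[, cross_index$i, drop = FALSE] * d[, cross_index$j, drop = FALSE]) %*%
      w[(N_FEATURES + 1L):N_WEIGHTS]
  vals <- rectify_rho(as.numeric(vals))
  keep <- order(vals)[seq_len(ceiling(trim * nrow(T1)))]
  colMeans(T1[keep, , drop = FALSE])
}

#' Mass-center segment distance (d2)
#'
#' Quasilinear distance between the untrimmed mass centers of two segments.
#' @inheritParams seg_dist_d1
#' @return Nonnegative scalar.
#' @export
seg_dist_d2 <- function(T1, T2, w) {
  rho_quasilinear(mass_center(T1), mass_center(T2), w)
}

#' Trimmed mass-center segment distance (d3)
#'
#' Quasilinear distance between trimmed mass centers (default: the 90%
#' closest members to each segment's mean), combining the center-based
#' distance with outlier rejection.
#'
#' @inheritParams seg_dist_d1
#' @param trim Fraction of members kept.
#' @return Nonnegative scalar.
#' @export
seg_dist_d3 <- function(T1, T2, w, trim = 0.9) {
  rho_quasilinear(mass_center(T1, trim, w), mass_center(T2, trim, w), w)
}

seg_dist_fn <- function(method = c("d3", "d1", "d2"), trim = 0.9) {
  method <- match.arg(method)
  switch(method,
         d1 = function(T1, T2, w) seg_dist_d1(T1, T2, w),
         d2 = function(T1, T2, w) seg_dist_d2(T1, T2, w),
         d3 = function(T1, T2, w) seg_dist_d3(T1, T2, w, trim))
}

#' Person distance
#'
#' Minimum segment distance over all cross pairs of the two persons'
#' segments.
#'
#' @param K1,K2 Persons: lists of segment feature matrices.
#' @param w Weight vector.
#' @param method Segment distance: `"d3"` (default), `"d1"` or `"d2"`.
#' @param trim Trim fraction for `"d3"`.
#' @return Nonnegative scalar.
#' @export
person_dist <- function(K1, K2, w, method = "d3", trim = 0.9) {
  if (!length(K1) || !length(K2)) stop("each person needs at least one segment")
  d <- seg_dist_fn(method, trim)
  min(vapply(K1, function(T1)
    min(vapply(K2, function(T2) d(T1, T2, w), numeric(1))), numeric(1)))
}

#' Within/between-person error ratio
#'
#' The objective of the weight learning: the sum of segment distances within
#' persons (all unordered pairs of each person's segments) divided by the sum
#' of segment distances between different persons (ordered person pairs
#' `i != k`, all segment pairs). Scale-invariant in `w` and bounded below
#' by 0; smaller is better.
#'
#' @param w Weight vector of length 91.
#' @param fcohort List of persons, each a list of segment feature matrices
#'   (at least 2 persons with 2 segments each).
#' @param method,trim Segment distance selection.
#' @return Scalar in `[0, Inf)` (typically `[0, 1]`).
#' @export
err_ratio <- function(w, fcohort, method = "d3", trim = 0.9) {
  f <- make_err_fn(fcohort, method, trim)
  f(w)
}

#' Precompiled error function for a fixed cohort
#'
#' Precomputes per-segment feature matrices, untrimmed means and the
#' quadratic feature maps used by the trim ranking, returning a fast
#' `function(w)` evaluating the error ratio. This is the objective handed to
#' the optimizer, where it is called thousands of times.
#'
#' @inheritParams err_ratio
#' @return A function of a 91-weight vector.
#' @export
make_err_fn <- function(fcohort, method = "d3", trim = 0.9) {
  if (length(fcohort) < 2L) stop("need at least 2 persons")
  fcohort <- lapply(fcohort, function(p) lapply(p, as_feature_matrix))
  if (any(vapply(fcohort, length, integer(1)) < 2L))
    stop("each person needs at least 2 segments")
  n_persons <- length(fcohort)
  idx <- list()
  for (i in seq_len(n_persons)) for (j in seq_along(fcohort[[i]]))
    idx[[length(idx) + 1L]] <- c(i, j)
  seg_person <- vapply(idx, `[[`, integer(1), 1L)
  segs <- lapply(idx, function(ij) fcohort[[ij[1L]]][[ij[2L]]])
  S <- length(segs)

  within_pairs <- do.call(rbind, lapply(seq_len(n_persons), function(i) {
    js <- which(seg_person == i)
    if (length(js) < 2L) return(NULL)
    t(utils::combn(js, 2L))
  }))
  between_pairs <- do.call(rbind, lapply(seq_len(S), function(a) {
    b <- which(seg_person != seg_person[a])
    cbind(a, b)
  }))

  ws <- seq_len(N_FEATURES)
  wc <- (N_FEATURES + 1L):N_WEIGHTS
  ci <- cross_index$i; cj <- cross_index$j

  if (method == "d3" && !is.null(trim) && trim < 1) {
    means <- lapply(segs, colMeans)
    # per-segment quadratic maps of member deviations, for the trim ranking
    phis <- lapply(seq_len(S), function(s) {
      d <- sweep(segs[[s]], 2L, means[[s]])
      cbind(d^2, d[, ci, drop = FALSE] * d[, cj, drop = FALSE])
    })
    keep_n <- vapply(segs, function(m) ceiling(trim * nrow(m)), numeric(1))
    function(w) {
      check_weights(w)
      centers <- matrix(0, S, N_FEATURES)
      for (s in seq_len(S)) {
        vals <- rectify_rho(as.numeric(phis[[s]] %*% w))
        keep <- order(vals)[seq_len(keep_n[s])]
        centers[s, ] <- colMeans(segs[[s]][keep, , drop = FALSE])
      }
      err_from_centers(centers, w, within_pairs, between_pairs, ws, wc, ci, cj)
    }
  } else if (method == "d2" || (method == "d3" && (is.null(trim) || trim >= 1))) {
    centers <- do.call(rbind, lapply(segs, colMeans))
    function(w) {
      check_weights(w)
      err_from_centers(centers, w, within_pairs, between_pairs, ws, wc, ci, cj)
    }
  } else if (method == "d1") {
    function(w) {
      check_weights(w)
      d1 <- function(a, b) seg_dist_d1(segs[[a]], segs[[b]], w)
      num <- sum(vapply(seq_len(nrow(within_pairs)), function(r)
        d1(within_pairs[r, 1L], within_pairs[r, 2L]), numeric(1)))
      den <- sum(vapply(seq_len(nrow(between_pairs)), function(r)
        d1(between_pairs[r, 1L], between_pairs[r, 2L]), numeric(1)))
      if (den <= 0) stop("degenerate cohort: zero between-person distance")
      num / den
    }
  } else stop("unknown method")
}

err_from_centers <- function(centers, w, within_pairs, between_pairs,
                             ws, wc, ci, cj) {
  pair_sum <- function(pairs) {
    d <- centers[pairs[, 1L], , drop = FALSE] - centers[pairs[, 2L], , drop = FALSE]
    vals <- d^2 %*% w[ws] +
      (d[, ci, drop = FALSE] * d[, cj, drop = FALSE]) %*% w[wc]
    sum(rectify_rho(as.numeric(vals)))
  }
  den <- pair_sum(between_pairs)
  if (den <= 0) stop("degenerate cohort: zero between-person distance")
  pair_sum(within_pairs) / den
}

#' Between-person summary distance matrix
#'
#' `F[i, k]` is the mean of all cross-segment distances between persons `i`
#' and `k` (25 pairs when both have 5 segments). Symmetric when the segment
#' distance is symmetric.
#'
#' @inheritParams err_ratio
#' @return Symmetric numeric matrix with person labels.
#' @export
between_person_matrix <- function(fcohort, w, method = "d3", trim = 0.9) {
  fcohort <- lapply(fcohort, function(p) lapply(p, as_feature_matrix))
  d <- seg_dist_fn(method, trim)
  n <- length(fcohort)
  F_mat <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    vals <- outer(seq_along(fcohort[[i]]), seq_along(fcohort[[k]]),
                  Vectorize(function(a, b) d(fcohort[[i]][[a]], fcohort[[k]][[b]], w)))
    F_mat[i, k] <- mean(vals)
  }
  nms <- names(fcohort) %||% paste0("P", seq_len(n))
  dimnames(F_mat) <- list(nms, nms)
  F_mat
}
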