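# Distance functions: printed axioms, segment/person distances, the error
# ratio and its invariances.

fv <- function(...) { v <- numeric(13); vals <- c(...); v[seq_along(vals)] <- vals; v }

test_that("weight layout has 13 singles and 78 lexicographic cross terms", {
  lay <- weight_layout()
  expect_equal(nrow(lay), 91)
  expect_equal(sum(lay$kind == "single"), 13)
  expect_equal(sum(lay$kind == "cross"), 78)
  cross <- lay[lay$kind == "cross", ]
  expect_true(all(cross$i < cross$j))
  expect_equal(cross$i[1:12], rep(1, 12))
  expect_equal(cross$j[1:12], 2:13)
  expect_equal(cross[nrow(cross), "i"], 12)
  expect_equal(cross[nrow(cross), "j"], 13)
})

test_that("linear rho satisfies the printed distance axioms", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(13); b <- runif(13); w <- runif(13)
    expect_equal(rho_linear(a, a, w), 0)
    expect_equal(rho_linear(a, b, w), rho_linear(b, a, w))
    expect_gte(rho_linear(a, b, w), 0)
    # identity of indiscernibles for strictly positive weights
    if (rho_linear(a, b, w + 0.1) == 0) expect_equal(a, b)
    # triangle inequality holds for the linear form (weighted squared L2):
    # rho is a squared metric, so test on sqrt scale
    cc <- runif(13)
    expect_lte(sqrt(rho_linear(a, b, w)),
               sqrt(rho_linear(a, cc, w)) + sqrt(rho_linear(cc, b, w)) + 1e-12)
  }
  expect_equal(rho_linear(fv(1), fv(0), rep(1, 13)), 1)
  expect_error(rho_linear(runif(12), runif(13), rep(1, 13)), "length")
})

test_that("quasilinear rho reduces to the linear form and expands cross terms", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(13); b <- runif(13)
    w <- c(runif(13), rep(0, 78))
    expect_equal(rho_quasilinear(a, b, w), rho_linear(a, b, w[1:13]),
                 tolerance = 1e-12)
    expect_equal(rho_quasilinear(a, a, w), 0)
    wfull <- runif(91)
    expect_equal(rho_quasilinear(a, b, wfull), rho_quasilinear(b, a, wfull))
  }
  # hand expansion: only w_{1,2} = 1, differences (1, 1, 0, ...)
  w <- numeric(91); w[14] <- 1
  expect_equal(rho_quasilinear(fv(1, 1), fv(0, 0), w), 1)
  # signed raw value is exposed: opposite-sign differences give a negative raw
  expect_equal(rho_quasilinear(fv(1, -1), fv(0, 0), w, signed = TRUE), -1)
  expect_gte(rho_quasilinear(fv(1, -1), fv(0, 0), w), 0)
  expect_error(rho_quasilinear(fv(1), fv(0), rep(1, 13)), "length")
})

test_that("d1 is a minimum over event pairs and violates the triangle inequality", {
  w <- project_weights(rep(1, 91))
  ev_a <- rbind(fv(0), fv(5))
  ev_b <- rbind(fv(5), fv(10))
  expect_equal(seg_dist_d1(ev_a, ev_b, w), 0)     # shared event
  s1 <- rbind(fv(1)); s2 <- rbind(fv(2))
  expect_equal(seg_dist_d1(s1, s2, w), rho_quasilinear(fv(1), fv(2), w))
  # T2 contains events near both T1 and T3: d1(T1,T2) = d1(T2,T3) = 0 but
  # d1(T1,T3) > 0
  T1 <- rbind(fv(0)); T3 <- rbind(fv(10)); T2 <- rbind(fv(0), fv(10))
  expect_equal(seg_dist_d1(T1, T2, w), 0)
  expect_equal(seg_dist_d1(T2, T3, w), 0)
  expect_gt(seg_dist_d1(T1, T3, w),
            seg_dist_d1(T1, T2, w) + seg_dist_d1(T2, T3, w))
  expect_error(seg_dist_d1(matrix(numeric(0), 0, 13), s2, w), "non-empty")
})

test_that("mass centers average features and trimming rejects outliers", {
  w <- project_weights(rep(1, 91))
  two <- rbind(fv(0), fv(2))
  expect_equal(mass_center(two), fv(1))
  common <- matrix(rep(fv(1, 2, 3), each = 10), 10, 13)
  outlier <- matrix(fv(50, -20, 8), 1, 13)
  seg <- rbind(common, outlier)
  expect_equal(mass_center(seg, trim = 0.9, w = w), fv(1, 2, 3), tolerance = 1e-12)
  expect_equal(mass_center(seg, trim = 1), colMeans(seg))
})

test_that("d2 and d3 compare (trimmed) centers", {
  w <- project_weights(rep(1, 91))
  seg <- matrix(runif(5 * 13), 5, 13)
  expect_equal(seg_dist_d2(seg, seg, w), 0)
  expect_equal(seg_dist_d3(seg, seg, w), 0)
  s1 <- rbind(fv(1)); s2 <- rbind(fv(3))
  expect_equal(seg_dist_d2(s1, s2, w), rho_quasilinear(fv(1), fv(3), w))
  expect_equal(seg_dist_d3(s1, s2, w), rho_quasilinear(fv(1), fv(3), w))
  # adding one far outlier changes d3 less than d2
  set.seed(9)
  base <- matrix(rnorm(10 * 13, 5, 0.1), 10, 13)
  other <- matrix(rnorm(10 * 13, 6, 0.1), 10, 13)
  contaminated <- rbind(base, fv(100, 100, 100))
  d2_shift <- abs(seg_dist_d2(contaminated, other, w) - seg_dist_d2(base, other, w))
  d3_shift <- abs(seg_dist_d3(contaminated, other, w) - seg_dist_d3(base, other, w))
  expect_lt(d3_shift, d2_shift)
})

test_that("person distance is the minimum over segment pairs", {
  w <- project_weights(rep(1, 91))
  K1 <- list(rbind(fv(0)), rbind(fv(4)))
  K2 <- list(rbind(fv(4.5)), rbind(fv(9)))
  dp <- person_dist(K1, K2, w, method = "d2")
  cross <- c(seg_dist_d2(K1[[1]], K2[[1]], w), seg_dist_d2(K1[[1]], K2[[2]], w),
             seg_dist_d2(K1[[2]], K2[[1]], w), seg_dist_d2(K1[[2]], K2[[2]], w))
  expect_equal(dp, min(cross))
  expect_true(all(dp <= cross))
  expect_equal(person_dist(K1, K1, w), 0)
})

test_that("the error ratio is scale-invariant, bounded and permutation-stable", {
  fco <- toy_feature_cohort()
  w <- random_weights(5)
  e1 <- err_ratio(w, fco)
  expect_gte(e1, 0)
  for (alpha in c(0.5, 2, 10)) {
    expect_equal(err_ratio(alpha * w, fco), e1, tolerance = 1e-12)
  }
  # person relabelling leaves Err unchanged
  expect_equal(err_ratio(w, fco[c(3, 1, 2)]), e1, tolerance = 1e-12)
  # identical segments within each person: zero numerator
  seg <- matrix(runif(4 * 13), 4, 13)
  seg2 <- matrix(runif(4 * 13) + 3, 4, 13)
  clone_cohort <- list(list(seg, seg), list(seg2, seg2))
  expect_equal(err_ratio(w, clone_cohort), 0)
  # degenerate cohort: all persons identical
  expect_error(err_ratio(w, list(list(seg, seg), list(seg, seg))), "degenerate")
  expect_error(make_err_fn(list(list(seg, seg))), "2 persons")
  expect_error(make_err_fn(list(list(seg), list(seg2))), "2 segments")
})

test_that("err_ratio agrees with a direct from-definition computation", {
  fco <- toy_feature_cohort(n_persons = 2, n_segments = 3, n_events = 4)
  w <- random_weights(11)
  # brute-force reference written straight from the definition
  num <- 0; den <- 0
  for (i in seq_along(fco)) {
    segs <- fco[[i]]
    for (a in 1:2) for (b in (a + 1):3)
      num <- num + seg_dist_d3(segs[[a]], segs[[b]], w)
  }
  for (i in seq_along(fco)) for (k in seq_along(fco)) {
    if (i == k) next
    for (a in 1:3) for (b in 1:3)
      den <- den + seg_dist_d3(fco[[i]][[a]], fco[[k]][[b]], w)
  }
  expect_equal(err_ratio(w, fco), num / den, tolerance = 1e-12)
  # d1 and d2 methods run through the same contract
  expect_equal(err_ratio(w, fco, method = "d2"),
               local({
                 n2 <- 0; d2s <- 0
                 for (i in 1:2) for (a in 1:2) for (b in (a + 1):3)
                   n2 <- n2 + seg_dist_d2(fco[[i]][[a]], fco[[i]][[b]], w)
                 for (i in 1:2) for (k in 1:2) if (i != k)
                   for (a in 1:3) for (b in 1:3)
                     d2s <- d2s + seg_dist_d2(fco[[i]][[a]], fco[[k]][[b]], w)
                 n2 / d2s
               }), tolerance = 1e-12)
})

test_that("the between-person matrix averages cross-segment distances", {
  fco <- toy_feature_cohort(n_persons = 3, n_segments = 5, n_events = 4)
  w <- random_weights(3)
  F_mat <- between_person_matrix(fco, w)
  expect_equal(dim(F_mat), c(3, 3))
  expect_equal(F_mat, t(F_mat), tolerance = 1e-12)
  # diagonal (within-person) entries are smaller than off-diagonal ones
  expect_true(all(diag(F_mat) < F_mat[upper.tri(F_mat)]))
  # single-segment persons: F equals the single distance
  one <- list(list(fco[[1]][[1]]), list(fco[[2]][[1]]))
  F1 <- between_person_matrix(one, w)
  expect_equal(F1[1, 2], seg_dist_d3(fco[[1]][[1]], fco[[2]][[1]], w))
})
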