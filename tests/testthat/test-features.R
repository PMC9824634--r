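# The 13 trajectory features: worked examples, oracle equivalences and
# geometric invariances.

test_that("duration counts samples minus one in ms", {
  line50 <- cbind(x = seq(0, 0.2, length.out = 50), y = 0)
  expect_equal(msac_duration(line50), 49)
  expect_equal(msac_duration(line50[1:2, ]), 1)
  expect_equal(msac_duration(line50[1:11, ]), 10)
  expect_error(msac_duration(line50[1, , drop = FALSE]), "at least 2")
})

test_that("height handles open, collinear and closed trajectories", {
  expect_equal(msac_height(cbind(c(0, 1, 2), c(0, 1, 0))), 1)
  expect_equal(msac_height(cbind(c(0, 1, 2), c(0, 0, 0))), 0)
  # closed loop: zero base -> distance-to-start branch
  loop <- cbind(c(0, 0, 1, 0), c(0, 2, 2, 0))
  expect_equal(msac_height(loop), sqrt(5))
  expect_equal(msac_height(cbind(c(0, 1), c(0, 1))), 0)
})

test_that("height equals the Heron-formula value on random events", {
  for (s in 1:100) {
    pts <- random_polyline(12, seed = 4000 + s)
    if (msac_base_length(pts) < 1e-6) next
    expect_equal(msac_height(pts), oracle_heron_height(pts), tolerance = 1e-9)
  }
})

test_that("self-intersections match the brute-force oracle", {
  # symmetric X
  pts <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  hits <- msac_self_intersections(pts)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$x, hits$y), c(0.5, 0.5))
  expect_equal(c(hits$lambda, hits$mu), c(0.5, 0.5))
  # parallel segments never cross
  par <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(nrow(msac_self_intersections(par)), 0)
  # oracle equivalence on random 20-point polylines
  for (s in 1:100) {
    pts <- random_polyline(20, seed = 900 + s)
    got <- msac_self_intersections(pts)
    want <- oracle_self_intersections(pts)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      ord_g <- order(got$k, got$l)
      ord_w <- order(want[, "k"], want[, "l"])
      expect_equal(got$k[ord_g], unname(want[ord_w, "k"]))
      expect_equal(got$l[ord_g], unname(want[ord_w, "l"]))
      expect_equal(got$lambda[ord_g], unname(want[ord_w, "lambda"]),
                   tolerance = 1e-9)
      expect_equal(got$x[ord_g], unname(want[ord_w, "x"]), tolerance = 1e-9)
    }
  }
})

test_that("area equals shoelace on simple polygons", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(msac_area(square), 1)
  expect_equal(msac_area(square[1:2, ]), 0)
  for (s in 1:100) {
    poly <- random_simple_polygon(10, seed = 1700 + s)
    expect_equal(msac_area(poly), oracle_shoelace(poly), tolerance = 1e-9)
  }
})

test_that("self-crossing areas equal the decomposition oracle", {
  # figure-eight: two triangles joined at (1,1)
  fig8 <- cbind(c(1, 0, 0, 1, 2, 2), c(1, 1, 0, 1, 1, 0))
  t1 <- cbind(c(1, 0, 0), c(1, 1, 0))
  t2 <- cbind(c(1, 2, 2), c(1, 1, 0))
  expect_equal(msac_area(fig8), oracle_shoelace(t1) + oracle_shoelace(t2),
               tolerance = 1e-9)
  # random bowties: 4 points whose closure self-crosses once
  n_checked <- 0
  for (s in 1:400) {
    set.seed(2500 + s)
    pts <- cbind(runif(4, -1, 1), runif(4, -1, 1))
    hit <- oracle_segment_intersection(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    hits_all <- msac_self_intersections(pts, closed = TRUE)
    if (is.null(hit) || nrow(hits_all) != 1) next
    n_checked <- n_checked + 1
    X <- hit$point
    lobe1 <- rbind(X, pts[2, ], pts[3, ])
    lobe2 <- rbind(X, pts[4, ], pts[1, ])
    expect_equal(msac_area(pts), oracle_shoelace(lobe1) + oracle_shoelace(lobe2),
                 tolerance = 1e-9)
  }
  expect_gte(n_checked, 50)
})

test_that("sharpness composes height and area with safe degenerate cases", {
  expect_equal(msac_sharpness(1, 2), 0.5)
  expect_equal(msac_sharpness(0, 0), 0)
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  f <- extract_features(square)
  expect_equal(f[["sharpness"]], f[["height"]] / 1)
})

test_that("base length and double classification follow their definitions", {
  expect_equal(msac_base_length(cbind(c(0, 1, 3), c(0, 1, 4))), 5)
  loop <- cbind(c(0, 1, 0), c(0, 1, 0))
  expect_equal(msac_base_length(loop), 0)
  expect_equal(double_classify(0.4, 50)$flag, 1)   # ratio 0.008
  expect_equal(double_classify(1, 50)$flag, 0)     # ratio 0.02
  expect_equal(double_classify(0.5, 50)$flag, 0)   # exactly 0.01: mono
  expect_error(double_classify(1, 0), "> 0")
})

test_that("speed summaries match the sliding-mean oracle", {
  # constant speed
  ev <- cbind(x = seq(0, 2.9, by = 0.1), y = 0)
  sp <- msac_speed_profile(ev)
  expect_equal(sp$v_av, 0.1, tolerance = 1e-12)
  expect_equal(sp$v_max11, 0.1, tolerance = 1e-12)
  expect_equal(sp$v_max21, 0.1, tolerance = 1e-12)
  # single spike of displacement among 30 steps
  steps <- rep(0, 30); steps[15] <- 1
  ev <- cbind(x = cumsum(c(0, steps)), y = 0)
  sp <- msac_speed_profile(ev)
  expect_equal(sp$v_max11, 1 / 11, tolerance = 1e-12)
  # short event: fallback to the average
  ev8 <- cbind(x = cumsum(c(0, runif(7))), y = 0)
  sp8 <- msac_speed_profile(ev8)
  expect_equal(sp8$v_max11, sp8$v_av)
  # random events vs oracle
  for (s in 1:100) {
    set.seed(600 + s)
    v <- runif(sample(5:40, 1))
    expect_equal(windowed_max_mean_for_test(v, 11), oracle_windowed_max(v, 11),
                 tolerance = 1e-12)
  }
})


test_that("pseudo accelerations average correctly", {
  expect_equal(msac_accel_profile(c(1, 1, 1, 1))$accel_av, 0)
  expect_equal(msac_accel_profile(c(0, 1, 2, 3))$accel_av, 1)
  for (s in 1:50) {
    set.seed(70 + s)
    v <- runif(20)
    a <- diff(v)
    want <- mean(sort(abs(a), decreasing = TRUE)[1:10])
    expect_equal(msac_accel_profile(v)$accel_max10, want, tolerance = 1e-12)
  }
  short <- runif(5)
  expect_equal(msac_accel_profile(short)$accel_max10,
               mean(abs(diff(short))), tolerance = 1e-12)
  expect_warning(res <- msac_accel_profile(numeric(1)), "undefined")
  expect_equal(res$accel_av, 0)
})

test_that("maximal diameter dominates base length and height", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(msac_max_diameter(sq), sqrt(2))
  two <- cbind(c(0, 3), c(0, 4))
  expect_equal(msac_max_diameter(two), msac_base_length(two))
  for (s in 1:50) {
    pts <- random_polyline(15, seed = 300 + s)
    dmax <- msac_max_diameter(pts)
    expect_gte(dmax, msac_base_length(pts) - 1e-12)
    expect_gte(dmax, msac_height(pts) - 1e-12)
  }
})

test_that("the full feature vector has the canonical layout", {
  line50 <- cbind(x = seq(0, 0.2, length.out = 50), y = 0)
  f <- extract_features(line50)
  expect_length(f, 13)
  expect_equal(names(f), feature_names())
  expect_equal(f[["duration"]], 49)
  expect_equal(unname(f[c("height", "area", "sharpness")]), c(0, 0, 0))
})

test_that("features are invariant under translation and distance features under rotation", {
  rot <- function(pts, th) pts %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  rot_invariant <- c("duration", "height", "area", "base_length",
                     "double_ratio", "double_flag", "v_av", "v_max11",
                     "v_max21", "max_diameter")
  for (s in 1:20) {
    pts <- random_polyline(15, seed = 40 + s) * 0.1
    f0 <- extract_features(pts)
    shift <- sweep(pts, 2, c(2.5, -1.3), "+")
    expect_equal(extract_features(shift), f0, tolerance = 1e-8)
    set.seed(s)
    fr <- extract_features(rot(pts, runif(1, 0, 2 * pi)))
    expect_equal(fr[rot_invariant], f0[rot_invariant], tolerance = 1e-7)
  }
})

test_that("unit-vector normalization scales by train-derived column norms", {
  train <- rbind(c(3, rep(1, 12)), c(4, rep(1, 12)))
  others <- rbind(c(10, rep(1, 12)))
  out <- normalize_features(train, others)
  expect_equal(out$train[, 1], c(0.6, 0.8))
  expect_equal(out$others[1, 1], 2)
  expect_equal(unname(sqrt(colSums(out$train^2))), rep(1, 13), tolerance = 1e-12)
  zero <- cbind(rep(0, 3), matrix(1, 3, 12))
  outz <- normalize_features(zero)
  expect_equal(outz$scales[[1]], 1)
  expect_equal(outz$train[, 1], rep(0, 3))
})
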