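test_that("principal_axis recovers known axes and rejects symmetric clouds", {
  tube <- tube_cloud()
  ax <- principal_axis(tube)
  expect_gt(abs(ax[1]), cos(pi / 180))
  # rotate-and-compare oracle
  R <- rot_z(40)
  ax_rot <- principal_axis(tube %*% t(R))
  target <- R %*% c(1, 0, 0)
  expect_gt(abs(sum(ax_rot * target)), cos(pi / 180))
  set.seed(3)
  u <- matrix(rnorm(900), ncol = 3)
  sphere <- u / sqrt(rowSums(u^2))
  expect_error(principal_axis(sphere), class = "degenerate_cloud")
})

test_that("score_angle computes axial angles with endpoint-swap invariance", {
  ax <- c(1, 0, 0)
  expect_equal(score_angle(rbind(c(0, 0, 0), c(1, 0, 0)), ax), 0)
  expect_equal(score_angle(rbind(c(0, 0, 0), c(0, 1, 0)), ax), 90)
  expect_equal(score_angle(rbind(c(0, 0, 0), c(1, 1, 0)), ax), 45)
  expect_equal(score_angle(rbind(c(0, 0, 0), c(1, -1, 0)), ax), 135)
  # swapping endpoints changes nothing (axial data)
  set.seed(6)
  for (i in 1:20) {
    e1 <- runif(3, -1, 1); e2 <- runif(3, -1, 1)
    expect_equal(score_angle(rbind(e1, e2), ax),
                 score_angle(rbind(e2, e1), ax), tolerance = 1e-12)
  }
  # joint rigid rotation of scores, axis and reference leaves the angle
  # unchanged
  R <- rot_z(25)
  for (i in 1:10) {
    e1 <- runif(3, -1, 1); e2 <- runif(3, -1, 1)
    expect_equal(score_angle(rbind(e1, e2), ax),
                 score_angle(rbind(c(R %*% e1), c(R %*% e2)), c(R %*% ax),
                             ref = c(R %*% c(0, 1, 0))),
                 tolerance = 1e-9)
  }
  pit <- data.frame(mark_type = "pit", x1 = NA_real_)
  expect_error(score_angle(pit, ax), class = "not_linear")
})

test_that("circular_summary handles degenerate and balanced samples", {
  s30 <- circular_summary(orientation_sample(c(30, 30, 30)))
  expect_equal(s30$Rbar, 1)
  expect_equal(s30$variance, 0)
  expect_equal(s30$central_deg, c(30, -150), tolerance = 1e-9)
  expect_true(is.na(s30$dispersion) && is.na(s30$skewness))
  # doubled angles at the four compass points cancel exactly
  bal <- circular_summary(orientation_sample(c(0, 45, 90, 135)))
  expect_equal(bal$Rbar, 0, tolerance = 1e-12)
  expect_equal(bal$variance, 1, tolerance = 1e-12)
  # the central orientation pair is 180 degrees apart (mod 360, both
  # reported in (-180, 180])
  set.seed(7)
  cs <- circular_summary(orientation_sample(runif(50, 40, 80)))
  expect_equal(abs(diff(cs$central_deg)) %% 360, 180)
  expect_true(all(cs$central_deg > -180 & cs$central_deg <= 180))
})

test_that("a sample symmetric about its centre has zero skewness", {
  set.seed(9)
  half <- runif(40, 0, 50)
  angles <- c(90 + half, 90 - half)  # exact reflection about 90
  cs <- circular_summary(orientation_sample(angles))
  expect_equal(cs$skewness, 0, tolerance = 1e-9)
  expect_equal(cs$central_deg[1] %% 180, 90, tolerance = 1e-6)
})

test_that("circular variance decreases with von Mises concentration", {
  mean_v <- vapply(c(0.5, 2, 8), function(kap) {
    mean(vapply(1:50, function(i) {
      a <- with_seed <- NULL
      set.seed(8000 + 100 * kap + i)
      th <- osteotrace:::rvonmises(60, pi, kap) / 2 * 180 / pi
      circular_summary(orientation_sample(th))$variance
    }, 0))
  }, 0)
  expect_true(all(diff(mean_v) < 0))
})

test_that("rayleigh_test reproduces the published worked examples", {
  # printed (Rbar, n) pairs with p-values known to 2 significant figures
  cases <- list(list(R = 0.7258, n = 39, p = 1.0e-9),
                list(R = 0.7477, n = 29, p = 3.5e-8),
                list(R = 0.8116, n = 45, p = 6.9e-13),
                list(R = 0.7465, n = 32, p = 1.0e-8),
                list(R = 0.9319, n = 16, p = 5.0e-7))
  for (cc in cases) {
    rt <- rayleigh_test(Rbar = cc$R, n = cc$n)
    expect_equal(signif(rt$p, 2), cc$p)
    expect_equal(rt$statistic, cc$R)
  }
  # Z = 0 gives p = 1; the series bracket collapses to 1
  expect_equal(rayleigh_test(Rbar = 0, n = 20)$p, 1)
  # large-Z fallback: bracket goes negative, leading term takes over
  big <- rayleigh_test(Rbar = 0.8329, n = 363)
  expect_equal(signif(big$p, 2), 4.4e-110)
  expect_error(rayleigh_test(Rbar = 1.2, n = 10), class = "bad_parameter")
  expect_error(rayleigh_test(Rbar = 0.5, n = 3), class = "too_few_points")
})

test_that("rayleigh_test accepts a raw sample and matches the direct mode", {
  set.seed(15)
  ang <- osteotrace:::rvonmises(40, pi / 2, 3) / 2 * 180 / pi
  s <- orientation_sample(ang)
  rt <- rayleigh_test(s)
  cs <- circular_summary(s)
  expect_equal(rt$p, rayleigh_test(Rbar = cs$Rbar, n = 40)$p)
})

test_that("mww_test is calibrated and powered", {
  # identical samples: W ~ 0, p large
  set.seed(4)
  a <- orientation_sample(runif(30, 0, 180))
  suppressWarnings(t0 <- mww_test(a, a, n_rand = 99, seed = 2))
  expect_lt(t0$statistic, 1e-9)
  expect_gte(t0$p, 0.5)
  # concentrated at 0 vs 90 degrees: strong rejection
  rej <- vapply(1:40, function(i) {
    set.seed(9000 + i)
    x <- orientation_sample(osteotrace:::rvonmises(30, 0, 8) / 2 * 180 / pi)
    y <- orientation_sample(osteotrace:::rvonmises(30, pi, 8) / 2 * 180 / pi)
    mww_test(x, y, n_rand = 199, seed = i)$p < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.95)
  expect_error(mww_test(orientation_sample(1:3), a, seed = 1),
               class = "too_few_points")
  # determinism
  b <- orientation_sample(runif(25, 0, 180))
  expect_identical(mww_test(a, b, n_rand = 99, seed = 3)$p,
                   mww_test(a, b, n_rand = 99, seed = 3)$p)
})

test_that("false_positive_risk matches the closed form and is monotone", {
  fp <- false_positive_risk(0.05, 0.5)
  expect_equal(fp$statistic, 0.4072, tolerance = 1e-4)
  expect_equal(fp$p, 0.2894, tolerance = 1e-3)
  # p -> 0 drives FPR -> 0; monotone increasing on (0, 1/e)
  ps <- c(1e-8, 1e-5, 1e-3, 0.01, 0.1, 0.3)
  fprs <- vapply(ps, function(p) false_positive_risk(p)$p, 0)
  expect_true(all(diff(fprs) > 0))
  expect_lt(fprs[1], 1e-6)
  # the tiny published p gives FPR well under the 0.008% bound
  tiny <- false_positive_risk(5.0e-7, 0.5)
  expect_equal(tiny$p, 2.0e-5, tolerance = 0.05)
  expect_lt(tiny$p, 8e-5)
  expect_error(false_positive_risk(0.5), class = "bound_not_informative")
  expect_error(false_positive_risk(0), class = "bad_parameter")
})

test_that("rose_histogram duplicates axial angles into opposite sectors", {
  r <- rose_histogram(orientation_sample(0), 36)
  expect_equal(r$count[1], 1L)   # sector [0, 10)
  expect_equal(r$count[19], 1L)  # sector [180, 190)
  expect_equal(sum(r$count), 2L)
  # flat histogram for a uniform sweep: 180 angles over 36 sectors of 10
  # degrees, each axial angle counted twice
  ru <- rose_histogram(orientation_sample(0:179), 36)
  expect_true(all(ru$count == 10L))
  # conservation: counts always sum to 2n
  set.seed(10)
  n <- 73
  expect_equal(sum(rose_histogram(orientation_sample(runif(n, 0, 180)))$count),
               2L * n)
})

test_that("orientation_report mirrors the published table layout", {
  tp <- small_template(n_points = 800)
  sc <- sample_scores(tp, 60, 90, 4, seed = 31)
  sc$context <- "captive"
  sc$element <- "femur"
  sc$side <- "left"
  rep <- orientation_report(sc, axis = principal_axis(tp))
  expect_named(rep, c("context", "element", "side", "n", "skewness",
                      "kurtosis", "circular_variance", "circular_dispersion",
                      "central_deg_1", "central_deg_2", "Rbar", "rayleigh_p"))
  expect_equal(rep$n, 60L)
  expect_equal(abs(rep$central_deg_1 - rep$central_deg_2) %% 360, 180)
  expect_lt(rep$rayleigh_p, 0.05)  # kappa = 4 concentration is detectable
})
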