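test_that("exact ellipse points are recovered to machine-level accuracy", {
  pts <- ellipse_points(360, cx = 100, cy = 50, a = 40, b = 12)
  f <- fit_ellipse(pts)
  expect_equal(f$cx, 100, tolerance = 1e-6)
  expect_equal(f$cy, 50, tolerance = 1e-6)
  expect_equal(f$a_px, 40, tolerance = 1e-6)
  expect_equal(f$b_px, 12, tolerance = 1e-6)
  expect_equal(f$theta_deg, 0, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-9)

  # rotated case: axes assigned so a_px is the more-horizontal direction
  pts_r <- ellipse_points(100, cx = -20, cy = 7, a = 30, b = 9, theta_deg = 8)
  f_r <- fit_ellipse(pts_r)
  expect_equal(f_r$a_px, 30, tolerance = 1e-6)
  expect_equal(f_r$b_px, 9, tolerance = 1e-6)
  expect_equal(f_r$theta_deg, 8, tolerance = 1e-6)
})

test_that("a circle fits with unit axis ratio and any orientation", {
  pts <- ellipse_points(90, cx = 10, cy = 10, a = 30, b = 30)
  f <- fit_ellipse(pts)
  expect_equal(f$axis_ratio, 1, tolerance = 1e-9)
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_ellipse(ellipse_points(5, 0, 0, 10, 5)), "at least 6")
  line <- cbind(x = 1:20, y = 2 * (1:20) + 3)
  expect_error(fit_ellipse(line), "collinear|ellipse|degenerate")
  expect_error(fit_ellipse(matrix(1, 10, 2)), "degenerate|coincide")
})

test_that("small exact instances agree with a brute-force grid search", {
  for (seed in 1:3) {
    set.seed(seed)
    cx <- runif(1, 40, 60); cy <- runif(1, 20, 30)
    a <- runif(1, 15, 25); b <- runif(1, 6, 10)
    pts <- ellipse_points(8, cx, cy, a, b)
    f <- fit_ellipse(pts)
    g <- grid_fit_oracle(pts)
    expect_lt(abs(f$cx - g$cx), g$res$cx)
    expect_lt(abs(f$cy - g$cy), g$res$cy)
    expect_lt(abs(f$a_px - g$a), g$res$a)
    expect_lt(abs(f$b_px - g$b), g$res$b)
  }
})

test_that("axis ratio is robust to 0.5 px boundary jitter", {
  # quick version of the 500-trial acceptance property
  set.seed(7)
  hits <- 0L; n_trials <- 100L
  for (i in seq_len(n_trials)) {
    pts <- ellipse_points(200, 60, 30, a = 3.35 * 12, b = 12)
    pts <- pts + matrix(rnorm(400, 0, 0.5), ncol = 2)
    f <- fit_ellipse(pts)
    if (abs(f$axis_ratio - 3.35) / 3.35 <= 0.02) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("fits are translation-equivariant and X-flip invariant", {
  set.seed(11)
  pts <- ellipse_points(80, 50, 25, 28, 9) + matrix(rnorm(160, 0, 0.2), ncol = 2)
  f0 <- fit_ellipse(pts)
  shift <- cbind(pts[, 1] + 13.5, pts[, 2] - 4.25)
  f1 <- fit_ellipse(shift)
  expect_equal(f1$cx - f0$cx, 13.5, tolerance = 1e-9)
  expect_equal(f1$cy - f0$cy, -4.25, tolerance = 1e-9)
  expect_equal(f1$axis_ratio, f0$axis_ratio, tolerance = 1e-9)

  # reflection changes the optimizer's path, so equality here is only up to
  # refinement convergence noise
  flipped <- cbind(-pts[, 1], pts[, 2])
  f2 <- fit_ellipse(flipped)
  expect_equal(f2$axis_ratio, f0$axis_ratio, tolerance = 1e-4)
  expect_equal(f2$a_px, f0$a_px, tolerance = 1e-4)
})

test_that("doubling the sampling density doubles axes but not the ratio", {
  sp1 <- single_bead_phantom(true_k = 2.5, y_um_per_px = 154 / 24)
  sp2 <- single_bead_phantom(true_k = 2.5, y_um_per_px = 154 / 48)
  f1 <- fit_ellipse(segment_beads(render_phantom(sp1)$image, c(16, 160))[[1]])
  f2 <- fit_ellipse(segment_beads(render_phantom(sp2)$image, c(16, 320))[[1]])
  expect_equal(f2$a_px / f1$a_px, 2, tolerance = 0.02)
  expect_equal(f2$b_px / f1$b_px, 2, tolerance = 0.02)
  expect_equal(f2$axis_ratio, f1$axis_ratio, tolerance = 0.005)
})
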