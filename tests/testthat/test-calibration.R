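obs_from_ratio <- function(ratio, b_px = 12) {
  pts <- ellipse_points(60, 50, 30, a = ratio * b_px, b = b_px)
  structure(list(ellipse = fit_ellipse(pts), truncated = FALSE,
                 n_boundary_points = 60L, qc_pass = TRUE, qc_reason = "ok"),
            class = "bead_observation")
}

test_that("calibration aggregates ratios with mean and sample SD", {
  obs <- lapply(c(3.2, 3.35, 3.5), obs_from_ratio)
  cal <- calibrate(obs, bead_diameter_um = 154)
  expect_equal(cal$k_mean, 3.35, tolerance = 1e-6)
  expect_equal(cal$k_sd, 0.15, tolerance = 1e-6)
  expect_identical(cal$n, 3L)
  expect_equal(cal$y_um_per_px, 154 / 24, tolerance = 1e-6)
  expect_equal(cal$x_um_per_px, cal$y_um_per_px / cal$k_mean, tolerance = 1e-9)
})

test_that("a single bead calibrates with undefined SD", {
  cal <- calibrate(list(obs_from_ratio(3.35)))
  expect_equal(cal$k_mean, 3.35, tolerance = 1e-6)
  expect_true(is.na(cal$k_sd))
  expect_identical(cal$n, 1L)
})

test_that("calibration is permutation-invariant and ignores QC failures", {
  obs <- lapply(c(3.1, 3.3, 3.6, 3.4), obs_from_ratio)
  fail <- obs_from_ratio(9.9); fail$qc_pass <- FALSE; fail$qc_reason <- "residual"
  c1 <- calibrate(c(obs, list(fail)))
  c2 <- calibrate(c(list(fail), rev(obs)))
  expect_equal(c1$k_mean, c2$k_mean, tolerance = 1e-12)
  expect_equal(c1$k_sd, c2$k_sd, tolerance = 1e-12)
  expect_identical(c1$n, 4L)

  all_fail <- list(fail)
  expect_error(calibrate(all_fail), "no QC-passing.*residual")
})

test_that("median policy resists a wild outlier", {
  obs <- lapply(c(3.3, 3.32, 3.35, 3.37, 6.5), obs_from_ratio)
  expect_equal(calibrate(obs, policy = "median")$k_mean, 3.35, tolerance = 1e-6)
})

test_that("absolute axial scale is exact on noise-free geometry", {
  ph <- render_phantom(single_bead_phantom())
  # use the annotated truth directly: b = 12 px, D = 154 um
  cal <- scale_calibration(ratios = ph$truth$a_px / ph$truth$b_px,
                           b_px = ph$truth$b_px, bead_diameter_um = 154)
  expect_equal(cal$y_um_per_px, 154 / 24, tolerance = 1e-9)
})

test_that("phantom calibration recovers the true factor within 3%", {
  cal <- calibrate_study(sample_study(20, true_k = 3.35, seed = 101))
  expect_lt(abs(cal$k_mean - 3.35) / 3.35, 0.03)
})

test_that("group comparison matches the hand-computed pooled t-test", {
  a <- c(3.28, 3.41, 3.30, 3.52, 3.33)
  b <- c(3.25, 3.38, 3.44, 3.29)
  cmp <- compare_groups(scale_calibration(a), scale_calibration(b),
                        labels = c("subretinal", "epiretinal"))
  # independent oracle: pooled-variance Student's t from first principles
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_manual <- 2 * pt(-abs(t_manual), length(a) + length(b) - 2)
  expect_equal(cmp$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_manual, tolerance = 1e-12)
  expect_false(cmp$degenerate)
})

test_that("identical groups compare as no difference", {
  g <- scale_calibration(c(3.3, 3.4))
  cmp <- compare_groups(g, g)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("zero-variance groups are handled explicitly", {
  same <- compare_groups(scale_calibration(rep(2, 4)), scale_calibration(rep(2, 4)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  diff <- compare_groups(scale_calibration(rep(1, 4)), scale_calibration(rep(2, 4)))
  expect_true(diff$degenerate)
  expect_equal(diff$p_value, 0)

  expect_error(compare_groups(scale_calibration(3.3), scale_calibration(c(3, 3.1))),
               "n >= 2")
})

test_that("same-truth phantom groups rarely differ significantly", {
  p_vals <- vapply(1:20, function(i) {
    cal_a <- calibrate_study(sample_study(10, seed = 1000 + 2 * i))
    cal_b <- calibrate_study(sample_study(10, seed = 1001 + 2 * i))
    compare_groups(cal_a, cal_b)$p_value
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("pooling is gated on the group comparison", {
  set.seed(3)
  a <- scale_calibration(rnorm(10, 3.35, 0.05))
  b <- scale_calibration(rnorm(10, 3.35, 0.05))
  pooled <- pool_calibrations(a, b)
  expect_s3_class(pooled, "scale_calibration")
  expect_identical(pooled$n, 20L)

  c_far <- scale_calibration(rnorm(10, 4.2, 0.05))
  expect_message(expect_null(pool_calibrations(a, c_far)), "not pooling")
})

test_that("calibration JSON round-trips losslessly and validates on load", {
  cal <- calibrate(lapply(c(3.21, 3.37, 3.44), obs_from_ratio))
  path <- withr::local_tempfile(fileext = ".json")
  save_calibration(cal, path)
  back <- load_calibration(path)
  expect_equal(back$k_mean, cal$k_mean, tolerance = 1e-12)
  expect_equal(back$ratios, cal$ratios, tolerance = 1e-12)
  expect_equal(back$y_um_per_px, cal$y_um_per_px, tolerance = 1e-12)
  expect_identical(back$policy, cal$policy)

  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$k_mean <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_calibration(path), "k_mean missing")

  doc2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc2$schema_version <- NULL
  jsonlite::write_json(doc2, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_calibration(path), "schema_version")
})
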