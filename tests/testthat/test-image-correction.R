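round_half_away_ref <- function(x) as.integer(floor(x + 0.5))

test_that("rescaling at k = 1 is the identity and row counts follow round(h*k)", {
  m <- matrix(runif(100 * 64), 100, 64)
  img <- bscan_image(m)
  expect_identical(rescale_image(img, 1, "nearest")$pixels, m)
  expect_lt(max(abs(rescale_image(img, 1, "linear")$pixels - m)), 1e-12)
  expect_identical(nrow(rescale_image(img, 3.35)$pixels), 335L)
  expect_identical(ncol(rescale_image(img, 3.35)$pixels), 64L)
  expect_identical(nrow(rescale_image(bscan_image(matrix(0.5, 33, 40)), 2.5)$pixels),
                   round_half_away_ref(33 * 2.5))
})

test_that("invalid factors and oversized outputs are refused", {
  img <- bscan_image(matrix(0.5, 64, 64))
  expect_error(rescale_image(img, 0), "positive")
  expect_error(rescale_image(img, -3), "positive")
  expect_error(rescale_image(img, 3, max_pixels = 1000), "downscale")
})

test_that("rescaling by the bead's own calibration makes it circular", {
  ph <- render_phantom(single_bead_phantom(seed = 21))
  obs <- detect_beads(ph$image, c(16, 120))
  cal <- calibrate(obs)
  corrected <- rescale_image(ph$image, cal, "linear")
  refit <- fit_ellipse(segment_beads(corrected$pixels |> pmin(1) |> pmax(0) |>
                                       bscan_image(), c(20, 120))[[1]])
  expect_lt(abs(refit$axis_ratio - 1), 0.01)
})

test_that("linear rescaling preserves mean intensity away from borders", {
  ph <- render_phantom(single_bead_phantom(speckle_sigma = 0.4, seed = 5))
  out <- rescale_image(ph$image, 3.35, "linear")
  inner_in <- ph$image$pixels[3:(nrow(ph$image$pixels) - 2), ]
  inner_out <- out$pixels[8:(nrow(out$pixels) - 7), ]
  expect_lt(abs(mean(inner_out) - mean(inner_in)) / mean(inner_in), 0.01)
})

test_that("provenance records the exact factor and method", {
  img <- bscan_image(matrix(0.5, 64, 64), y_um_per_px = 154 / 24)
  out <- rescale_image(img, scale_calibration(c(3.3, 3.4)), "nearest")
  expect_equal(out$provenance$k, 3.35)
  expect_identical(out$provenance$interpolation, "nearest")
  expect_identical(out$provenance$input_rows, 64L)
  expect_equal(out$y_um_per_px, (154 / 24) / 3.35, tolerance = 1e-12)
  expect_equal(out$x_um_per_px, out$y_um_per_px)
})

test_that("segments measure correctly on corrected and raw images", {
  img <- bscan_image(matrix(0.5, 64, 64), y_um_per_px = 154 / 24)
  # vertical bead-diameter segment on the raw scan: 24 px spans 154 um
  m <- measure_segment(img, c(10, 5), c(10, 29))
  expect_equal(m$length_um, 154, tolerance = 1e-9)
  expect_equal(m$angle_deg, 90)

  corr <- rescale_image(bscan_image(matrix(0.4, 64, 64), y_um_per_px = 1), 1)
  h <- measure_segment(corr, c(5, 10), c(15, 10))
  expect_equal(h$length_um, 10, tolerance = 1e-12)
  expect_equal(h$angle_deg, 0)
})

test_that("oblique raw measurements need a calibration", {
  img <- bscan_image(matrix(0.5, 64, 64))
  expect_error(measure_segment(img, c(5, 5), c(20, 30)), "calibration|rescale")
  expect_error(measure_segment(img, c(5, 5), c(500, 5)), "inside")
})

test_that("raw-plus-calibration equals measuring on the rescaled image", {
  k <- 3.35; y_um <- 154 / 24
  img <- bscan_image(matrix(runif(120 * 150), 120, 150), y_um_per_px = y_um)
  cal <- scale_calibration(rep(k, 3), b_px = rep(12, 3))
  corr <- rescale_image(img, cal, "linear")
  set.seed(99)
  for (i in 1:25) {
    p1 <- c(runif(1, 1, 150), runif(1, 1, 110))
    p2 <- c(runif(1, 1, 150), runif(1, 1, 110))
    raw <- measure_segment(img, p1, p2, cal = cal)
    # same physical endpoints on the corrected grid: y' = 1 + (y - 1) * k
    q1 <- c(p1[1], 1 + (p1[2] - 1) * k)
    q2 <- c(p2[1], 1 + (p2[2] - 1) * k)
    cor <- measure_segment(corr, q1, q2)
    expect_equal(raw$length_um, cor$length_um, tolerance = 0.005)
    if (raw$displayed_length_px > 1) {
      expect_equal(raw$angle_deg, cor$angle_deg, tolerance = 1e-6)
    }
  }
})

test_that("vessel angles are restored from the displayed angle", {
  expect_equal(adjust_vessel_angle(atan(1 / 3.35) * 180 / pi, 3.35), 45,
               tolerance = 1e-9)
  expect_equal(adjust_vessel_angle(90, scale_calibration(rep(2.2, 2))), 90)
  expect_equal(adjust_vessel_angle(0, 5), 0)
})
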