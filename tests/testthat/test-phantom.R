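test_that("annotations carry the forced rendering arithmetic", {
  sp <- single_bead_phantom(true_k = 3.35, diameter_um = 154,
                            y_um_per_px = 154 / 24)
  ph <- render_phantom(sp)
  expect_equal(ph$truth$b_px, 12, tolerance = 1e-12)
  expect_equal(ph$truth$a_px, 40.2, tolerance = 1e-12)

  iso <- render_phantom(single_bead_phantom(true_k = 1))
  expect_equal(iso$truth$a_px, iso$truth$b_px, tolerance = 1e-12)
})

test_that("rendering is bit-identical per seed and seed-free when clean", {
  sp <- single_bead_phantom(speckle_sigma = 0.5, seed = 42)
  expect_identical(render_phantom(sp)$image$pixels,
                   render_phantom(sp)$image$pixels)

  c1 <- single_bead_phantom(speckle_sigma = 0, seed = 1)
  c2 <- single_bead_phantom(speckle_sigma = 0, seed = 999)
  expect_identical(render_phantom(c1)$image$pixels,
                   render_phantom(c2)$image$pixels)

  s2 <- single_bead_phantom(speckle_sigma = 0.5, seed = 43)
  expect_false(identical(render_phantom(sp)$image$pixels,
                         render_phantom(s2)$image$pixels))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(render_phantom(single_bead_phantom(speckle_sigma = 0.5)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("invalid scenes are refused and overlaps are warned about", {
  expect_error(
    phantom_spec(64, 64, 2, data.frame(center_x_um = 1e5, center_y_um = 10,
                                       diameter_um = 154)),
    "outside")
  expect_error(
    phantom_spec(64, 64, 2, data.frame(center_x_um = 10, center_y_um = 10,
                                       diameter_um = -5)),
    "positive")
  y_um <- 154 / 24
  sp <- phantom_spec(200, 64, 2, data.frame(
    center_x_um = c(100 * y_um / 2, 120 * y_um / 2),
    center_y_um = c(30 * y_um, 30 * y_um),
    diameter_um = c(154, 154)), y_um_per_px = y_um)
  expect_warning(ph <- render_phantom(sp), "overlap")
  expect_true(all(ph$truth$overlaps))
})

test_that("study sampling is reproducible and honors the diameter model", {
  s1 <- sample_study(6, seed = 7)
  s2 <- sample_study(6, seed = 7)
  expect_identical(lapply(s1, function(r) r$image$pixels),
                   lapply(s2, function(r) r$image$pixels))

  d1 <- vapply(s1, function(r) r$truth$diameter_um, numeric(1))
  expect_true(all(abs(d1 - 154) <= 3 * (5 / 3) + 1e-9))  # truncated at 3 SD
  expect_gt(stats::sd(d1), 0)

  s0 <- sample_study(5, diameter_um_sd = 0, seed = 11)
  b0 <- vapply(s0, function(r) r$truth$b_px, numeric(1))
  expect_equal(b0, rep(12, 5), tolerance = 1e-12)
})

test_that("end-to-end study recovery reaches the truth within 3%", {
  cal <- calibrate_study(sample_study(20, true_k = 2.5, seed = 77))
  expect_lt(abs(cal$k_mean - 2.5) / 2.5, 0.03)
})

test_that("both bead styles calibrate to the same anisotropy", {
  ring <- calibrate_study(sample_study(10, style = "ring", seed = 5))
  disc <- calibrate_study(sample_study(10, style = "disc", seed = 5))
  expect_lt(abs(ring$k_mean - disc$k_mean) / 3.35, 0.02)
})

test_that("a retina-like band does not break bead detection", {
  y_um <- 154 / 24
  sp <- phantom_spec(160, 80, 3.35,
                     data.frame(center_x_um = 80 * y_um / 3.35,
                                center_y_um = 40 * y_um, diameter_um = 154),
                     y_um_per_px = y_um, band = c(5 * y_um, 14 * y_um, 0.35),
                     speckle_sigma = 0.4, seed = 8)
  ph <- render_phantom(sp)
  obs <- detect_beads(ph$image, c(16, 120))
  expect_length(obs, 1)
  expect_true(obs[[1]]$qc_pass)
  expect_equal(obs[[1]]$ellipse$axis_ratio, 3.35, tolerance = 0.03)
})
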