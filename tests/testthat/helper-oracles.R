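# Independent oracles and small fixture builders used across the suite.

# Brute-force chord oracle: sample the ellipse x^2/a^2 + y^2/b^2 = 1
# (a = k, b = 1) densely in the parametric angle, then read off the polar
# radius at the requested polar angle by interpolation. Independent of the
# closed form in the package.
chord_oracle <- function(alpha_deg, k, n = 1e6) {
  t <- seq(0, pi, length.out = n)        # upper half covers all diameters
  x <- k * cos(t)
  y <- sin(t)
  phi <- atan2(y, x) * 180 / pi          # in [0, 180]
  r <- sqrt(x^2 + y^2)
  a <- alpha_deg %% 180
  stats::approx(phi, r, xout = a, rule = 2)$y
}

# Brute-force ellipse fit: dense grid search over axis-aligned ellipse
# parameters minimizing the summed squared normalized algebraic residual.
grid_fit_oracle <- function(pts, n_grid = 21) {
  x <- pts[, 1]; y <- pts[, 2]
  cx0 <- mean(range(x)); cy0 <- mean(range(y))
  a0 <- diff(range(x)) / 2; b0 <- diff(range(y)) / 2
  span <- function(v, f) seq(v * (1 - f), v * (1 + f), length.out = n_grid)
  grid <- expand.grid(cx = cx0 + seq(-1, 1, length.out = n_grid),
                      cy = cy0 + seq(-1, 1, length.out = n_grid),
                      a = span(a0, 0.1), b = span(b0, 0.1))
  sse <- mapply(function(cx, cy, a, b) {
    sum((((x - cx) / a)^2 + ((y - cy) / b)^2 - 1)^2)
  }, grid$cx, grid$cy, grid$a, grid$b)
  best <- grid[which.min(sse), ]
  list(cx = best$cx, cy = best$cy, a = best$a, b = best$b,
       res = list(cx = 2 / (n_grid - 1), cy = 2 / (n_grid - 1),
                  a = 0.2 * a0 / (n_grid - 1), b = 0.2 * b0 / (n_grid - 1)))
}

# exact points on an (optionally rotated) ellipse
ellipse_points <- function(n, cx, cy, a, b, theta_deg = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- theta_deg * pi / 180
  u <- a * cos(t); v <- b * sin(t)
  cbind(x = cx + u * cos(th) - v * sin(th),
        y = cy + u * sin(th) + v * cos(th))
}

# single centered bead phantom, sized to fit the bead with margin
single_bead_phantom <- function(true_k = 3.35, diameter_um = 154,
                                y_um_per_px = 154 / 24, speckle_sigma = 0,
                                style = "ring", seed = 1L) {
  b_px <- diameter_um / (2 * y_um_per_px)
  a_px <- true_k * b_px
  W <- max(32L, as.integer(ceiling(2 * a_px)) + 24L)
  H <- max(32L, as.integer(ceiling(2 * b_px)) + 20L)
  x_um_per_px <- y_um_per_px / true_k
  phantom_spec(
    W, H, true_k,
    data.frame(center_x_um = (W - 1) / 2 * x_um_per_px,
               center_y_um = (H - 1) / 2 * y_um_per_px,
               diameter_um = diameter_um, style = style, contrast = 0.75),
    y_um_per_px = y_um_per_px, speckle_sigma = speckle_sigma, seed = seed
  )
}

# detect + fit + calibrate a list of renders (as from sample_study())
calibrate_study <- function(study, diameter_px_range = c(16, 160), ...) {
  obs <- lapply(study, function(r) {
    o <- detect_beads(r$image, diameter_px_range, ...)
    if (length(o)) o[[1]] else NULL
  })
  calibrate(Filter(Negate(is.null), obs))
}
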