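#' Describe a synthetic B-scan phantom
#'
#' A phantom is a fully specified synthetic scene with exact ground truth:
#' spherical beads of known physical diameter placed in micrometer
#' coordinates, rendered onto a pixel grid whose X (lateral) spacing is
#' `true_k` times finer in micrometers than the Y (axial) spacing — so true
#' circles render as axis-aligned ellipses with `a/b = true_k`, exactly the
#' distortion an anisotropic OCT display produces. Optional ingredients
#' emulate the look of a retinal B-scan: a bright horizontal band (retinal
#' layers) and multiplicative log-normal speckle.
#'
#' @param width_px,height_px image size in pixels.
#' @param true_k true X/Y anisotropy used to render (> 0).
#' @param beads data frame with columns `center_x_um`, `center_y_um`,
#'   `diameter_um`, and optionally `style` (`"ring"` or `"disc"`, default
#'   ring) and `contrast` (peak intensity above background, default 0.75).
#' @param y_um_per_px axial scale, micrometers per row (default `154/24`, so
#'   a nominal 154 um bead spans 24 rows).
#' @param band optional `c(top_um, bottom_um, intensity)` bright horizontal
#'   band.
#' @param speckle_sigma log-scale sigma of the multiplicative speckle
#'   (default 0 = clean).
#' @param background_level base intensity (default 0.08).
#' @param seed integer; together with the spec it fully determines the
#'   rendered image.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_px, height_px, true_k, beads,
                         y_um_per_px = 154 / 24, band = NULL,
                         speckle_sigma = 0, background_level = 0.08,
                         seed = 1L) {
  check_axis_ratio(true_k)
  beads <- as.data.frame(beads)
  need <- c("center_x_um", "center_y_um", "diameter_um")
  if (!all(need %in% names(beads)) || nrow(beads) < 1L) {
    stop("`beads` needs columns center_x_um, center_y_um, diameter_um", call. = FALSE)
  }
  if (any(beads$diameter_um <= 0)) stop("bead diameters must be positive", call. = FALSE)
  if (is.null(beads$style)) beads$style <- "ring"
  if (is.null(beads$contrast)) beads$contrast <- 0.75
  if (!all(beads$style %in% c("ring", "disc"))) {
    stop("bead style must be 'ring' or 'disc'", call. = FALSE)
  }
  if (speckle_sigma < 0 || background_level < 0 || background_level > 1) {
    stop("invalid noise/background parameters", call. = FALSE)
  }
  x_um_per_px <- y_um_per_px / true_k
  w_um <- (width_px - 1) * x_um_per_px
  h_um <- (height_px - 1) * y_um_per_px
  r <- beads$diameter_um / 2
  outside <- beads$center_x_um + r < 0 | beads$center_x_um - r > w_um |
    beads$center_y_um + r < 0 | beads$center_y_um - r > h_um
  if (any(outside)) {
    stop("bead(s) ", paste(which(outside), collapse = ", "),
         " lie fully outside the image", call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         true_k = true_k, beads = beads, y_um_per_px = y_um_per_px,
         x_um_per_px = x_um_per_px, band = band,
         speckle_sigma = speckle_sigma, background_level = background_level,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Render a phantom to an image with ground-truth annotations
#'
#' Beads are rendered in physical (micrometer) space — a `ring` as a bright
#' capsule wall with a dimmer interior, a `disc` as a uniformly bright blob —
#' with 4x supersampling and box downsampling for subpixel-accurate edges.
#' Speckle is multiplicative: `I * exp(N(0, sigma^2))`, clipped to `[0, 1]`;
#' `sigma = 0` reproduces the clean render bit for bit. All randomness comes
#' from `spec$seed` through R's Mersenne-Twister generator with inversion
#' normals (set explicitly, so renders are reproducible across platforms and
#' regardless of the session's RNG settings); the caller's RNG state is left
#' untouched.
#'
#' @param spec a [phantom_spec()].
#' @param supersample supersampling factor per axis (default 4).
#' @return a list with `image` (a [bscan_image()] carrying the spec's
#'   scales) and `truth`, a data frame of exact displayed ellipse parameters
#'   per bead (`cx_px`, `cy_px`, `a_px`, `b_px`, `style`, `truncated`,
#'   `overlaps`).
#' @export
render_phantom <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- as.integer(supersample)
  W <- spec$width_px; H <- spec$height_px

  # sub-pixel sample coordinates: pixel i covers [i - 0.5, i + 0.5]
  sub <- function(n) rep(seq_len(n), each = S) - 0.5 + (seq_len(S) - 0.5) / S
  x_um <- (sub(W) - 1) * spec$x_um_per_px
  y_um <- (sub(H) - 1) * spec$y_um_per_px

  canvas <- matrix(spec$background_level, length(y_um), length(x_um))
  if (!is.null(spec$band)) {
    rows <- y_um >= spec$band[1] & y_um <= spec$band[2]
    canvas[rows, ] <- canvas[rows, ] + spec$band[3]
  }

  b <- spec$beads
  for (i in seq_len(nrow(b))) {
    R <- b$diameter_um[i] / 2
    rho2 <- outer((y_um - b$center_y_um[i])^2, (x_um - b$center_x_um[i])^2, `+`)
    if (b$style[i] == "disc") {
      canvas <- canvas + b$contrast[i] * (rho2 <= R^2)
    } else {
      wall <- min(20, 0.4 * R)  # capsule wall thickness, um
      ring <- rho2 <= R^2 & rho2 >= (R - wall)^2
      lumen <- rho2 < (R - wall)^2
      canvas <- canvas + b$contrast[i] * ring + 0.3 * b$contrast[i] * lumen
    }
  }

  clean <- pmin(pmax(block_mean(canvas, S), 0), 1)
  img_px <- clean
  if (spec$speckle_sigma > 0) {
    img_px <- with_phantom_rng(spec$seed, {
      noise <- exp(matrix(stats::rnorm(H * W, 0, spec$speckle_sigma), H, W))
      pmin(pmax(clean * noise, 0), 1)
    })
  }

  r_vec <- b$diameter_um / 2
  cx_px <- b$center_x_um / spec$x_um_per_px + 1
  cy_px <- b$center_y_um / spec$y_um_per_px + 1
  a_px <- r_vec / spec$x_um_per_px
  b_px <- r_vec / spec$y_um_per_px
  truncated <- cx_px - a_px < 1 | cx_px + a_px > W | cy_px - b_px < 1 | cy_px + b_px > H
  overlaps <- vapply(seq_len(nrow(b)), function(i) {
    if (nrow(b) == 1L) return(FALSE)
    d <- sqrt((b$center_x_um[i] - b$center_x_um[-i])^2 +
                (b$center_y_um[i] - b$center_y_um[-i])^2)
    any(d < r_vec[i] + r_vec[-i])
  }, logical(1))
  if (any(overlaps)) warning("phantom contains overlapping beads", call. = FALSE)

  list(
    image = bscan_image(img_px, y_um_per_px = spec$y_um_per_px,
                        x_um_per_px = spec$x_um_per_px, source = "phantom"),
    truth = data.frame(cx_px = cx_px, cy_px = cy_px, a_px = a_px, b_px = b_px,
                       diameter_um = b$diameter_um, style = b$style,
                       truncated = truncated, overlaps = overlaps)
  )
}

# mean over S x S blocks
block_mean <- function(m, S) {
  H <- nrow(m) / S; W <- ncol(m) / S
  m <- matrix(colMeans(matrix(m, nrow = S)), nrow = H)         # rows
  t(matrix(colMeans(matrix(t(m), nrow = S)), nrow = W))        # cols
}

# run expr under a fixed, fully specified RNG; restore the caller's state
with_phantom_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# default speckle level: the strongest multiplicative speckle at which
# segmentation and QC remain reliable; pixel-level speckle alone cannot
# reproduce the per-bead scatter of in-vivo data, which is dominated by
# bead-level effects (see the methods vignette)
DEFAULT_SPECKLE_SIGMA <- 0.6

#' Generate a seeded study of single-bead scans
#'
#' Draws `n_beads` bead diameters from a normal distribution truncated at
#' +/- 3 SD (matching a manufacturing tolerance quoted as a +/- spread),
#' places each bead at a randomized subpixel position near the center of its
#' own scan, and renders each with a per-item seed derived reproducibly from
#' `seed`. This is the package's stand-in for an in-vivo bead dataset.
#'
#' @param n_beads number of single-bead scans (>= 1).
#' @param true_k true anisotropy of the simulated device (default 3.35).
#' @param diameter_um_mean,diameter_um_sd bead diameter distribution in
#'   micrometers (defaults 154 and 5/3, i.e. a 154 +/- 5 um tolerance read
#'   as a 3-SD band).
#' @param speckle_sigma multiplicative speckle level (default `0.6`, the
#'   strongest level the segmentation stage handles reliably; see the
#'   methods vignette for why phantom scatter stays below in-vivo scatter).
#' @param style bead rendering style, `"ring"` (default) or `"disc"`.
#' @param y_um_per_px axial scale (default `154/24`).
#' @param seed master seed; per-item seeds are drawn from it.
#' @return a list of `n_beads` renders, each as returned by
#'   [render_phantom()].
#' @export
sample_study <- function(n_beads, true_k = 3.35, diameter_um_mean = 154,
                         diameter_um_sd = 5 / 3,
                         speckle_sigma = DEFAULT_SPECKLE_SIGMA,
                         style = c("ring", "disc"),
                         y_um_per_px = 154 / 24, seed = 1L) {
  style <- match.arg(style)
  if (n_beads < 1L) stop("`n_beads` must be >= 1", call. = FALSE)
  if (diameter_um_mean <= 0 || diameter_um_sd < 0) {
    stop("invalid diameter distribution", call. = FALSE)
  }
  draws <- with_phantom_rng(seed, {
    item_seeds <- sample.int(.Machine$integer.max, n_beads)
    d <- stats::rnorm(n_beads, diameter_um_mean, diameter_um_sd)
    if (diameter_um_sd > 0) {
      lim <- 3 * diameter_um_sd
      while (any(bad <- abs(d - diameter_um_mean) > lim)) {
        d[bad] <- stats::rnorm(sum(bad), diameter_um_mean, diameter_um_sd)
      }
    }
    jx <- stats::runif(n_beads, -0.5, 0.5)
    jy <- stats::runif(n_beads, -0.5, 0.5)
    list(item_seeds = item_seeds, d = d, jx = jx, jy = jy)
  })

  lapply(seq_len(n_beads), function(i) {
    D <- draws$d[i]
    b_px <- D / (2 * y_um_per_px)
    a_px <- true_k * b_px
    W <- max(32L, as.integer(ceiling(2 * a_px)) + 24L)
    H <- max(32L, as.integer(ceiling(2 * b_px)) + 20L)
    x_um_per_px <- y_um_per_px / true_k
    cx_um <- ((W - 1) / 2 + draws$jx[i]) * x_um_per_px
    cy_um <- ((H - 1) / 2 + draws$jy[i]) * y_um_per_px
    spec <- phantom_spec(
      W, H, true_k,
      data.frame(center_x_um = cx_um, center_y_um = cy_um, diameter_um = D,
                 style = style, contrast = 0.75),
      y_um_per_px = y_um_per_px, speckle_sigma = speckle_sigma,
      seed = draws$item_seeds[i]
    )
    render_phantom(spec)
  })
}
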