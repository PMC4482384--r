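#' Resample the Y axis so X and Y scales agree
#'
#' Stretches the axial (Y) axis of a B-scan by the correction factor, the
#' direction the underlying physics recommends: the lateral (X) sampling is
#' left untouched and the trusted A-scan axis is interpolated. The output
#' has `round(rows * k)` rows (half-away-from-zero rounding) and unchanged
#' columns; the exact, unrounded `k` is stored in the provenance and used by
#' [measure_segment()], so measurement math never sees the rounding.
#'
#' Output row `j` samples the input at row `1 + (j - 1)/k`, i.e. physical
#' depth positions are preserved with pixel centers at integer coordinates.
#' Linear interpolation is the default; nearest keeps the original
#' intensities exactly and cubic (natural splines per column) is sharper but
#' can overshoot at bright edges such as the bead ring.
#'
#' @param image a [bscan_image()] or intensity matrix.
#' @param cal a `scale_calibration`, or a single positive number used
#'   directly as the factor `k`.
#' @param interpolation `"linear"` (default), `"nearest"`, or `"cubic"`.
#' @param max_pixels guard on the output size (default 5e7); exceeding it is
#'   an error suggesting the input be downscaled first.
#' @return an object of classes `corrected_image` and `bscan_image`. After
#'   correction both scales equal `y_um_per_px / k` (when the axial scale is
#'   known); `provenance` records the source, exact factor, calibration
#'   summary and interpolation method.
#' @export
rescale_image <- function(image, cal, interpolation = c("linear", "nearest", "cubic"),
                          max_pixels = 5e7) {
  interpolation <- match.arg(interpolation)
  img <- as_bscan_image(image)
  k <- extract_factor(cal)
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  h_out <- round_half_away(h * k)
  if (as.double(h_out) * w > max_pixels) {
    stop(sprintf(paste0("rescaled image would have %d x %d pixels ",
                        "(> max_pixels = %g); downscale the input first"),
                 h_out, w, max_pixels), call. = FALSE)
  }
  y_in <- 1 + (seq_len(h_out) - 1) / k
  y_in <- pmin(pmax(y_in, 1), h)
  out <- switch(
    interpolation,
    nearest = px[pmin(pmax(round_half_away(y_in), 1L), h), , drop = FALSE],
    linear = {
      lo <- pmin(floor(y_in), h - 1L)
      fr <- y_in - lo
      px[lo, , drop = FALSE] * (1 - fr) + px[lo + 1L, , drop = FALSE] * fr
    },
    cubic = apply(px, 2, function(col) {
      stats::splinefun(seq_len(h), col, method = "natural")(y_in)
    })
  )
  um <- if (!is.null(img$y_um_per_px)) img$y_um_per_px / k else NULL
  res <- bscan_image_nocheck(out, y_um_per_px = um, x_um_per_px = um,
                             source = img$source)
  res$provenance <- list(
    source = img$source %||% "in-memory",
    k = k,
    calibration = if (inherits(cal, "scale_calibration")) {
      list(k_mean = cal$k_mean, k_sd = cal$k_sd, n = cal$n)
    } else list(k_mean = k, k_sd = NA_real_, n = NA_integer_),
    interpolation = interpolation,
    input_rows = h, output_rows = h_out
  )
  class(res) <- c("corrected_image", class(res))
  res
}

# corrected images may legitimately overshoot [0,1] (cubic) — skip the
# range check but keep the structure
bscan_image_nocheck <- function(pixels, y_um_per_px, x_um_per_px, source) {
  structure(
    list(pixels = pixels, y_um_per_px = y_um_per_px, x_um_per_px = x_um_per_px,
         source = source),
    class = "bscan_image"
  )
}

extract_factor <- function(cal) {
  k <- if (inherits(cal, "scale_calibration")) cal$k_mean else cal
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("correction factor must be a single positive number", call. = FALSE)
  }
  k
}

round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Measure a straight segment in physical units
#'
#' On a corrected image (equal scales) this is plain Euclidean geometry:
#' pixel distance times the micrometer-per-pixel scale. On an uncorrected
#' scan with a calibration, the displayed length is divided by the relative
#' diameter for its direction and converted through the axial scale, and the
#' displayed angle is mapped to its true value — the two routes agree. On an
#' uncorrected scan without a calibration only axis-aligned segments are
#' measurable; oblique ones are refused because the correction needs `k`.
#'
#' @param image a `bscan_image` or `corrected_image`.
#' @param p1,p2 segment endpoints, numeric `c(x, y)` in pixel coordinates of
#'   `image` (1-based, x = column).
#' @param cal optional `scale_calibration` (or single number `k`) for
#'   measurements on uncorrected scans.
#' @return a list with `length_um` (or `length_px_y_scale` when no absolute
#'   scale is known), `angle_deg` (true angle from the X axis, `[0, 180)`),
#'   `displayed_length_px`, `displayed_angle_deg` and `space` (`"corrected"`
#'   or `"raw"`).
#' @export
measure_segment <- function(image, p1, p2, cal = NULL) {
  img <- if (is.matrix(image)) as_bscan_image(image) else image
  if (!inherits(img, "bscan_image")) {
    stop("`image` must be a bscan_image or corrected_image", call. = FALSE)
  }
  px <- img$pixels
  for (p in list(p1, p2)) {
    if (length(p) != 2L || any(!is.finite(p)) ||
        p[1] < 1 || p[1] > ncol(px) || p[2] < 1 || p[2] > nrow(px)) {
      stop("segment endpoints must lie inside the image", call. = FALSE)
    }
  }
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len_px <- sqrt(dx^2 + dy^2)
  ang_disp <- if (len_px == 0) 0 else normalize_section_angle(atan2(dy, dx) / DEG)

  if (inherits(img, "corrected_image")) {
    um <- img$y_um_per_px
    return(list(
      length_um = if (is.null(um)) NULL else len_px * um,
      length_px_y_scale = NULL,
      angle_deg = ang_disp,
      displayed_length_px = len_px, displayed_angle_deg = ang_disp,
      space = "corrected"
    ))
  }

  axis_aligned <- isTRUE(all.equal(ang_disp %% 90, 0, tolerance = 1e-9)) ||
    ang_disp %% 90 > 90 - 1e-9
  if (is.null(cal)) {
    if (!axis_aligned) {
      stop(paste0("oblique segment on an uncorrected image: the displayed ",
                  "length depends on the unknown X/Y factor k; supply a ",
                  "calibration or rescale the image first"), call. = FALSE)
    }
    vertical <- abs(dy) >= abs(dx)
    um <- if (vertical) img$y_um_per_px else img$x_um_per_px
    return(list(
      length_um = if (is.null(um)) NULL else len_px * um,
      length_px_y_scale = NULL,
      angle_deg = ang_disp,
      displayed_length_px = len_px, displayed_angle_deg = ang_disp,
      space = "raw"
    ))
  }

  k <- extract_factor(cal)
  len_y_scale <- correct_length(len_px, ang_disp, k)
  um <- if (inherits(cal, "scale_calibration") && !is.null(cal$y_um_per_px)) {
    cal$y_um_per_px
  } else img$y_um_per_px
  list(
    length_um = if (is.null(um)) NULL else len_y_scale * um,
    length_px_y_scale = len_y_scale,
    angle_deg = true_angle(ang_disp, k),
    displayed_length_px = len_px, displayed_angle_deg = ang_disp,
    space = "raw"
  )
}

#' Correct the displayed off-axis angle of a vessel
#'
#' Thin wrapper over [true_angle()] using a calibration's mean factor:
#' restores, e.g., the angle of a retinal vessel running obliquely in the
#' X-Y plane, which an anisotropic display compresses towards the X axis.
#'
#' @param alpha_displayed_deg displayed angle(s) in degrees from the X axis.
#' @param cal a `scale_calibration` or a single positive factor `k`.
#' @return true angle(s) in degrees.
#' @export
#' @examples
#' adjust_vessel_angle(16.62, 3.35)  # ~45 degrees
adjust_vessel_angle <- function(alpha_displayed_deg, cal) {
  true_angle(alpha_displayed_deg, extract_factor(cal))
}
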