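#' Segment bead cross-sections in a B-scan
#'
#' Finds bright ring/disc candidates of plausible size and extracts a
#' subpixel boundary for each: the image is smoothed, thresholded (Otsu by
#' default), connected components are filtered by their bounding box against
#' the expected displayed diameter range, and for each surviving component
#' the outer boundary is localized to subpixel precision by casting radial
#' rays from the component centroid and finding, along each ray, the
#' outermost half-maximum crossing of the smoothed intensity profile.
#'
#' Ray casting makes the boundary insensitive to interior texture (e.g. the
#' dim lumen of an encapsulated-cell bead renders the component an annulus)
#' and to small centroid errors, since the crossing lies on the physical
#' edge wherever the ray originates.
#'
#' @param image a [bscan_image()] or numeric intensity matrix in `[0, 1]`.
#' @param expected_diameter_px_range length-2 numeric, the plausible range of
#'   displayed bead diameters in pixels (covering both the minor and the
#'   stretched major axis).
#' @param seeds optional matrix/data frame of approximate bead centers
#'   (`x`, `y` in pixels); when given, only the component nearest each seed
#'   (within half the maximum expected diameter) is kept.
#' @param smooth_sigma Gaussian smoothing sigma in pixels applied before
#'   thresholding and edge localization (default 1).
#' @param threshold optional fixed segmentation threshold in `[0, 1]`;
#'   default `NULL` uses Otsu's method on the smoothed image.
#' @param n_rays number of radial rays used for boundary extraction
#'   (default 120).
#' @return a list of boundary point sets, each a two-column matrix
#'   (`x`, `y`, subpixel coordinates) with attributes `centroid` and `bbox`
#'   (`c(x0, x1, y0, y1)`). An empty list when nothing plausible is found.
#' @export
segment_beads <- function(image, expected_diameter_px_range, seeds = NULL,
                          smooth_sigma = 1, threshold = NULL, n_rays = 120L) {
  img <- as_bscan_image(image)
  px <- img$pixels
  rng <- as.numeric(expected_diameter_px_range)
  if (length(rng) != 2L || any(!is.finite(rng)) || any(rng <= 0) || rng[1] > rng[2]) {
    stop("`expected_diameter_px_range` must be a positive increasing interval", call. = FALSE)
  }
  if (rng[1] > min(dim(px))) {
    stop("expected bead diameter exceeds the image size", call. = FALSE)
  }

  if (diff(range(px)) < 1e-8) return(list())  # constant image: nothing to detect
  sm <- imageData(gblur(Image(px), sigma = smooth_sigma))

  thr <- if (is.null(threshold)) otsu(Image(sm), range = c(0, 1)) else threshold
  bw <- sm > thr
  if (!any(bw)) return(list())
  lab <- imageData(bwlabel(Image(bw)))

  comps <- component_table(lab)
  # interior texture (e.g. a speckle-lit lumen) labels as components nested
  # inside the bead annulus: keep only the outermost component of any nest
  if (nrow(comps) > 1L) {
    nested <- vapply(seq_len(nrow(comps)), function(i) {
      any(comps$area > comps$area[i] &
            comps$x0 <= comps$x0[i] + 1 & comps$x1 >= comps$x1[i] - 1 &
            comps$y0 <= comps$y0[i] + 1 & comps$y1 >= comps$y1[i] - 1)
    }, logical(1))
    comps <- comps[!nested, , drop = FALSE]
  }
  # bounding box of a bead component must fit the expected displayed size
  lo <- 0.5 * rng[1]; hi <- 1.3 * rng[2]
  keep <- comps$w >= lo & comps$w <= hi & comps$h >= lo & comps$h <= hi &
    comps$area >= max(9, pi * (rng[1] / 2)^2 / 8)
  comps <- comps[keep, , drop = FALSE]
  if (nrow(comps) == 0L) return(list())

  if (!is.null(seeds)) {
    sd_m <- as.matrix(seeds)
    pick <- unique(vapply(seq_len(nrow(sd_m)), function(i) {
      d <- sqrt((comps$cx - sd_m[i, 1])^2 + (comps$cy - sd_m[i, 2])^2)
      j <- which.min(d)
      if (d[j] <= rng[2] / 2) j else NA_integer_
    }, integer(1)))
    comps <- comps[pick[!is.na(pick)], , drop = FALSE]
    if (nrow(comps) == 0L) return(list())
  }

  bg <- stats::median(sm[lab == 0])
  out <- vector("list", nrow(comps))
  for (i in seq_len(nrow(comps))) {
    cc <- comps[i, ]
    peak <- stats::quantile(sm[lab == cc$id], 0.95, names = FALSE)
    edge_thr <- (bg + peak) / 2
    rmax <- 0.65 * max(cc$w, cc$h) + 4
    pts <- trace_boundary(sm, c(cc$cx, cc$cy), rmax, edge_thr, n_rays,
                          mask = lab == cc$id)
    attr(pts, "centroid") <- c(x = cc$cx, y = cc$cy)
    attr(pts, "bbox") <- c(x0 = cc$x0, x1 = cc$x1, y0 = cc$y0, y1 = cc$y1)
    out[[i]] <- pts
  }
  out[vapply(out, nrow, integer(1)) > 0L]
}

# summarize labelled components; lab is a matrix of integer labels
component_table <- function(lab) {
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  ag <- function(v, f) as.numeric(tapply(v, ids, f))
  uid <- sort(unique(ids))
  data.frame(
    id = uid,
    area = as.integer(tapply(ids, ids, length)),
    cx = ag(idx[, 2], mean), cy = ag(idx[, 1], mean),
    x0 = ag(idx[, 2], min), x1 = ag(idx[, 2], max),
    y0 = ag(idx[, 1], min), y1 = ag(idx[, 1], max)
  ) -> tb
  tb$w <- tb$x1 - tb$x0 + 1
  tb$h <- tb$y1 - tb$y0 + 1
  tb
}

# subpixel outer boundary via radial rays and half-maximum crossing; the
# crossing is searched near the outer rim of the component mask so that
# unrelated bright structure further out along the ray (a retinal band,
# another bead) cannot capture it
trace_boundary <- function(sm, center, rmax, edge_thr, n_rays, mask = NULL,
                           step = 0.25) {
  phis <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  radii <- seq(step, rmax, by = step)
  xx <- center[1] + outer(radii, cos(phis))   # [radius, ray]
  yy <- center[2] + outer(radii, sin(phis))
  vals <- matrix(bilinear_interp(sm, as.vector(xx), as.vector(yy)),
                 nrow = length(radii))
  in_mask <- if (is.null(mask)) {
    !is.na(vals)
  } else {
    h <- nrow(mask); w <- ncol(mask)
    xr <- pmin(pmax(round(as.vector(xx)), 1L), w)
    yr <- pmin(pmax(round(as.vector(yy)), 1L), h)
    matrix(mask[cbind(yr, xr)] & !is.na(as.vector(vals)), nrow = length(radii))
  }
  pts <- matrix(NA_real_, n_rays, 2L, dimnames = list(NULL, c("x", "y")))
  nr <- length(radii)
  win <- as.integer(ceiling(2.5 / step))  # search +/- 2.5 px around the rim
  for (j in seq_len(n_rays)) {
    v <- vals[, j]
    if (!any(in_mask[, j])) next
    i_rim <- max(which(in_mask[, j]))
    lo_i <- max(1L, i_rim - win); hi_i <- min(nr - 1L, i_rim + win)
    idx <- lo_i:hi_i
    ok <- !is.na(v[idx]) & !is.na(v[idx + 1L])
    cross <- idx[ok & v[idx] >= edge_thr & v[idx + 1L] < edge_thr]
    if (length(cross) == 0L) next
    i <- cross[which.min(abs(cross - i_rim))]  # crossing nearest the rim
    frac <- (v[i] - edge_thr) / (v[i] - v[i + 1])
    r <- radii[i] + frac * step
    pts[j, ] <- center + r * c(cos(phis[j]), sin(phis[j]))
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

# bilinear interpolation at (x, y) pixel coordinates (1-based, x = column);
# NA outside the image
bilinear_interp <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  v <- m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
  out[ok] <- v
  out
}

#' Assemble a quality-controlled bead observation
#'
#' Fits an ellipse to one boundary point set and attaches the QC flags used
#' by the calibration step: a bead passes QC only if the fit succeeded, its
#' boundary is not truncated by the image border, it has at least
#' `min_boundary_points` boundary points, and the fit's RMS residual does not
#' exceed `residual_threshold`. Fit failures are reported as non-passing
#' observations, not errors. Because the distortion model is strictly
#' axis-aligned, a QC-passing fit with `|theta| > 10` degrees raises a
#' warning (a model-adequacy diagnostic, not a rejection).
#'
#' @inheritParams segment_beads
#' @param points one boundary point set from [segment_beads()].
#' @param residual_threshold maximum RMS boundary residual in pixels
#'   (default 0.75, about 1.5x the operating residual under strong speckle;
#'   fits above it are almost always segmentation failures).
#' @param min_boundary_points minimum number of boundary points (default 20).
#' @return an object of class `bead_observation`: `ellipse`
#'   ([fit_ellipse()] result or `NULL`), `truncated`, `n_boundary_points`,
#'   `qc_pass`, `qc_reason`.
#' @export
observe_bead <- function(image, points, residual_threshold = 0.75,
                         min_boundary_points = 20L) {
  img <- as_bscan_image(image)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  pts <- as.matrix(points)
  n <- nrow(pts)
  bbox <- attr(points, "bbox")
  truncated <- (n > 0L &&
    any(pts[, 1] <= 2 | pts[, 1] >= w - 1 | pts[, 2] <= 2 | pts[, 2] >= h - 1)) ||
    (!is.null(bbox) &&
       (bbox[["x0"]] <= 1 || bbox[["x1"]] >= w || bbox[["y0"]] <= 1 || bbox[["y1"]] >= h))

  ell <- tryCatch(fit_ellipse(pts), error = function(e) e)
  if (inherits(ell, "error")) {
    return(new_bead_observation(NULL, truncated, n, FALSE,
                                paste0("fit: ", conditionMessage(ell))))
  }

  qc_pass <- TRUE; qc_reason <- "ok"
  if (truncated) {
    qc_pass <- FALSE; qc_reason <- "truncated"
  } else if (n < min_boundary_points) {
    qc_pass <- FALSE; qc_reason <- "too few boundary points"
  } else if (ell$rms_residual > residual_threshold) {
    qc_pass <- FALSE; qc_reason <- "residual"
  }
  if (qc_pass && abs(ell$theta_deg) > 10) {
    warning(sprintf(
      "fitted orientation %.1f deg departs from the axis-aligned distortion model",
      ell$theta_deg), call. = FALSE)
  }
  new_bead_observation(ell, truncated, n, qc_pass, qc_reason)
}

new_bead_observation <- function(ellipse, truncated, n, qc_pass, qc_reason) {
  structure(
    list(ellipse = ellipse, truncated = truncated,
         n_boundary_points = as.integer(n), qc_pass = qc_pass,
         qc_reason = qc_reason),
    class = "bead_observation"
  )
}

#' Detect and fit all beads in a B-scan
#'
#' Convenience wrapper: [segment_beads()] then [observe_bead()] on each
#' candidate.
#'
#' @inheritParams segment_beads
#' @inheritParams observe_bead
#' @return a list of `bead_observation` objects (possibly empty).
#' @export
detect_beads <- function(image, expected_diameter_px_range, seeds = NULL,
                         smooth_sigma = 1, threshold = NULL, n_rays = 120L,
                         residual_threshold = 0.75, min_boundary_points = 20L) {
  sets <- segment_beads(image, expected_diameter_px_range, seeds = seeds,
                        smooth_sigma = smooth_sigma, threshold = threshold,
                        n_rays = n_rays)
  lapply(sets, function(p) {
    observe_bead(image, p, residual_threshold = residual_threshold,
                 min_boundary_points = min_boundary_points)
  })
}
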