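#' B-scan image container
#'
#' A light S3 container for a single OCT B-scan: an intensity matrix in
#' `[0, 1]` whose rows run along the axial (Y, depth) axis, top row =
#' vitreous side, and whose columns run along the lateral (X) axis, plus
#' optional absolute scales. Pixel centers sit at integer coordinates,
#' `x` = column index and `y` = row index (both 1-based).
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`, at least 32 x 32.
#' @param y_um_per_px optional axial scale, micrometers per row step.
#' @param x_um_per_px optional lateral scale, micrometers per column step.
#' @param source optional character tag (e.g. the file the scan was read
#'   from) carried along for provenance.
#' @return an object of class `bscan_image` with fields `pixels`,
#'   `y_um_per_px`, `x_um_per_px`, `source`.
#' @export
bscan_image <- function(pixels, y_um_per_px = NULL, x_um_per_px = NULL,
                        source = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite", call. = FALSE)
  if (nrow(pixels) < 32L || ncol(pixels) < 32L) {
    stop("a B-scan must be at least 32 x 32 pixels", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]", call. = FALSE)
  }
  for (s in list(y_um_per_px, x_um_per_px)) {
    if (!is.null(s) && (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)) {
      stop("pixel scales must be single positive numbers", call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, y_um_per_px = y_um_per_px, x_um_per_px = x_um_per_px,
         source = source),
    class = "bscan_image"
  )
}

as_bscan_image <- function(x) {
  if (inherits(x, "bscan_image")) return(x)
  if (is.matrix(x)) return(bscan_image(x))
  stop("expected a `bscan_image` or an intensity matrix", call. = FALSE)
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("<bscan_image> %d rows (Y/axial) x %d cols (X/lateral)\n",
              nrow(x$pixels), ncol(x$pixels)))
  fmt <- function(s) if (is.null(s)) "unknown" else sprintf("%.4f um/px", s)
  cat("  Y scale:", fmt(x$y_um_per_px), " X scale:", fmt(x$x_um_per_px), "\n")
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse_params> center (%.2f, %.2f) px, a = %.3f px (X), b = %.3f px (Y)\n",
    x$cx, x$cy, x$a_px, x$b_px))
  cat(sprintf("  theta = %.2f deg, axis ratio a/b = %.4f, rms residual = %.4g px (n = %d)\n",
              x$theta_deg, x$axis_ratio, x$rms_residual, x$n_points))
  invisible(x)
}

#' @export
print.bead_observation <- function(x, ...) {
  cat("<bead_observation>",
      if (isTRUE(x$qc_pass)) "QC pass" else paste0("QC FAIL [", x$qc_reason, "]"),
      "\n")
  if (!is.null(x$ellipse)) print(x$ellipse)
  cat(sprintf("  boundary points: %d, truncated: %s\n",
              x$n_boundary_points, x$truncated))
  invisible(x)
}

#' @export
print.scale_calibration <- function(x, ...) {
  sd_txt <- if (is.na(x$k_sd)) "NA (n = 1)" else sprintf("%.4f", x$k_sd)
  cat(sprintf("<scale_calibration> k = %.4f +/- %s (n = %d beads, policy = %s)\n",
              x$k_mean, sd_txt, x$n, x$policy))
  if (!is.null(x$y_um_per_px)) {
    cat(sprintf("  absolute scales: Y %.4f um/px, X %.4f um/px (bead D = %g +/- %g um)\n",
                x$y_um_per_px, x$x_um_per_px, x$bead_diameter_um,
                x$bead_diameter_tol_um))
  }
  invisible(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n = %d) vs %s (n = %d)\n",
              x$group_labels[1], x$ns[1], x$group_labels[2], x$ns[2]))
  cat(sprintf("  means %.4f vs %.4f; %s t = %.4g, p = %.4g%s\n",
              x$means[1], x$means[2], x$method, x$t_statistic, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate: zero variance]" else ""))
  invisible(x)
}
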