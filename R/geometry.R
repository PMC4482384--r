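#' Closed-form geometry of anisotropic display scales
#'
#' In an OCT B-scan the axial (Y) scale derives from the A-scan and is
#' trusted, while the lateral (X) scale is a product of post-processing. When
#' the displayed X scale exceeds the Y scale by a factor `k`, a physical
#' circle displays as an axis-aligned ellipse with semi-axes `a = k*b` along
#' X and `b` along Y, oblique chords are stretched, and off-axis angles are
#' compressed towards the X axis. The functions in this file give the exact
#' corrections.
#'
#' Angles are measured from the X (lateral) axis in degrees and treated with
#' period 180 degrees (an undirected section direction). `k` is the
#' dimensionless axis ratio a/b; `k = 1` means isotropic display.
#'
#' @name geometry
NULL

DEG <- pi / 180

check_axis_ratio <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("axis ratio `k` must be a single finite positive number", call. = FALSE)
  }
  invisible(k)
}

#' Normalize a section angle to [0, 180)
#'
#' Central chords of an ellipse (and undirected line directions) have period
#' 180 degrees; all angle-valued functions in the package normalize their
#' arguments with this helper.
#'
#' @param alpha_deg numeric vector of angles in degrees, measured from the X
#'   axis.
#' @return angles folded into `[0, 180)`.
#' @export
#' @examples
#' normalize_section_angle(c(-45, 180, 270))
normalize_section_angle <- function(alpha_deg) {
  if (!is.numeric(alpha_deg) || any(!is.finite(alpha_deg))) {
    stop("angles must be finite numbers", call. = FALSE)
  }
  alpha_deg %% 180
}

#' Relative diameter of a displayed central chord
#'
#' A physical circle displays, under X/Y anisotropy `k`, as the ellipse
#' `x^2/a^2 + y^2/b^2 = 1` with `a = k*b`. The central chord whose endpoints
#' lie at polar angle `alpha` (in the displayed image) is longer than the
#' true diameter expressed at the Y-axis scale by the factor
#'
#'   `d_r(alpha, k) = k / sqrt(cos(alpha)^2 + k^2 * sin(alpha)^2)`,
#'
#' obtained by evaluating the ellipse's polar radius at `alpha` and dividing
#' by `b`. A length measured on the displayed image along direction `alpha`
#' must be divided by `d_r` to recover the true length in Y-scale units.
#'
#' @param alpha_deg section angle(s) in degrees from the X axis, in displayed
#'   (pixel) space; any finite value, folded to `[0, 180)`.
#' @param k axis ratio a/b (> 0).
#' @return the dimensionless relative diameter, in `[min(k,1), max(k,1)]`;
#'   `d_r(0) = k` and `d_r(90) = 1`.
#' @seealso [correct_length()], [displayed_angle()]
#' @export
#' @examples
#' relative_diameter(0, 3.35)    # k: chord along X
#' relative_diameter(90, 3.35)   # 1: chord along Y is undistorted
#' relative_diameter(45, 5)      # 5 / sqrt(13)
relative_diameter <- function(alpha_deg, k) {
  check_axis_ratio(k)
  a <- normalize_section_angle(alpha_deg) * DEG
  k / sqrt(cos(a)^2 + k^2 * sin(a)^2)
}

#' Correct a length measured along an oblique direction
#'
#' Divides a displayed length by the relative diameter for its direction,
#' yielding the true length at the Y-axis scale. With `k = 1` the input is
#' returned unchanged.
#'
#' @param measured non-negative displayed length(s) (pixels or any unit tied
#'   to the Y scale).
#' @param alpha_deg direction of the measurement in displayed space, degrees
#'   from the X axis.
#' @inheritParams relative_diameter
#' @return corrected length(s) in the same unit, at the Y-axis scale.
#' @export
#' @examples
#' correct_length(33.5, 0, 3.35)  # 10: horizontal lengths shrink by k
#' correct_length(10, 90, 3.35)   # 10: vertical lengths are already correct
correct_length <- function(measured, alpha_deg, k) {
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured < 0)) {
    stop("measured length must be finite and non-negative", call. = FALSE)
  }
  measured / relative_diameter(alpha_deg, k)
}

#' Angle at which a physical direction displays
#'
#' Stretching X coordinates by `k` while leaving Y fixed maps a direction at
#' true angle `alpha_true` to `atan(tan(alpha_true) / k)`: for a structure at
#' a true 45-degree angle the displayed angle is `arctan(b/a) = arctan(1/k)`.
#' 0 and 90 degrees are fixed points; for `k > 1` every oblique angle is
#' displayed smaller than it is.
#'
#' @param alpha_true_deg true (physical-space) angle(s) in degrees from the X
#'   axis.
#' @inheritParams relative_diameter
#' @return displayed angle(s) in degrees, in `[0, 180)`.
#' @export
#' @examples
#' displayed_angle(45, 5)  # atan(1/5) in degrees, ~11.31
displayed_angle <- function(alpha_true_deg, k) {
  check_axis_ratio(k)
  a <- normalize_section_angle(alpha_true_deg) * DEG
  normalize_section_angle(atan2(sin(a), k * cos(a)) / DEG)
}

#' True angle of a direction measured on the displayed image
#'
#' Inverse of [displayed_angle()]: `tan(alpha_true) = k * tan(alpha_displayed)`.
#' Used to restore, e.g., the off-axis angle of a retinal vessel measured on
#' an uncorrected B-scan.
#'
#' @param alpha_displayed_deg angle(s) in degrees measured on the displayed
#'   image, from the X axis.
#' @inheritParams relative_diameter
#' @return true angle(s) in degrees, in `[0, 180)`.
#' @export
#' @examples
#' true_angle(displayed_angle(45, 5), 5)  # 45
true_angle <- function(alpha_displayed_deg, k) {
  check_axis_ratio(k)
  a <- normalize_section_angle(alpha_displayed_deg) * DEG
  normalize_section_angle(atan2(k * sin(a), cos(a)) / DEG)
}
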