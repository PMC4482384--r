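#' Aggregate bead fits into a scale calibration
#'
#' Each QC-passing bead contributes one axis ratio `a_px/b_px`; because the
#' physical bead is a sphere, this ratio estimates the X/Y scale anisotropy
#' `k` directly. Ratios are aggregated by their arithmetic mean (or median
#' under `policy = "median"`) with the sample standard deviation (`n - 1`
#' denominator) as dispersion. The known bead diameter anchors the absolute
#' axial scale, `y_um_per_px = D / mean(2 b_px)`, and with it the lateral
#' scale `x_um_per_px = y_um_per_px / k_mean` (each column covers fewer
#' micrometers than each row when `k > 1`). The bead manufacturing tolerance
#' is recorded but not propagated into `k_sd`.
#'
#' @param observations a list of `bead_observation` objects (see
#'   [observe_bead()]); only QC-passing ones enter the calibration.
#' @param bead_diameter_um nominal physical bead diameter in micrometers
#'   (default 154).
#' @param bead_diameter_tol_um manufacturing tolerance on the diameter
#'   (default 5).
#' @param policy aggregation policy for the per-bead ratios: `"mean"`
#'   (default) or the outlier-robust `"median"`.
#' @return an object of class `scale_calibration`: `k_mean`, `k_sd` (`NA`
#'   for `n = 1`), `n`, `ratios` (per-bead), `b_px` (per-bead minor
#'   semi-axes), `bead_diameter_um`, `bead_diameter_tol_um`, `y_um_per_px`,
#'   `x_um_per_px`, `policy`.
#' @export
calibrate <- function(observations, bead_diameter_um = 154,
                      bead_diameter_tol_um = 5,
                      policy = c("mean", "median")) {
  policy <- match.arg(policy)
  if (!is.list(observations) || length(observations) == 0L) {
    stop("need at least one bead observation", call. = FALSE)
  }
  ok <- vapply(observations, function(o) isTRUE(o$qc_pass), logical(1))
  if (!any(ok)) {
    reasons <- vapply(observations, function(o) o$qc_reason %||% "unknown", character(1))
    stop("no QC-passing beads to calibrate from; reasons: ",
         paste(sprintf("[%s]", reasons), collapse = " "), call. = FALSE)
  }
  passed <- observations[ok]
  ratios <- vapply(passed, function(o) o$ellipse$axis_ratio, numeric(1))
  b_px <- vapply(passed, function(o) o$ellipse$b_px, numeric(1))
  new_scale_calibration(ratios, b_px, bead_diameter_um, bead_diameter_tol_um,
                        policy)
}

#' Build a calibration directly from axis ratios
#'
#' Low-level constructor used when per-bead ratios come from elsewhere
#' (e.g. an external fitting tool); [calibrate()] is the usual entry point.
#'
#' @param ratios numeric vector of per-bead axis ratios `a/b` (> 0).
#' @param b_px optional per-bead minor semi-axes in pixels (needed for the
#'   absolute scale).
#' @inheritParams calibrate
#' @return a `scale_calibration`; see [calibrate()].
#' @export
scale_calibration <- function(ratios, b_px = NULL, bead_diameter_um = 154,
                              bead_diameter_tol_um = 5,
                              policy = c("mean", "median")) {
  policy <- match.arg(policy)
  if (!is.numeric(ratios) || length(ratios) < 1L || any(!is.finite(ratios)) ||
      any(ratios <= 0)) {
    stop("`ratios` must be a non-empty vector of positive numbers", call. = FALSE)
  }
  new_scale_calibration(as.numeric(ratios), b_px, bead_diameter_um,
                        bead_diameter_tol_um, policy)
}

new_scale_calibration <- function(ratios, b_px, bead_diameter_um,
                                  bead_diameter_tol_um, policy) {
  n <- length(ratios)
  k_mean <- if (policy == "median") stats::median(ratios) else mean(ratios)
  k_sd <- if (n >= 2L) stats::sd(ratios) else NA_real_
  y_um_per_px <- x_um_per_px <- NULL
  if (!is.null(b_px) && length(b_px) == n && all(is.finite(b_px)) && all(b_px > 0)) {
    y_um_per_px <- bead_diameter_um / mean(2 * b_px)
    x_um_per_px <- y_um_per_px / k_mean
  }
  structure(
    list(k_mean = k_mean, k_sd = k_sd, n = n, ratios = ratios,
         b_px = if (is.null(b_px)) NULL else as.numeric(b_px),
         bead_diameter_um = bead_diameter_um,
         bead_diameter_tol_um = bead_diameter_tol_um,
         y_um_per_px = y_um_per_px, x_um_per_px = x_um_per_px,
         policy = policy),
    class = "scale_calibration"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare correction factors between two bead groups
#'
#' Two-sample t-test on the per-bead axis ratios of two calibrations, e.g.
#' subretinally versus epiretinally placed beads. The default is the
#' classical Student's test (equal-variance, pooled SD, two-sided); Welch's
#' unequal-variance test is available via `method = "welch"`. Degenerate
#' zero-variance inputs are handled explicitly rather than erroring: equal
#' means give `t = 0, p = 1`; different means are flagged `degenerate` with
#' `p = 0`.
#'
#' @param cal_a,cal_b `scale_calibration` objects carrying per-bead ratios,
#'   each with `n >= 2`.
#' @param labels character pair naming the groups.
#' @param method `"student"` (default) or `"welch"`.
#' @return an object of class `group_comparison`: `group_labels`, `means`,
#'   `sds`, `ns`, `t_statistic`, `p_value`, `method`, `degenerate`.
#' @export
compare_groups <- function(cal_a, cal_b, labels = c("A", "B"),
                           method = c("student", "welch")) {
  method <- match.arg(method)
  for (cal in list(cal_a, cal_b)) {
    if (!inherits(cal, "scale_calibration")) {
      stop("inputs must be `scale_calibration` objects", call. = FALSE)
    }
    if (cal$n < 2L) stop("group comparison needs n >= 2 per group", call. = FALSE)
  }
  x <- cal_a$ratios; y <- cal_b$ratios
  degenerate <- FALSE
  if (stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      t_stat <- 0; p <- 1
    } else {
      degenerate <- TRUE
      t_stat <- sign(mean(x) - mean(y)) * Inf
      p <- 0
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = (method == "student"))
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(group_labels = labels,
         means = c(mean(x), mean(y)), sds = c(stats::sd(x), stats::sd(y)),
         ns = c(length(x), length(y)),
         t_statistic = t_stat, p_value = p, method = method,
         degenerate = degenerate),
    class = "group_comparison"
  )
}

#' Pool two calibrations when they do not differ
#'
#' Mirrors the study design the package supports: calibrate bead groups from
#' different positions separately, test for a difference, and pool only when
#' the test finds none (`p >= alpha`).
#'
#' @inheritParams compare_groups
#' @param alpha significance level gate for pooling (default 0.05).
#' @return a pooled `scale_calibration`, or `NULL` (with a message) when the
#'   groups differ significantly.
#' @export
pool_calibrations <- function(cal_a, cal_b, alpha = 0.05,
                              method = c("student", "welch")) {
  cmp <- compare_groups(cal_a, cal_b, method = method)
  if (cmp$p_value < alpha) {
    message(sprintf("groups differ (p = %.3g < %g); not pooling", cmp$p_value, alpha))
    return(NULL)
  }
  b_px <- if (!is.null(cal_a$b_px) && !is.null(cal_b$b_px)) {
    c(cal_a$b_px, cal_b$b_px)
  } else NULL
  new_scale_calibration(c(cal_a$ratios, cal_b$ratios), b_px,
                        cal_a$bead_diameter_um, cal_a$bead_diameter_tol_um,
                        cal_a$policy)
}

CALIBRATION_SCHEMA_VERSION <- 1L

#' Save or load a calibration as JSON
#'
#' Once a correction factor has been determined for a population and setup
#' it can be stored and applied to all similar recordings. The JSON schema
#' is versioned; loading rejects files without a `schema_version` and names
#' any missing required field.
#'
#' @param cal a `scale_calibration`.
#' @param path file path for the JSON document.
#' @return `save_calibration` returns `path` invisibly; `load_calibration`
#'   returns the restored `scale_calibration`.
#' @export
save_calibration <- function(cal, path) {
  if (!inherits(cal, "scale_calibration")) {
    stop("`cal` must be a scale_calibration", call. = FALSE)
  }
  doc <- list(
    schema_version = CALIBRATION_SCHEMA_VERSION,
    k_mean = cal$k_mean, k_sd = cal$k_sd, n = cal$n, ratios = cal$ratios,
    b_px = cal$b_px,
    bead_diameter_um = cal$bead_diameter_um,
    bead_diameter_tol_um = cal$bead_diameter_tol_um,
    y_um_per_px = cal$y_um_per_px, x_um_per_px = cal$x_um_per_px,
    policy = cal$policy
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed calibration JSON: ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(doc$schema_version)) {
    stop("schema_version missing: not a calibration file (or a legacy file; ",
         "re-save it with save_calibration())", call. = FALSE)
  }
  if (doc$schema_version != CALIBRATION_SCHEMA_VERSION) {
    stop("unsupported calibration schema_version ", doc$schema_version, call. = FALSE)
  }
  for (f in c("k_mean", "n", "ratios", "bead_diameter_um", "policy")) {
    if (is.null(doc[[f]])) stop(f, " missing from calibration file", call. = FALSE)
  }
  cal <- new_scale_calibration(
    as.numeric(doc$ratios),
    if (is.null(doc$b_px)) NULL else as.numeric(doc$b_px),
    doc$bead_diameter_um,
    doc$bead_diameter_tol_um %||% 5,
    doc$policy
  )
  if (abs(cal$k_mean - doc$k_mean) > 1e-9) {
    stop("calibration file is inconsistent: stored k_mean does not match its ratios",
         call. = FALSE)
  }
  cal
}
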