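#' Build a pipeline run configuration
#'
#' Bundles every tunable of the detect-fit-calibrate(-rescale) pipeline with
#' validated defaults. A JSON echo of the configuration is written to the
#' output directory of every run so that each run is reproducible from its
#' artifacts alone.
#'
#' @param input a directory of images, or a character vector of image files
#'   (PNG/TIFF/BMP).
#' @param output_dir directory for artifacts (created if missing).
#' @param bead_diameter_um,diameter_tolerance_um nominal bead size and
#'   manufacturing tolerance in micrometers (defaults 154 and 5).
#' @param expected_diameter_px_range plausible displayed bead diameters in
#'   pixels (default `c(16, 160)`, spanning the unstretched minor axis up to
#'   a strongly stretched major axis).
#' @param residual_threshold,min_boundary_points QC thresholds passed to
#'   [observe_bead()].
#' @param smooth_sigma segmentation smoothing in pixels.
#' @param interpolation resampling method for corrected images.
#' @param rescale write Y-rescaled copies of the inputs (default TRUE).
#' @param y_um_per_px optional known axial scale attached to inputs.
#' @param seed integer seed echoed into the config (the analysis itself is
#'   deterministic).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, output_dir,
                       bead_diameter_um = 154, diameter_tolerance_um = 5,
                       expected_diameter_px_range = c(16, 160),
                       residual_threshold = 0.75, min_boundary_points = 20L,
                       smooth_sigma = 1, interpolation = "linear",
                       rescale = TRUE, y_um_per_px = NULL, seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  for (v in list(bead_diameter_um, diameter_tolerance_um, residual_threshold,
                 min_boundary_points, smooth_sigma)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("all thresholds must be single positive numbers", call. = FALSE)
    }
  }
  structure(
    list(input = input, output_dir = output_dir,
         bead_diameter_um = bead_diameter_um,
         diameter_tolerance_um = diameter_tolerance_um,
         expected_diameter_px_range = expected_diameter_px_range,
         residual_threshold = residual_threshold,
         min_boundary_points = as.integer(min_boundary_points),
         smooth_sigma = smooth_sigma, interpolation = interpolation,
         rescale = rescale, y_um_per_px = y_um_per_px,
         seed = as.integer(seed), log_level = log_level),
    class = "run_config"
  )
}

#' Load a pipeline configuration from JSON or key=value text
#'
#' @param path a `.json` file with [run_config()] fields, or a plain-text
#'   file of `key=value` lines.
#' @param ... overrides applied after reading (flags beat the file).
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                  value = TRUE, invert = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    vv <- lapply(kv, function(p) {
      x <- trimws(paste(p[-1], collapse = "="))
      if (grepl("^-?[0-9.eE, +-]+$", x) && nzchar(x)) {
        as.numeric(strsplit(x, ",")[[1]])
      } else if (x %in% c("TRUE", "FALSE", "true", "false")) {
        as.logical(toupper(x))
      } else x
    })
    stats::setNames(vv, vapply(kv, function(p) trimws(p[1]), character(1)))
  }
  vals[names(list(...))] <- list(...)
  do.call(run_config, vals)
}

#' Run the full calibration pipeline
#'
#' For every readable input image: detect beads, fit ellipses, QC. All
#' QC-passing beads are pooled into one [calibrate()] call. Artifacts
#' written to `output_dir`: `beads.csv` (one row per observation),
#' `calibration.json`, `report.txt`, `config.json`, and (optionally)
#' Y-rescaled copies of each input with provenance sidecars. Unreadable
#' files are reported and skipped; zero QC-passing beads overall is an
#' error.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `calibration`, `beads` (data frame),
#'   `files`, `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  info <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  files <- if (length(config$input) == 1L && dir.exists(config$input)) {
    list.files(config$input, pattern = "\\.(png|tif|tiff|bmp)$",
               ignore.case = TRUE, full.names = TRUE)
  } else config$input
  if (length(files) == 0L) stop("no images found in ", config$input, call. = FALSE)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  rows <- list(); all_obs <- list(); errors <- character()
  images <- list()
  for (f in files) {
    img <- tryCatch(read_bscan(f, y_um_per_px = config$y_um_per_px),
                    error = function(e) e)
    if (inherits(img, "error")) {
      errors <- c(errors, sprintf("%s: %s", f, conditionMessage(img)))
      info("SKIP %s (%s)", basename(f), conditionMessage(img))
      next
    }
    images[[f]] <- img
    obs <- detect_beads(img, config$expected_diameter_px_range,
                        smooth_sigma = config$smooth_sigma,
                        residual_threshold = config$residual_threshold,
                        min_boundary_points = config$min_boundary_points)
    info("%s: %d candidate bead(s), %d QC-passing", basename(f), length(obs),
         sum(vapply(obs, function(o) isTRUE(o$qc_pass), logical(1))))
    for (o in obs) {
      e <- o$ellipse
      rows[[length(rows) + 1L]] <- data.frame(
        file = basename(f),
        cx = e$cx %||% NA_real_, cy = e$cy %||% NA_real_,
        a_px = e$a_px %||% NA_real_, b_px = e$b_px %||% NA_real_,
        theta = e$theta_deg %||% NA_real_,
        ratio = e$axis_ratio %||% NA_real_,
        rms_residual = e$rms_residual %||% NA_real_,
        n_boundary_points = o$n_boundary_points,
        truncated = o$truncated, qc_pass = o$qc_pass, qc_reason = o$qc_reason
      )
    }
    all_obs <- c(all_obs, obs)
  }

  beads <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.csv(beads, file.path(config$output_dir, "beads.csv"),
                   row.names = FALSE)

  n_pass <- sum(beads$qc_pass %||% logical(0))
  if (length(all_obs) == 0L || n_pass == 0L) {
    writeLines(c("CALIBRATION FAILED: no QC-passing beads", errors),
               file.path(config$output_dir, "report.txt"))
    stop("no QC-passing beads across ", length(files), " image(s)", call. = FALSE)
  }

  cal <- calibrate(all_obs, bead_diameter_um = config$bead_diameter_um,
                   bead_diameter_tol_um = config$diameter_tolerance_um)
  save_calibration(cal, file.path(config$output_dir, "calibration.json"))

  if (isTRUE(config$rescale)) {
    for (f in names(images)) {
      out <- rescale_image(images[[f]], cal, interpolation = config$interpolation)
      write_image(out, file.path(
        config$output_dir,
        paste0(tools::file_path_sans_ext(basename(f)), "_corrected.png")))
    }
  }

  report <- c(
    sprintf("isoscale pipeline report"),
    sprintf("images: %d (%d unreadable)", length(files), length(errors)),
    sprintf("beads: %d candidates, %d QC-passing", nrow(beads), n_pass),
    sprintf("correction factor k = %.4f +/- %s (n = %d)", cal$k_mean,
            ifelse(is.na(cal$k_sd), "NA", sprintf("%.4f", cal$k_sd)), cal$n),
    if (!is.null(cal$y_um_per_px)) {
      sprintf("absolute scales: Y %.4f um/px, X %.4f um/px",
              cal$y_um_per_px, cal$x_um_per_px)
    },
    if (length(errors)) c("unreadable files:", paste(" ", errors))
  )
  writeLines(unlist(report), file.path(config$output_dir, "report.txt"))
  info("k = %.4f +/- %.4f (n = %d)", cal$k_mean, cal$k_sd, cal$n)

  invisible(list(calibration = cal, beads = beads, files = files,
                 errors = errors))
}
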