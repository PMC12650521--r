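# ---- clinical bands, detection range, flow rate, reports ------------------

#' Clinical band boundaries
#'
#' Defaults follow the normal fasting window of about 70-110 mg/dL:
#' readings below `low_upper` are Low, readings in `[low_upper,
#' normal_upper]` (both boundaries inclusive) are Normal, higher readings
#' are High.
#'
#' @param low_upper Upper boundary of the Low band, mg/dL (default 70).
#' @param normal_upper Upper boundary of the Normal band, mg/dL (default 110).
#' @return A `band_config`.
#' @export
band_config <- function(low_upper = 70, normal_upper = 110) {
  if (!(0 < low_upper && low_upper < normal_upper))
    stop_glc("schema", "band boundaries must satisfy 0 < low_upper < normal_upper")
  structure(list(low_upper = low_upper, normal_upper = normal_upper),
            class = "band_config")
}

#' Classify a glucose concentration into a clinical band
#'
#' @param glucose Glucose concentration(s), mg/dL (finite).
#' @param bands A [band_config].
#' @return An ordered factor with levels `Low < Normal < High`.
#' @export
classify_band <- function(glucose, bands = band_config()) {
  stopifnot(inherits(bands, "band_config"), all(is.finite(glucose)))
  idx <- ifelse(glucose < bands$low_upper, 1L,
         ifelse(glucose <= bands$normal_upper, 2L, 3L))
  factor(c("Low", "Normal", "High")[idx],
         levels = c("Low", "Normal", "High"), ordered = TRUE)
}

#' Check a reading against the strip's detection range
#'
#' The strip response is considered usable from approximately 50 to
#' 140 mg/dL (boundaries inclusive); the range is carried by the
#' calibration model.
#'
#' @param glucose Glucose concentration(s), mg/dL.
#' @param model A `calibration_model` (its `detection_range` is used).
#' @return Logical: `TRUE` iff within range.
#' @export
check_detection_range <- function(glucose, model = reference_models()$whole_blood) {
  stopifnot(inherits(model, "calibration_model"))
  glucose >= model$detection_range[1] & glucose <= model$detection_range[2]
}

#' Average capillary flow rate
#'
#' Distance travelled over elapsed time, reported to three decimals
#' (e.g. the 10 mm channel transit in 286.5 s gives 0.035 mm/s).
#'
#' @param distance_mm Distance, mm (positive).
#' @param elapsed_s Elapsed time, s (positive).
#' @return Flow rate in mm/s, rounded to three decimals.
#' @export
compute_flow_rate <- function(distance_mm, elapsed_s) {
  if (any(distance_mm <= 0) || any(elapsed_s <= 0))
    stop_glc("schema", "distance and elapsed time must be positive")
  round_half_up(distance_mm / elapsed_s * 1000) / 1000
}

#' Construct a glucose reading
#'
#' The final result of one measurement: the concentration, its clinical
#' band, the detection-range flag, and the provenance of the intensity
#' measurement.
#'
#' @param glucose Concentration, mg/dL.
#' @param intensity An `intensity_score`.
#' @param model The `calibration_model` used.
#' @param bands A [band_config].
#' @param timestamp Time of measurement (default now, UTC).
#' @return A `glucose_reading`.
#' @export
glucose_reading <- function(glucose, intensity, model, bands = band_config(),
                            timestamp = format(Sys.time(), tz = "UTC",
                                               "%Y-%m-%dT%H:%M:%SZ")) {
  stopifnot(inherits(intensity, "intensity_score"),
            inherits(model, "calibration_model"))
  structure(list(
    glucose_mg_dl = glucose,
    band = as.character(classify_band(glucose, bands)),
    in_detection_range = unname(check_detection_range(glucose, model)),
    intensity = intensity$score,
    white_count = intensity$white_count,
    roi_area = intensity$roi_area,
    model_id = model$sample_type,
    model_source = model$source,
    timestamp = timestamp),
    class = "glucose_reading")
}

#' @export
print.glucose_reading <- function(x, ...) {
  cat(sprintf("<glucose_reading> %.1f mg/dL [%s]%s\n", x$glucose_mg_dl, x$band,
              if (x$in_detection_range) "" else " (outside detection range)"))
  cat(sprintf("  intensity %.2f (%d white px / %g ROI px), model %s/%s\n",
              x$intensity, x$white_count, x$roi_area, x$model_id,
              x$model_source))
  invisible(x)
}

#' Build a machine-readable measurement report
#'
#' Emits a JSON record with all reading fields, the HSV ranges used, and
#' mask statistics, plus (optionally) a rendered reference color-scale PNG
#' for visual comparison of concentration bands without the app.
#'
#' @param reading A `glucose_reading`.
#' @param mask_stats Optional named list of per-color white-pixel counts.
#' @param ranges HSV range set used for segmentation.
#' @param bands The [band_config] used.
#' @param path Optional path for the JSON report file.
#' @param scale_png Optional path for the reference color-scale PNG.
#' @return The report as a named list (class `glucose_report`), invisibly
#'   when written to file.
#' @export
build_report <- function(reading, mask_stats = NULL,
                         ranges = default_hsv_ranges(),
                         bands = band_config(),
                         path = NULL, scale_png = NULL) {
  stopifnot(inherits(reading, "glucose_reading"))
  range_entry <- function(r) list(lower = r$lower, upper = r$upper)
  report <- list(
    schema = "glucopad/report/v1",
    reading = unclass(reading),
    bands = unclass(bands),
    hsv_ranges = list(blue = range_entry(ranges$blue),
                      green = range_entry(ranges$green),
                      red = lapply(ranges$red, range_entry)),
    mask_stats = mask_stats)
  class(report) <- "glucose_report"
  if (!is.null(scale_png)) {
    write_chip_image(render_color_scale(bands), scale_png)
    report$color_scale_png <- scale_png
  }
  if (!is.null(path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Read a JSON report written by [build_report()]
#' @param path File path.
#' @return A `glucose_report` list.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "glucose_report"
  x
}

#' Validate a report against the package report schema
#'
#' Checks the `glucopad/report/v1` structure: required reading fields with
#' the right types, band consistency, and HSV range blocks.
#'
#' @param report A `glucose_report` (or list parsed from report JSON).
#' @return `TRUE` invisibly; signals a `glucopad_error_schema` otherwise.
#' @export
validate_report <- function(report) {
  fail <- function(msg) stop_glc("schema", paste("invalid report:", msg))
  if (!identical(report$schema, "glucopad/report/v1")) fail("schema tag")
  rd <- report$reading
  need <- c("glucose_mg_dl", "band", "in_detection_range", "intensity",
            "white_count", "roi_area", "model_id", "timestamp")
  if (!all(need %in% names(rd))) fail("missing reading fields")
  if (!rd$band %in% c("Low", "Normal", "High")) fail("band value")
  if (!is.logical(rd$in_detection_range)) fail("in_detection_range type")
  bands <- report$bands
  if (is.null(bands$low_upper) || is.null(bands$normal_upper)) fail("bands")
  expected <- as.character(classify_band(rd$glucose_mg_dl,
                                         band_config(bands$low_upper,
                                                     bands$normal_upper)))
  if (!identical(expected, rd$band)) fail("band inconsistent with config")
  if (!all(c("blue", "green", "red") %in% names(report$hsv_ranges)))
    fail("hsv_ranges")
  invisible(TRUE)
}

#' Render the reference visual-comparison color scale
#'
#' A vertical scale of TMB-blue shades, darker with higher glucose, with
#' band boundaries marked: the fallback visual readout when no app or
#' connection is available.
#'
#' @param bands A [band_config].
#' @param glucose_range Concentration span of the scale, mg/dL.
#' @param width,height Size of the rendered scale, pixels.
#' @return An [rgb_image].
#' @export
render_color_scale <- function(bands = band_config(),
                               glucose_range = c(40, 160),
                               width = 60L, height = 220L) {
  g <- seq(glucose_range[2], glucose_range[1], length.out = height)
  # deeper TMB blue with concentration: interpolate value/saturation
  frac <- (g - glucose_range[1]) / diff(glucose_range)
  col <- grDevices::hsv(h = 210 / 360, s = 0.25 + 0.7 * frac,
                        v = 0.95 - 0.55 * frac)
  rgbm <- grDevices::col2rgb(col)
  px <- array(0, c(height, width, 3))
  for (k in 1:3) px[, , k] <- matrix(rgbm[k, ], height, width)
  # white tick rows at band boundaries
  for (b in c(bands$low_upper, bands$normal_upper)) {
    if (b > glucose_range[1] && b < glucose_range[2]) {
      row <- round(1 + (glucose_range[2] - b) / diff(glucose_range) * (height - 1))
      px[row, , ] <- 255
    }
  }
  rgb_image(px)
}

#' Summarize a batch of readings as a table
#'
#' @param readings List of `glucose_reading` objects.
#' @param ids Optional identifiers (e.g. image paths), one per reading.
#' @return A data frame with one row per reading.
#' @export
readings_table <- function(readings, ids = NULL) {
  stopifnot(all(vapply(readings, inherits, TRUE, "glucose_reading")))
  df <- do.call(rbind, lapply(readings, function(r)
    data.frame(glucose_mg_dl = r$glucose_mg_dl, band = r$band,
               in_detection_range = r$in_detection_range,
               intensity = r$intensity, white_count = r$white_count,
               roi_area = r$roi_area, model_id = r$model_id,
               timestamp = r$timestamp)))
  if (!is.null(ids)) df <- cbind(id = ids, df)
  df
}
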