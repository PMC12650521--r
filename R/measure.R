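# ---- the end-to-end measurement pipeline ----------------------------------

#' Run configuration
#'
#' Collects everything the measurement pipeline needs: HSV ranges, clinical
#' bands, mask mode, calibration model, and the chip geometry used to
#' convert the detected chip scale into the nominal reaction-zone area.
#'
#' @param ranges HSV range set ([default_hsv_ranges()] by default).
#' @param bands A [band_config].
#' @param mask_mode `"union"`, `"blue"`, or `"green"` — which color mask(s)
#'   define the reaction zone.
#' @param model A `calibration_model` (default: built-in whole-blood line).
#' @param layout A [chip_layout] describing the chip being photographed.
#' @param roi_area Optional fixed ROI area (pixels) overriding the
#'   geometry-based estimate.
#' @param seed Integer seed for any randomized steps.
#' @return A `run_config`.
#' @export
run_config <- function(ranges = default_hsv_ranges(), bands = band_config(),
                       mask_mode = c("union", "blue", "green"),
                       model = reference_models()$whole_blood,
                       layout = chip_layout(), roi_area = NULL, seed = 1L) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(inherits(bands, "band_config"),
            inherits(model, "calibration_model"),
            inherits(layout, "chip_layout"))
  structure(list(ranges = ranges, bands = bands, mask_mode = mask_mode,
                 model = model, layout = layout, roi_area = roi_area,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys (all optional, defaults as in [run_config()]):
#' `hsv_ranges` (named lower/upper triples for blue, green, and the red
#' wraparound pair), `bands` (`low_upper`, `normal_upper`), `mask_mode`,
#' `model` (`"whole_blood"`, `"plasma"`, or a path to a model file),
#' `layout` (chip dimensions in mm), `roi_area`, `seed`.
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ranges <- default_hsv_ranges()
  if (!is.null(y$hsv_ranges)) {
    hr <- y$hsv_ranges
    if (!is.null(hr$blue))
      ranges$blue <- hsv_range(unlist(hr$blue$lower), unlist(hr$blue$upper), "blue")
    if (!is.null(hr$green))
      ranges$green <- hsv_range(unlist(hr$green$lower), unlist(hr$green$upper), "green")
    if (!is.null(hr$red))
      ranges$red <- lapply(seq_along(hr$red), function(i)
        hsv_range(unlist(hr$red[[i]]$lower), unlist(hr$red[[i]]$upper),
                  paste0("red_", i)))
  }
  bands <- if (!is.null(y$bands))
    band_config(y$bands$low_upper %||% 70, y$bands$normal_upper %||% 110)
  else band_config()
  model <- resolve_model(y$model %||% "whole_blood")
  layout <- if (!is.null(y$layout)) do.call(chip_layout, y$layout) else chip_layout()
  run_config(ranges = ranges, bands = bands,
             mask_mode = y$mask_mode %||% "union", model = model,
             layout = layout, roi_area = y$roi_area,
             seed = y$seed %||% 1L)
}

resolve_model <- function(spec) {
  if (inherits(spec, "calibration_model")) return(spec)
  if (spec %in% c("whole_blood", "plasma")) return(reference_models()[[spec]])
  if (file.exists(spec)) return(read_calibration_model(spec))
  stop_glc("schema", sprintf("cannot resolve calibration model '%s'", spec))
}

#' Measure glucose from a chip photograph
#'
#' The full readout: convert to HSV, locate the chip, label the blood and
#' reaction regions, extract the reaction ROI (largest connected reacted
#' component), score its intensity against the nominal analysis-zone area,
#' convert to concentration with the calibration line, classify, and flag
#' the detection range.
#'
#' The score denominator is the chip's nominal analysis-zone area in
#' pixels, obtained from the configured chip geometry and the scale
#' (pixels/mm) estimated from the detected chip's bounding-box length; a
#' fixed `roi_area` in the config overrides this.
#'
#' @param image An [rgb_image] or a path to a PNG/JPEG file.
#' @param config A [run_config].
#' @return A list with `reading` (a `glucose_reading`), `score`, `chip`,
#'   `labels`, `roi`, and `mask_stats`.
#' @export
measure_chip <- function(image, config = run_config()) {
  if (is.character(image)) image <- read_chip_image(image)
  stopifnot(inherits(image, "rgb_image"), inherits(config, "run_config"))
  hsv <- rgb_to_hsv(image)
  chip <- detect_chip(hsv)
  labels <- label_regions(hsv, chip, ranges = config$ranges,
                          mask_mode = config$mask_mode)
  roi <- extract_reaction_roi(labels, hsv = hsv)
  roi_area <- config$roi_area %||% {
    bbox_w <- chip$bbox["xmax"] - chip$bbox["xmin"] + 1
    px_per_mm <- as.numeric(bbox_w) / config$layout$paper_length
    analysis_zone_area_px(config$layout, px_per_mm)
  }
  score <- intensity_score(roi$area, roi_area)
  pred <- predict_glucose(config$model, score)
  reading <- glucose_reading(pred$glucose_mg_dl, score, config$model,
                             bands = config$bands)
  lab <- unclass(labels)
  mask_stats <- list(chip_px = chip$area,
                     blood_px = sum(lab == 2L),
                     reaction_px = sum(lab == 3L),
                     reaction_roi_px = roi$area,
                     mask_mode = config$mask_mode)
  list(reading = reading, score = score, chip = chip, labels = labels,
       roi = roi, mask_stats = mask_stats)
}

#' Measure a batch of chip photographs
#'
#' @param paths Image file paths.
#' @param config A [run_config].
#' @return A data frame, one row per image, with the reading fields and a
#'   `status` column (`"ok"`, `"chip_not_found"`, `"no_reaction"`).
#' @export
measure_batch <- function(paths, config = run_config()) {
  rows <- lapply(paths, function(p) {
    res <- tryCatch(measure_chip(p, config), glucopad_error = identity)
    if (inherits(res, "glucopad_error")) {
      status <- if (inherits(res, "glucopad_error_chip_not_found"))
        "chip_not_found"
      else if (inherits(res, "glucopad_error_no_reaction")) "no_reaction"
      else "error"
      data.frame(id = p, glucose_mg_dl = NA_real_, band = NA_character_,
                 in_detection_range = NA, intensity = NA_real_,
                 white_count = NA_integer_, roi_area = NA_real_,
                 model_id = config$model$sample_type,
                 timestamp = NA_character_, status = status)
    } else {
      cbind(readings_table(list(res$reading), ids = p), status = "ok")
    }
  })
  do.call(rbind, rows)
}
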