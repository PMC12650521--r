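# ---- linear intensity -> glucose calibration ------------------------------

#' Build a table of calibration pairs
#'
#' @param intensity Color-intensity scores on the 0-255 scale.
#' @param glucose Reference glucose concentrations, mg/dL (positive).
#' @param replicate Optional replicate identifiers.
#' @return A data frame of class `calibration_pairs` with columns
#'   `intensity`, `glucose_mg_dl` (and `replicate` if given).
#' @export
calibration_pairs <- function(intensity, glucose, replicate = NULL) {
  intensity <- as.numeric(intensity); glucose <- as.numeric(glucose)
  if (length(intensity) != length(glucose))
    stop_glc("schema", "intensity and glucose must have equal length")
  if (any(!is.finite(intensity)) || any(intensity < 0 | intensity > 255))
    stop_glc("schema", "intensity values must lie in [0, 255]")
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop_glc("schema", "reference glucose must be positive")
  df <- data.frame(intensity = intensity, glucose_mg_dl = glucose)
  if (!is.null(replicate)) df$replicate <- replicate
  class(df) <- c("calibration_pairs", "data.frame")
  df
}

#' Read calibration pairs from delimited text
#'
#' Expects a header with columns `intensity` and `glucose_mg_dl`
#' (optionally `replicate`), comma- or tab-delimited.
#'
#' @param path File path.
#' @return A `calibration_pairs` data frame.
#' @export
read_calibration_pairs <- function(path) {
  df <- utils::read.delim(path, sep = guess_sep(path), header = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("intensity", "glucose_mg_dl") %in% names(df)))
    stop_glc("schema", "pairs file must have columns intensity, glucose_mg_dl")
  calibration_pairs(df$intensity, df$glucose_mg_dl,
                    replicate = df[["replicate"]])
}

#' Write calibration pairs to CSV
#' @param pairs A `calibration_pairs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

new_calibration_model <- function(slope, intercept, sample_type,
                                  r_squared = NA_real_, rmse = NA_real_,
                                  n = NA_integer_, detection_range = c(50, 140),
                                  source = "fitted") {
  if (!is.finite(slope) || slope == 0)
    stop_glc("singular_fit", "slope must be finite and nonzero for a usable model")
  if (detection_range[1] >= detection_range[2])
    stop_glc("schema", "detection range low must be below high")
  structure(list(slope = slope, intercept = intercept,
                 sample_type = sample_type, r_squared = r_squared,
                 rmse = rmse, n = n,
                 detection_range = as.numeric(detection_range),
                 source = source),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s (%s)\n", x$sample_type, x$source))
  cat(sprintf("  Glucose [mg/dL] = %.4f x intensity %+.2f\n", x$slope, x$intercept))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 = %.4f, RMSE = %.3f mg/dL (n = %d)\n",
                x$r_squared, x$rmse, x$n))
  cat(sprintf("  detection range: %g-%g mg/dL\n",
              x$detection_range[1], x$detection_range[2]))
  invisible(x)
}

#' Fit the linear intensity -> glucose calibration
#'
#' Ordinary least squares with glucose as the response and color intensity
#' as the predictor, as used to construct the device's calibration line.
#'
#' @param pairs A `calibration_pairs` data frame (at least two pairs with at
#'   least two distinct intensities).
#' @param sample_type `"whole_blood"` or `"plasma"`.
#' @param detection_range Usable concentration interval in mg/dL.
#' @return A `calibration_model` with `slope`, `intercept`, `r_squared` and
#'   `rmse` (root mean square of the fit residuals).
#' @export
fit_calibration <- function(pairs, sample_type = c("whole_blood", "plasma"),
                            detection_range = c(50, 140)) {
  sample_type <- match.arg(sample_type)
  if (nrow(pairs) < 2L)
    stop_glc("singular_fit", "at least two calibration pairs are required")
  if (length(unique(pairs$intensity)) < 2L)
    stop_glc("singular_fit", "all intensities identical; the fit is singular")
  fit <- stats::lm(glucose_mg_dl ~ intensity, data = pairs)
  res <- stats::residuals(fit)
  r2 <- if (stats::var(pairs$glucose_mg_dl) > 0)
    1 - sum(res^2) / sum((pairs$glucose_mg_dl - mean(pairs$glucose_mg_dl))^2)
  else NA_real_
  new_calibration_model(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sample_type = sample_type,
    r_squared = r2,
    rmse = sqrt(mean(res^2)),
    n = nrow(pairs),
    detection_range = detection_range,
    source = "fitted")
}

#' Built-in reference calibration models
#'
#' The device's published calibration lines:
#' whole blood `Glucose = 1.4686 x intensity - 157.16` and
#' plasma `Glucose = 1.5278 x intensity - 194.35`, both with a 50-140 mg/dL
#' detection range. These are fixed reference models, not refittable in
#' place.
#'
#' @return Named list with elements `whole_blood` and `plasma`, each a
#'   `calibration_model` with `source = "reference"`.
#' @export
reference_models <- function() {
  list(
    whole_blood = new_calibration_model(1.4686, -157.16, "whole_blood",
                                        source = "reference"),
    plasma = new_calibration_model(1.5278, -194.35, "plasma",
                                   source = "reference"))
}

#' Predict glucose concentration from a color intensity
#'
#' Applies the calibration line `glucose = slope x intensity + intercept`.
#' Concentrations are reported to one decimal. Values outside the model's
#' detection range (including negative predictions) are returned flagged,
#' never clamped.
#'
#' @param model A `calibration_model`.
#' @param intensity Intensity score(s) on the 0-255 scale, or
#'   `intensity_score` objects.
#' @return A data frame with columns `intensity`, `glucose_mg_dl` (one
#'   decimal) and `in_detection_range`.
#' @export
predict_glucose <- function(model, intensity) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(intensity, "intensity_score")) intensity <- intensity$score
  intensity <- as.numeric(intensity)
  g <- round_half_up((model$slope * intensity + model$intercept) * 10) / 10
  data.frame(intensity = intensity,
             glucose_mg_dl = g,
             in_detection_range = g >= model$detection_range[1] &
                                  g <= model$detection_range[2])
}

#' Evaluate a calibration model on held-out pairs
#'
#' @param model A `calibration_model`.
#' @param pairs A `calibration_pairs` data frame (at least one pair).
#' @return List with `rmse` (mg/dL, root mean square prediction error,
#'   computed from unrounded predictions) and `r_squared` (`NA` when the
#'   pairs have zero glucose variance, in which case it is undefined).
#' @export
evaluate_model <- function(model, pairs) {
  stopifnot(inherits(model, "calibration_model"), nrow(pairs) >= 1L)
  pred <- model$slope * pairs$intensity + model$intercept
  res <- pairs$glucose_mg_dl - pred
  ss_tot <- sum((pairs$glucose_mg_dl - mean(pairs$glucose_mg_dl))^2)
  list(rmse = sqrt(mean(res^2)),
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_)
}

#' Compare two calibration lines
#'
#' Reports the slope difference `a - b` and the vertical offset between the
#' lines, evaluated at the intensity corresponding to the midpoint of the
#' shared (intersected) detection range. Near-zero slope difference with a
#' constant offset indicates parallel calibration lines.
#'
#' @param a,b `calibration_model` objects.
#' @return List with `slope_difference` and `mean_offset` (mg/dL).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "calibration_model"), inherits(b, "calibration_model"))
  lo <- max(a$detection_range[1], b$detection_range[1])
  hi <- min(a$detection_range[2], b$detection_range[2])
  g_mid <- (lo + hi) / 2
  i_mid <- mean(c((g_mid - a$intercept) / a$slope,
                  (g_mid - b$intercept) / b$slope))
  offset <- (a$slope - b$slope) * i_mid + (a$intercept - b$intercept)
  list(slope_difference = a$slope - b$slope, mean_offset = offset)
}

#' Serialize a calibration model to a structured text file
#'
#' Models are stored as a small YAML document (slope, intercept, sample
#' type, fit statistics, detection range, source).
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  yaml::write_yaml(unclass(model), path, precision = 15)
  invisible(path)
}

#' Read a calibration model written by [write_calibration_model()]
#' @param path File path.
#' @return A `calibration_model`.
#' @export
read_calibration_model <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("slope", "intercept", "sample_type")
  if (!all(need %in% names(x)))
    stop_glc("schema", "model file must contain slope, intercept, sample_type")
  new_calibration_model(x$slope, x$intercept, x$sample_type,
                        r_squared = x$r_squared %||% NA_real_,
                        rmse = x$rmse %||% NA_real_,
                        n = x$n %||% NA_integer_,
                        detection_range = unlist(x$detection_range %||% c(50, 140)),
                        source = x$source %||% "fitted")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Published whole-blood and plasma calibration measurements
#'
#' The packaged eight-sample parallel whole-blood/plasma dataset: for each
#' venous sample, the commercial-kit glucose, the mean color intensity
#' (triplicate) for whole blood and for plasma, their standard deviations,
#' and the chip-measured glucose obtained from each reference calibration
#' line.
#'
#' @param sample_type `"whole_blood"` or `"plasma"`.
#' @param reference Which glucose column to pair with the intensities:
#'   `"paper_chip"` (the chip's own reading, generated by the reference
#'   line) or `"commercial_kit"` (the enzymatic kit reference).
#' @return A `calibration_pairs` data frame of eight pairs.
#' @export
published_calibration_pairs <- function(sample_type = c("whole_blood", "plasma"),
                                        reference = c("paper_chip", "commercial_kit")) {
  sample_type <- match.arg(sample_type)
  reference <- match.arg(reference)
  df <- utils::read.csv(system.file("extdata", "published_calibration.csv",
                                    package = "glucopad"))
  int_col <- if (sample_type == "whole_blood") "intensity_whole_blood" else "intensity_plasma"
  glc_col <- if (reference == "commercial_kit") "glucose_kit"
             else if (sample_type == "whole_blood") "glucose_chip_whole_blood"
             else "glucose_chip_plasma"
  calibration_pairs(df[[int_col]], df[[glc_col]], replicate = df$sample)
}
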