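# ---- domain types: images, HSV ranges, masks, intensity scores ------------

#' Construct an 8-bit RGB image
#'
#' Images are stored as `height x width x 3` integer arrays in row/column
#' (y, x) order with channel values in `[0, 255]` (sRGB).
#'
#' @param pixels Numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]`. Values are rounded to integers.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_glc("invalid_image", "`pixels` must be a height x width x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop_glc("invalid_image", "image must be at least 1 x 1 pixel")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop_glc("invalid_image", "channel values must lie in [0, 255]")
  storage.mode(px) <- "integer"
  structure(px, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px (width x height), 8-bit sRGB\n",
              ncol(x), nrow(x)))
  invisible(x)
}

image_width <- function(img) ncol(img)
image_height <- function(img) nrow(img)

#' Read a chip photograph from PNG or JPEG
#'
#' Reads an 8-bit image file into an [rgb_image]. Grayscale images are
#' expanded to three identical channels; an alpha channel, if present, is
#' dropped with a warning (the readout pipeline ignores transparency).
#'
#' @param path Path to a PNG or JPEG file.
#' @return An [rgb_image].
#' @export
read_chip_image <- function(path) {
  if (!file.exists(path))
    stop_glc("io", sprintf("image file not found: %s", path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))  # grayscale
  if (dim(a)[3] > 3L) {
    warning("alpha channel dropped", call. = FALSE)
    a <- a[, , 1:3, drop = FALSE]
  }
  # EBImage stores (x, y, c) in [0,1]; transpose to (y, x, c) 0-255
  out <- array(0L, c(dim(a)[2], dim(a)[1], 3L))
  for (k in 1:3) out[, , k] <- t(a[, , k])
  rgb_image(out * 255)
}

#' Write an RGB image to PNG
#'
#' @param img An [rgb_image].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_chip_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Convert an RGB image to 8-bit HSV
#'
#' Standard max/min hexcone conversion in the 8-bit convention used
#' throughout the package: hue is computed in degrees, halved, and rounded
#' half-up to an integer in `[0, 179]` (half-degrees); saturation and value
#' are integers in `[0, 255]`. Achromatic pixels (max channel = min channel)
#' have S = 0 and H = 0; V is the max channel.
#'
#' @param img An [rgb_image].
#' @return An `hsv_image`: a `height x width x 3` integer array with
#'   channels H, S, V.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  hsv01 <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- round_half_up(hsv01[1, ] * 360 / 2) %% 180L
  s <- round_half_up(hsv01[2, ] * 255)
  v <- pmax(r, pmax(g, b))                 # V = max channel, exact
  out <- array(0L, d)
  out[, , 1] <- as.integer(h); out[, , 2] <- as.integer(s); out[, , 3] <- as.integer(v)
  structure(out, class = "hsv_image")
}

#' Construct an 8-bit HSV image from channel values
#'
#' Mostly useful for constructing test inputs; photographs enter the
#' pipeline through [rgb_to_hsv()].
#'
#' @param pixels Numeric array `c(height, width, 3)` with H in `[0, 179]`
#'   (half-degrees) and S, V in `[0, 255]`.
#' @return An `hsv_image`.
#' @export
hsv_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_glc("invalid_image", "`pixels` must be a height x width x 3 array")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px[, , 1]) > 179 ||
      max(px[, , 2:3]) > 255)
    stop_glc("invalid_image", "H must lie in [0, 179], S and V in [0, 255]")
  storage.mode(px) <- "integer"
  structure(px, class = "hsv_image")
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image> %d x %d px, H in [0,179] half-degrees, S/V in [0,255]\n",
              ncol(x), nrow(x)))
  invisible(x)
}

# round half up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Define an HSV color range
#'
#' A closed box in 8-bit HSV space. Hue wraparound colors (red) are
#' represented as a *list of two* ranges, never as `lower > upper`.
#'
#' @param lower,upper Length-3 integer vectors `(H, S, V)` with
#'   `H` in `[0, 179]`, `S`, `V` in `[0, 255]` and `lower <= upper`
#'   componentwise.
#' @param label Color name, e.g. `"blue"`.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(lower, upper, label = "unnamed") {
  lower <- as.integer(round(lower)); upper <- as.integer(round(upper))
  if (length(lower) != 3L || length(upper) != 3L)
    stop_glc("invalid_range", "lower and upper must be (H, S, V) triples")
  if (any(lower > upper))
    stop_glc("invalid_range",
             "lower must be componentwise <= upper (represent hue wraparound as two ranges)")
  lim <- c(179L, 255L, 255L)
  if (any(lower < 0L) || any(upper > lim))
    stop_glc("invalid_range", "components outside the 8-bit HSV domain")
  structure(list(lower = lower, upper = upper, label = label),
            class = "hsv_range")
}

#' @export
print.hsv_range <- function(x, ...) {
  cat(sprintf("<hsv_range> %s: [%s] - [%s]\n", x$label,
              paste(x$lower, collapse = ", "), paste(x$upper, collapse = ", ")))
  invisible(x)
}

#' Default HSV detection ranges
#'
#' The shipped segmentation defaults: blue `[90,50,50]`-`[130,255,255]` and
#' green `[35,50,50]`-`[85,255,255]` for the TMB blue-to-green reaction
#' color, and a hue-wraparound red pair (`[0,10]` and `[170,179]` in hue,
#' S, V at least 50) for the blood/sample zone.
#'
#' @return A named list: `blue` and `green` are single [hsv_range] objects;
#'   `red` is a list of two [hsv_range] objects (hue wraparound).
#' @export
default_hsv_ranges <- function() {
  list(
    blue  = hsv_range(c(90, 50, 50),  c(130, 255, 255), "blue"),
    green = hsv_range(c(35, 50, 50),  c(85, 255, 255),  "green"),
    red   = list(hsv_range(c(0, 50, 50),   c(10, 255, 255),  "red_low"),
                 hsv_range(c(170, 50, 50), c(179, 255, 255), "red_high"))
  )
}

#' Threshold an HSV image against a range
#'
#' A pixel is white (255) iff all three of its HSV components lie within the
#' closed range; otherwise black (0).
#'
#' @param hsv An `hsv_image` from [rgb_to_hsv()].
#' @param range An [hsv_range].
#' @return A `binary_mask`: an integer matrix of 0/255 with attribute
#'   `white_count`.
#' @export
in_range_mask <- function(hsv, range) {
  stopifnot(inherits(hsv, "hsv_image"), inherits(range, "hsv_range"))
  ok <- hsv[, , 1] >= range$lower[1] & hsv[, , 1] <= range$upper[1] &
        hsv[, , 2] >= range$lower[2] & hsv[, , 2] <= range$upper[2] &
        hsv[, , 3] >= range$lower[3] & hsv[, , 3] <= range$upper[3]
  new_binary_mask(ok)
}

#' Construct a binary mask from pixel values
#'
#' @param pixels Matrix containing only 0 and 255 (or a logical matrix).
#' @return A `binary_mask` with its `white_count` attribute set.
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) return(new_binary_mask(pixels))
  if (!all(pixels %in% c(0, 255)))
    stop_glc("invalid_image", "a binary mask may contain only 0 and 255")
  new_binary_mask(pixels == 255)
}

new_binary_mask <- function(logical_matrix) {
  m <- matrix(ifelse(logical_matrix, 255L, 0L), nrow = nrow(logical_matrix))
  structure(m, white_count = sum(logical_matrix), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d white\n",
              ncol(x), nrow(x), mask_white_count(x)))
  invisible(x)
}

#' White-pixel count of a binary mask
#' @param mask A `binary_mask`.
#' @return Integer count of 255-valued pixels.
#' @export
mask_white_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  attr(mask, "white_count")
}

#' Union of binary masks
#'
#' A pixel is white in the union iff it is white in any input mask. Used to
#' combine the blue and green masks during the TMB blue-to-green transition.
#'
#' @param masks A list of `binary_mask` objects with identical dimensions
#'   (a single mask is returned unchanged).
#' @return A `binary_mask`.
#' @export
union_mask <- function(masks) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L, all(vapply(masks, inherits, TRUE, "binary_mask")))
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d))
      stop_glc("dim_mismatch", "all masks must share dimensions")
  acc <- Reduce(`|`, lapply(masks, function(m) unclass(m) > 0L))
  new_binary_mask(acc)
}

#' Restrict a binary mask to a region of interest
#'
#' Pixels outside the ROI are set to 0.
#'
#' @param mask A `binary_mask`.
#' @param roi A [chip_roi] (or a logical matrix of the same dimensions).
#' @return A `binary_mask`.
#' @export
mask_in_roi <- function(mask, roi) {
  stopifnot(inherits(mask, "binary_mask"))
  sel <- if (inherits(roi, "chip_roi")) roi$mask else roi
  if (!identical(dim(sel), dim(mask)))
    stop_glc("dim_mismatch", "ROI and mask dimensions differ")
  new_binary_mask(unclass(mask) > 0L & sel)
}

#' Normalized color-intensity score
#'
#' The reaction intensity is quantified by counting white pixels in the
#' binary mask and normalizing by the reaction-zone area, on a 0-255 scale:
#' `score = 255 * white_count / roi_area`. The normalization makes the
#' score independent of image resolution; the raw `white_count` is always
#' retained alongside.
#'
#' @param mask A `binary_mask` (or a bare white-pixel count).
#' @param roi_area Area of the region of interest, in pixels; must be
#'   positive and at least `white_count`.
#' @return An `intensity_score`: list with `score` (0-255), `white_count`,
#'   `roi_area`.
#' @export
intensity_score <- function(mask, roi_area) {
  wc <- if (inherits(mask, "binary_mask")) mask_white_count(mask)
        else as.integer(mask)
  if (length(roi_area) != 1L || !is.finite(roi_area) || roi_area <= 0)
    stop_glc("degenerate_roi", "roi_area must be a positive pixel count")
  if (wc > roi_area)
    stop_glc("degenerate_roi", "white_count exceeds roi_area")
  structure(list(score = 255 * wc / roi_area,
                 white_count = wc,
                 roi_area = as.numeric(roi_area)),
            class = "intensity_score")
}

#' @export
print.intensity_score <- function(x, ...) {
  cat(sprintf("<intensity_score> %.2f / 255 (%d white px of %g ROI px)\n",
              x$score, x$white_count, x$roi_area))
  invisible(x)
}

# ---- error conditions -----------------------------------------------------

# typed conditions so callers (and the CLI) can map failures to exit codes
stop_glc <- function(class, message) {
  stop(structure(class = c(paste0("glucopad_error_", class), "glucopad_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
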