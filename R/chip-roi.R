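# ---- chip localisation, region labeling, reaction-zone extraction ---------

#' Construct a region of interest
#'
#' @param mask Logical matrix marking ROI pixels.
#' @return A `chip_roi`: list with `mask` (logical matrix), `area` (pixels)
#'   and `bbox` (`c(xmin, ymin, xmax, ymax)`, 1-based, x = column).
#' @keywords internal
new_roi <- function(mask) {
  area <- sum(mask)
  if (area == 0L) stop_glc("empty_roi", "ROI has zero area")
  idx <- which(mask, arr.ind = TRUE)
  bbox <- c(xmin = min(idx[, 2]), ymin = min(idx[, 1]),
            xmax = max(idx[, 2]), ymax = max(idx[, 1]))
  structure(list(mask = mask, area = area, bbox = bbox), class = "chip_roi")
}

#' @export
print.chip_roi <- function(x, ...) {
  cat(sprintf("<chip_roi> %d px, bbox x [%d, %d] y [%d, %d]\n", x$area,
              x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

# 8-connected component labeling of a logical matrix.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- matrix(0L, nrow(mask) * ncol(mask), 1)
  pos[fg] <- seq_along(fg)                      # linear index -> vertex id
  edges <- integer(0)
  # neighbour offsets covering each undirected 8-edge once: E, S, SE, SW
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  add_edges <- function(dr, dc) {
    ok <- row + dr >= 1L & row + dr <= nr & col + dc >= 1L & col + dc <= ncol(mask)
    nb <- (col[ok] + dc - 1L) * nr + (row[ok] + dr)
    hit <- pos[nb] > 0L
    rbind(pos[fg[ok][hit]], pos[nb[hit]])
  }
  e <- cbind(add_edges(0L, 1L), add_edges(1L, 0L), add_edges(1L, 1L), add_edges(-1L, 1L))
  g <- igraph::graph_from_edgelist(t(e), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Locate the chip (paper strip) in a photograph
#'
#' Thresholds image brightness (the HSV value channel) with Otsu's bimodal
#' histogram criterion and returns the largest above-threshold connected
#' component (8-connectivity), with interior holes filled; ties are broken
#' by leftmost, then topmost bounding box. The paper strip is assumed to be
#' the dominant bright object in the frame.
#'
#' @param img An [rgb_image] (or an `hsv_image`).
#' @param min_area_frac Minimum component area as a fraction of the frame;
#'   below this a `glucopad_error_chip_not_found` condition is signalled.
#' @return A `chip_roi` covering the chip.
#' @export
detect_chip <- function(img, min_area_frac = 0.01) {
  hsv <- if (inherits(img, "hsv_image")) img else rgb_to_hsv(img)
  v <- hsv[, , 3]
  rng <- range(v)
  if (diff(rng) < 8) {     # effectively uniform frame: no background/paper split
    if (mean(v) >= 128) return(new_roi(matrix(TRUE, nrow(v), ncol(v))))
    stop_glc("chip_not_found", "uniformly dark frame: no paper-white region")
  }
  thr <- 255 * EBImage::otsu(EBImage::Image(t(v) / 255), range = c(0, 1))
  bright <- v > thr
  if (!any(bright))
    stop_glc("chip_not_found", "no bright (paper-white) region in the image")
  lab <- label_components(bright)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {   # leftmost-then-topmost bounding box
    key <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      min(idx[, 2]) * (nrow(lab) + 1) + min(idx[, 1])
    }, numeric(1))
    best <- best[which.min(key)]
  }
  if (sizes[best] < min_area_frac * length(v))
    stop_glc("chip_not_found",
             sprintf("largest bright component (%d px) is below %.0f%% of the frame",
                     sizes[best], 100 * min_area_frac))
  comp <- lab == best
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(comp)))) > 0)
  new_roi(filled)
}

#' Label blood and reaction regions within the chip
#'
#' Within the chip ROI, pixels matching the red hue-wraparound range pair are
#' labeled `blood_zone`; pixels matching the reaction color (the blue and/or
#' green ranges, per `mask_mode`) are labeled `reaction_zone`; remaining chip
#' pixels are `chip` and everything else is `background`. Empty zones are
#' legal.
#'
#' @param hsv An `hsv_image`.
#' @param chip A `chip_roi` from [detect_chip()].
#' @param ranges HSV range set as returned by [default_hsv_ranges()].
#' @param mask_mode Which ranges define the reaction zone: `"union"`
#'   (blue or green, the default), `"blue"`, or `"green"`.
#' @return A `region_label_map`: integer matrix with levels background (0),
#'   chip (1), blood_zone (2), reaction_zone (3).
#' @export
label_regions <- function(hsv, chip, ranges = default_hsv_ranges(),
                          mask_mode = c("union", "blue", "green")) {
  stopifnot(inherits(hsv, "hsv_image"), inherits(chip, "chip_roi"))
  mask_mode <- match.arg(mask_mode)
  if (!identical(dim(chip$mask), dim(hsv)[1:2]))
    stop_glc("dim_mismatch", "chip ROI and image dimensions differ")
  red <- union_mask(lapply(ranges$red, in_range_mask, hsv = hsv))
  reaction <- switch(mask_mode,
    union = union_mask(list(in_range_mask(hsv, ranges$blue),
                            in_range_mask(hsv, ranges$green))),
    blue  = in_range_mask(hsv, ranges$blue),
    green = in_range_mask(hsv, ranges$green))
  lab <- matrix(0L, nrow(hsv), ncol(hsv))
  lab[chip$mask] <- 1L
  lab[chip$mask & unclass(red) > 0L] <- 2L
  lab[chip$mask & unclass(reaction) > 0L] <- 3L   # reaction wins over red
  structure(lab, class = "region_label_map",
            levels = c(background = 0L, chip = 1L, blood_zone = 2L,
                       reaction_zone = 3L),
            mask_mode = mask_mode)
}

#' @export
print.region_label_map <- function(x, ...) {
  n <- table(factor(unclass(x), levels = 0:3,
                    labels = names(attr(x, "levels"))))
  cat("<region_label_map>", paste(names(n), n, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract the reaction-zone region of interest
#'
#' Returns the largest 8-connected component of `reaction_zone` pixels —
#' the "region of greatest intensity" that is scored. Ties are broken by
#' larger mean saturation (when `hsv` is supplied), then by leftmost
#' bounding box.
#'
#' @param labels A `region_label_map` from [label_regions()].
#' @param hsv Optional `hsv_image`, used only for the saturation tie-break.
#' @return A `chip_roi` covering the reacted blob.
#' @export
extract_reaction_roi <- function(labels, hsv = NULL) {
  stopifnot(inherits(labels, "region_label_map"))
  rz <- unclass(labels) == 3L
  if (!any(rz))
    stop_glc("no_reaction",
             "no reaction-zone pixels detected; the photo is unusable (distinct from a zero score)")
  lab <- label_components(rz)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(hsv)) {
    sat <- vapply(best, function(k) mean(hsv[, , 2][lab == k]), numeric(1))
    best <- best[sat == max(sat)]
  }
  if (length(best) > 1L) {
    left <- vapply(best, function(k) min(which(lab == k, arr.ind = TRUE)[, 2]),
                   numeric(1))
    best <- best[which.min(left)]
  }
  new_roi(lab == best[1])
}

#' Derive an HSV range from user-selected sample pixels
#'
#' Semi-automatic calibration: the range is the componentwise min/max
#' envelope of the selected pixels, widened by a per-channel margin and
#' clipped to the HSV domain. Every input sample is guaranteed to fall
#' inside the returned range.
#'
#' @param samples Matrix or data frame of selected pixels, one row per pixel,
#'   columns `(H, S, V)`; or a list of length-3 vectors.
#' @param margin Nonnegative length-3 margin `(H, S, V)` added on each side.
#' @param label Name for the derived range.
#' @return An [hsv_range].
#' @export
derive_hsv_range <- function(samples, margin = c(0, 0, 0), label = "derived") {
  if (is.list(samples) && !is.data.frame(samples))
    samples <- do.call(rbind, samples)
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L)
    stop_glc("empty_samples", "at least one sample pixel is required")
  if (ncol(samples) != 3L)
    stop_glc("invalid_range", "samples must have three columns (H, S, V)")
  if (any(margin < 0) || length(margin) != 3L)
    stop_glc("invalid_range", "margin must be a nonnegative (H, S, V) triple")
  lim <- c(179, 255, 255)
  if (any(samples < 0) || any(sweep(samples, 2, lim) > 0))
    stop_glc("invalid_range", "sample pixels outside the 8-bit HSV domain")
  lo <- pmax(apply(samples, 2, min) - margin, 0)
  hi <- pmin(apply(samples, 2, max) + margin, lim)
  hsv_range(lo, hi, label)
}

#' Read HSV pixel samples from a delimited text file
#'
#' Expects a header with columns `h`, `s`, `v` (case-insensitive), comma- or
#' tab-delimited.
#'
#' @param path File path.
#' @return A numeric matrix with columns H, S, V.
#' @export
read_pixel_samples <- function(path) {
  df <- utils::read.delim(path, sep = guess_sep(path), header = TRUE)
  names(df) <- tolower(names(df))
  need <- c("h", "s", "v")
  if (!all(need %in% names(df)))
    stop_glc("schema", "sample file must have columns h, s, v")
  as.matrix(df[, need])
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Collect HSV samples at image coordinates
#'
#' Convenience for semi-automatic calibration from an image: looks up the
#' HSV triples at user-clicked points.
#'
#' @param hsv An `hsv_image`.
#' @param xy Matrix or data frame of 0-based `(x, y)` pixel coordinates,
#'   top-left origin.
#' @return A numeric matrix with columns H, S, V, one row per point.
#' @export
sample_pixels_at <- function(hsv, xy) {
  stopifnot(inherits(hsv, "hsv_image"))
  xy <- as.matrix(xy)
  col <- xy[, 1] + 1L; row <- xy[, 2] + 1L
  if (any(col < 1L | col > ncol(hsv) | row < 1L | row > nrow(hsv)))
    stop_glc("invalid_range", "sample coordinates outside the image")
  cbind(H = hsv[, , 1][cbind(row, col)],
        S = hsv[, , 2][cbind(row, col)],
        V = hsv[, , 3][cbind(row, col)])
}
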