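# ---- synthetic chip renders with exact ground truth -----------------------

#' Chip geometry
#'
#' Physical layout of the paper chip, in mm: a circular sample-collection
#' zone, a straight transport channel, and a circular analysis zone with an
#' optional pointed (tangent-cone) tip that concentrates the flow. The
#' default is the refined design (4 mm analysis zone, 2 mm channel); the
#' original wider design (3 mm channel) is selectable.
#'
#' @param sample_zone_diameter Sample zone diameter, mm (default 5).
#' @param channel_length Channel length, mm (default 10).
#' @param channel_width Channel width, mm (default 2).
#' @param analysis_zone_diameter Analysis zone diameter, mm (default 4).
#' @param pointed_tip Whether the analysis zone ends in a pointed tip.
#' @param tip_length Axial extent of the tip beyond the analysis disc, mm.
#' @param margin Paper margin around the features, mm.
#' @param pixels_per_mm Render scale (default 20, about a 10 cm smartphone
#'   shot); must be at least 4.
#' @return A `chip_layout`.
#' @export
chip_layout <- function(sample_zone_diameter = 5, channel_length = 10,
                        channel_width = 2, analysis_zone_diameter = 4,
                        pointed_tip = TRUE, tip_length = 2, margin = 2,
                        pixels_per_mm = 20) {
  dims <- c(sample_zone_diameter, channel_length, channel_width,
            analysis_zone_diameter, tip_length, margin)
  if (any(dims <= 0)) stop_glc("spec", "all chip dimensions must be positive")
  if (pixels_per_mm < 4) stop_glc("spec", "pixels_per_mm must be at least 4")
  l <- list(sample_zone_diameter = sample_zone_diameter,
            channel_length = channel_length, channel_width = channel_width,
            analysis_zone_diameter = analysis_zone_diameter,
            pointed_tip = pointed_tip,
            tip_length = if (pointed_tip) tip_length else 0,
            margin = margin, pixels_per_mm = pixels_per_mm)
  l$paper_length <- margin + sample_zone_diameter + channel_length +
    analysis_zone_diameter + l$tip_length + margin
  l$paper_width <- max(sample_zone_diameter, analysis_zone_diameter,
                       channel_width) + 2 * margin
  structure(l, class = "chip_layout")
}

# centers (mm, relative to the paper's top-left corner)
layout_centers <- function(l) {
  r_s <- l$sample_zone_diameter / 2
  r_z <- l$analysis_zone_diameter / 2
  cy <- l$paper_width / 2
  sample_cx <- l$margin + r_s
  zone_cx <- l$margin + l$sample_zone_diameter + l$channel_length + r_z
  list(sample = c(sample_cx, cy), zone = c(zone_cx, cy),
       apex = c(zone_cx + r_z + l$tip_length, cy),
       channel_x = c(sample_cx, zone_cx))
}

# membership of points (dx, dy in mm relative to the analysis-zone center)
# in the zone shape: disc of radius r plus, if pointed, the tangent-cone
# triangle toward the apex at distance d = r + tip_length
zone_membership <- function(dx, dy, layout) {
  r <- layout$analysis_zone_diameter / 2
  inside <- dx^2 + dy^2 <= r^2
  if (layout$pointed_tip) {
    d <- r + layout$tip_length
    theta <- acos(r / d)
    tx <- r * cos(theta); ty <- r * sin(theta)
    # triangle (tx, -ty), (tx, ty)... actually tangent points at (tx, +-ty),
    # apex (d, 0): half-planes x >= tangent chord, below/above tangent lines
    # tangent line through (tx, ty) and (d, 0): y = ty * (d - x) / (d - tx)
    tri <- dx >= tx & dx <= d & abs(dy) <= ty * (d - dx) / (d - tx)
    inside <- inside | tri
  }
  inside
}

#' Analytic area of the analysis zone
#'
#' Closed form for the disc plus tangent-cone tip:
#' `pi r^2 + r t - theta r^2` with `d = r + tip_length`,
#' `t = sqrt(d^2 - r^2)`, `theta = acos(r/d)`.
#'
#' @param layout A [chip_layout].
#' @return Area in mm^2.
#' @export
analysis_zone_area_mm2 <- function(layout) {
  r <- layout$analysis_zone_diameter / 2
  a <- pi * r^2
  if (layout$pointed_tip) {
    d <- r + layout$tip_length
    t <- sqrt(d^2 - r^2)
    a <- a + r * t - acos(r / d) * r^2
  }
  a
}

#' Rasterized analysis-zone area at a given scale
#'
#' Counts pixel centers falling inside the analysis zone when rasterized on
#' a pixel grid aligned with the zone center — the same rasterization the
#' renderer uses, and the nominal ROI area the measurement pipeline
#' normalizes by.
#'
#' @param layout A [chip_layout].
#' @param pixels_per_mm Scale; defaults to the layout's.
#' @return Pixel count.
#' @export
analysis_zone_area_px <- function(layout, pixels_per_mm = layout$pixels_per_mm) {
  p <- pixels_per_mm
  r <- layout$analysis_zone_diameter / 2
  ext <- r + layout$tip_length + 2 / p
  g <- seq(-ceiling(ext * p), ceiling(ext * p))  # pixel index offsets
  dx <- (rep(g, times = length(g)) - 0.5) / p
  dy <- (rep(g, each = length(g)) - 0.5) / p
  sum(zone_membership(dx, dy, layout))
}

#' Specification for one synthetic chip render
#'
#' The generator is explicitly model-based: the target glucose is mapped to
#' an intended color intensity by *inverting* a calibration model
#' (`intensity = (glucose - intercept) / slope`, default the built-in
#' whole-blood line), and the renderer colors exactly that fraction
#' (`intended_intensity / 255`) of analysis-zone pixels with an in-range
#' TMB blue, arranged as a V-shaped front advancing from the pointed tip.
#'
#' @param target_glucose Target concentration, mg/dL.
#' @param layout A [chip_layout].
#' @param generative_model `calibration_model` used for the inversion.
#' @param reacted_hue Hue of the reacted color, half-degrees (blue/green
#'   band; default 105).
#' @param reacted_sat,reacted_val Saturation and value of the fully reacted
#'   color, 0-255.
#' @param noise_sd Additive Gaussian pixel noise SD, 8-bit channel units.
#' @param illumination_gradient Relative span of a multiplicative
#'   left-to-right illumination ramp (0.1 = factors 0.9 to 1.0).
#' @param seed Integer seed; a fixed seed makes the render bit-identical.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(target_glucose, layout = chip_layout(),
                           generative_model = reference_models()$whole_blood,
                           reacted_hue = 105, reacted_sat = 200,
                           reacted_val = 210,
                           noise_sd = 0, illumination_gradient = 0,
                           seed = 1L) {
  stopifnot(inherits(layout, "chip_layout"),
            inherits(generative_model, "calibration_model"))
  intended <- (target_glucose - generative_model$intercept) / generative_model$slope
  if (!is.finite(intended) || intended < 0 || intended > 255)
    stop_glc("spec", sprintf(
      "target %g mg/dL inverts to intensity %.1f, outside [0, 255]",
      target_glucose, intended))
  if (reacted_hue < 35 || reacted_hue > 130)
    stop_glc("spec", "reacted hue must lie in the TMB blue/green band [35, 130]")
  if (noise_sd < 0 || illumination_gradient < 0 || illumination_gradient >= 1)
    stop_glc("spec", "invalid noise or illumination parameters")
  structure(list(layout = layout, target_glucose = target_glucose,
                 generative_model = generative_model,
                 intended_intensity = intended,
                 reacted_hue = reacted_hue, reacted_sat = reacted_sat,
                 reacted_val = reacted_val, noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

hsv8_to_rgb <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h * 2 / 360, s / 255, v / 255)))
}

#' Render a synthetic chip photograph
#'
#' Renders, at the layout's scale, a gray background, a white paper strip
#' with mild texture noise, a red blood/sample zone, a paper-white channel,
#' and an analysis zone in which exactly `round(fraction * N)` pixels
#' (fraction = intended intensity / 255) carry the reacted in-range color,
#' filled as a V-shaped front from the pointed tip. A multiplicative
#' illumination ramp and additive Gaussian noise are applied last.
#' Deterministic under a fixed seed.
#'
#' @param spec A [synthetic_spec].
#' @return List with `image` (an [rgb_image]) and `truth` (a
#'   `chip_ground_truth`: masks, polygons, target glucose, intended
#'   intensity, scale).
#' @export
render_chip <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  l <- spec$layout
  p <- l$pixels_per_mm
  border <- 1.5                              # background border, mm
  W <- round((l$paper_length + 2 * border) * p)
  H <- round((l$paper_width + 2 * border) * p)
  # pixel-center coordinates in mm, frame origin top-left
  xs <- (seq_len(W) - 0.5) / p
  ys <- (seq_len(H) - 0.5) / p
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  ctr <- layout_centers(l)
  ox <- border; oy <- border                 # paper origin in frame mm
  paper <- X >= ox & X <= ox + l$paper_length &
           Y >= oy & Y <= oy + l$paper_width
  r_s <- l$sample_zone_diameter / 2
  blood <- (X - (ox + ctr$sample[1]))^2 + (Y - (oy + ctr$sample[2]))^2 <= r_s^2
  channel <- X >= ox + ctr$channel_x[1] & X <= ox + ctr$channel_x[2] &
             abs(Y - (oy + ctr$sample[2])) <= l$channel_width / 2
  zone <- zone_membership(X - (ox + ctr$zone[1]), Y - (oy + ctr$zone[2]), l)

  set.seed(spec$seed)
  img <- array(70, c(H, W, 3))                       # background gray
  paper_col <- 250
  for (k in 1:3) {
    ch <- img[, , k]
    ch[paper] <- paper_col
    img[, , k] <- ch
  }
  # mild paper texture (achromatic, applied equally to all channels)
  tex <- matrix(stats::rnorm(H * W, 0, 1.5), H, W)
  for (k in 1:3) img[, , k][paper] <- img[, , k][paper] + tex[paper]
  blood_rgb <- c(200, 40, 50)
  for (k in 1:3) img[, , k][blood] <- blood_rgb[k]

  # reacted fill: rank zone pixels by a V-front metric from the tip apex
  n_zone <- sum(zone)
  frac <- spec$intended_intensity / 255
  n_react <- round_half_up(frac * n_zone)
  react <- matrix(FALSE, H, W)
  if (n_react > 0) {
    idx <- which(zone)
    dv <- (ox + ctr$apex[1]) - X[idx] + 0.7 * abs(Y[idx] - (oy + ctr$apex[2]))
    ord <- order(dv, idx)                    # deterministic tie-break
    react[idx[ord[seq_len(n_react)]]] <- TRUE
  }
  rc <- hsv8_to_rgb(spec$reacted_hue, spec$reacted_sat, spec$reacted_val)
  for (k in 1:3) img[, , k][react] <- rc[k]

  # illumination ramp then sensor noise
  if (spec$illumination_gradient > 0) {
    g <- spec$illumination_gradient
    ramp <- matrix(seq(1 - g, 1, length.out = W), H, W, byrow = TRUE)
    for (k in 1:3) img[, , k] <- img[, , k] * ramp
  }
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
  img <- pmin(pmax(img, 0), 255)

  truth <- structure(list(
    target_glucose = spec$target_glucose,
    intended_intensity = spec$intended_intensity,
    pixels_per_mm = p,
    paper_mask = paper, blood_mask = blood, reaction_zone_mask = zone,
    reacted_mask = react,
    zone_area_px = n_zone, reacted_px = n_react,
    blood_polygon = mask_hull_polygon(blood),
    reaction_polygon = mask_hull_polygon(zone),
    paper_polygon = mask_hull_polygon(paper)),
    class = "chip_ground_truth")
  list(image = rgb_image(img), truth = truth)
}

# convex-hull outline of a mask, as 0-based (x, y) pixel coordinates
mask_hull_polygon <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  pts[grDevices::chull(pts), , drop = FALSE]
}

#' Write ground truth as a JSON sidecar
#'
#' Polygons are 0-based pixel coordinate lists; masks are not serialized.
#'
#' @param truth A `chip_ground_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  poly <- function(p) lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
  jsonlite::write_json(list(
    target_glucose = truth$target_glucose,
    intended_intensity = truth$intended_intensity,
    pixels_per_mm = truth$pixels_per_mm,
    zone_area_px = truth$zone_area_px,
    reacted_px = truth$reacted_px,
    blood_polygon = poly(truth$blood_polygon),
    reaction_polygon = poly(truth$reaction_polygon),
    paper_polygon = poly(truth$paper_polygon)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a ladder of chips across a concentration series
#'
#' One render per concentration; each rung's seed is derived
#' deterministically from the template seed and the rung index, so the
#' whole ladder is reproducible from one seed.
#'
#' @param concentrations Glucose concentrations, mg/dL (each must invert to
#'   an intensity in `[0, 255]`).
#' @param spec_template A [synthetic_spec] whose non-concentration fields
#'   (layout, model, noise, illumination, seed) are reused.
#' @return A list of `list(image, truth)` pairs, one per concentration.
#' @export
make_calibration_ladder <- function(concentrations, spec_template) {
  stopifnot(inherits(spec_template, "synthetic_spec"))
  lapply(seq_along(concentrations), function(i) {
    s <- spec_template
    s$target_glucose <- concentrations[i]
    s$intended_intensity <- (concentrations[i] - s$generative_model$intercept) /
      s$generative_model$slope
    if (s$intended_intensity < 0 || s$intended_intensity > 255)
      stop_glc("spec", sprintf("concentration %g mg/dL not invertible to [0, 255]",
                               concentrations[i]))
    s$seed <- spec_template$seed + i
    render_chip(s)
  })
}
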