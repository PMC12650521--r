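make_render <- function(glucose = 90, seed = 3, noise_sd = 5, illum = 0.1, ...) {
  render_chip(synthetic_spec(glucose, seed = seed, noise_sd = noise_sd,
                             illumination_gradient = illum, ...))
}

test_that("detect_chip recovers the paper strip from a synthetic render", {
  r <- make_render()
  roi <- detect_chip(r$image)
  jac <- sum(roi$mask & r$truth$paper_mask) / sum(roi$mask | r$truth$paper_mask)
  expect_gte(jac, 0.9)
})

test_that("detect_chip handles degenerate frames", {
  black <- uniform_rgb(0, 0, 0, 20, 20)
  expect_error(detect_chip(black), class = "glucopad_error_chip_not_found")
  # a frame that is entirely chip (uniform paper white)
  white <- uniform_rgb(250, 250, 250, 15, 25)
  roi <- detect_chip(white)
  expect_equal(roi$area, 15L * 25L)
})

test_that("label_regions places blood and reaction centroids inside the true zones", {
  r <- make_render()
  hsv <- rgb_to_hsv(r$image)
  chip <- detect_chip(hsv)
  lab <- unclass(label_regions(hsv, chip))
  blood <- which(lab == 2L, arr.ind = TRUE)
  react <- which(lab == 3L, arr.ind = TRUE)
  cb <- round(colMeans(blood)); cr <- round(colMeans(react))
  expect_true(r$truth$blood_mask[cb[1], cb[2]])
  expect_true(r$truth$reaction_zone_mask[cr[1], cr[2]])
  # labeled zones are subsets of the chip ROI
  expect_true(all(chip$mask[lab == 2L]))
  expect_true(all(chip$mask[lab == 3L]))
})

test_that("label_regions on a uniform white chip finds empty zones; a fully blue chip is all reaction", {
  white <- uniform_rgb(250, 250, 250, 20, 30)
  chip <- detect_chip(white)
  lab <- unclass(label_regions(rgb_to_hsv(white), chip))
  expect_equal(sum(lab == 2L), 0L)
  expect_equal(sum(lab == 3L), 0L)
  blue <- uniform_rgb(40, 120, 220, 20, 30)   # vivid TMB-like blue
  chip2 <- detect_chip(blue)
  lab2 <- unclass(label_regions(rgb_to_hsv(blue), chip2))
  expect_equal(sum(lab2 == 3L), chip2$area)
})

test_that("extract_reaction_roi picks the largest connected component (vs BFS oracle)", {
  # two disjoint blobs, areas 100 and 40
  lab <- matrix(1L, 40, 60)
  lab[3:12, 3:12] <- 3L      # 100 px
  lab[25:32, 40:44] <- 3L    # 40 px
  lm <- structure(lab, class = "region_label_map",
                  levels = c(background = 0L, chip = 1L, blood_zone = 2L,
                             reaction_zone = 3L))
  roi <- extract_reaction_roi(lm)
  expect_equal(roi$area, 100L)
  expect_true(all(which(roi$mask, arr.ind = TRUE)[, 1] <= 12))

  # single blob is returned unchanged
  lab1 <- matrix(1L, 20, 20); lab1[5:9, 5:9] <- 3L
  lm1 <- structure(lab1, class = "region_label_map",
                   levels = attr(lm, "levels"))
  expect_equal(extract_reaction_roi(lm1)$area, 25L)

  # random blob fields match the flood-fill oracle maximum
  set.seed(33)
  for (rep in 1:5) {
    m <- matrix(stats::runif(30 * 30) < 0.4, 30, 30)
    labr <- matrix(1L, 30, 30); labr[m] <- 3L
    lmr <- structure(labr, class = "region_label_map",
                     levels = attr(lm, "levels"))
    sizes <- oracle_component_sizes(m)
    expect_equal(extract_reaction_roi(lmr)$area, max(sizes))
  }
})

test_that("an unreacted chip raises a no-reaction condition distinct from a zero score", {
  lab <- matrix(1L, 10, 10)
  lm <- structure(lab, class = "region_label_map",
                  levels = c(background = 0L, chip = 1L, blood_zone = 2L,
                             reaction_zone = 3L))
  expect_error(extract_reaction_roi(lm), class = "glucopad_error_no_reaction")
})

test_that("derive_hsv_range builds the min/max envelope and always contains its samples", {
  r <- derive_hsv_range(rbind(c(120, 200, 200)), margin = c(0, 0, 0))
  expect_equal(r$lower, c(120L, 200L, 200L))
  expect_equal(r$upper, c(120L, 200L, 200L))
  r2 <- derive_hsv_range(rbind(c(100, 60, 60), c(110, 80, 200)),
                         margin = c(5, 10, 10))
  expect_equal(r2$lower, c(95L, 50L, 50L))
  expect_equal(r2$upper, c(115L, 90L, 210L))
  expect_error(derive_hsv_range(matrix(numeric(0), 0, 3)),
               class = "glucopad_error_empty_samples")

  set.seed(55)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    samples <- cbind(sample(0:179, n, TRUE), sample(0:255, n, TRUE),
                     sample(0:255, n, TRUE))
    margin <- c(sample(0:30, 1), sample(0:60, 1), sample(0:60, 1))
    rng <- derive_hsv_range(samples, margin)
    # brute-force envelope
    expect_equal(rng$lower, pmax(apply(samples, 2, min) - margin, 0))
    expect_equal(rng$upper, pmin(apply(samples, 2, max) + margin, c(179, 255, 255)))
    # containment of every sample
    inside <- apply(samples, 1, function(px)
      all(px >= rng$lower) && all(px <= rng$upper))
    expect_true(all(inside))
  }
})

test_that("ROI extraction succeeds across the concentration ladder at the documented noise tolerance", {
  tmpl <- synthetic_spec(90, seed = 17, noise_sd = 5, illumination_gradient = 0.1)
  ladder <- make_calibration_ladder(seq(50, 140, by = 30), tmpl)
  for (r in ladder) {
    lab <- label_regions(rgb_to_hsv(r$image), detect_chip(r$image))
    roi <- extract_reaction_roi(lab)
    expect_lte(roi$area, sum(unclass(lab) == 3L))
    expect_gt(roi$area, 0)
  }
})
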