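test_that("rgb_to_hsv follows the 8-bit half-degree hexcone convention", {
  # pure primaries and an achromatic gray
  blue <- rgb_to_hsv(uniform_rgb(0, 0, 255))
  expect_equal(unname(blue[1, 1, ]), c(120L, 255L, 255L))
  green <- rgb_to_hsv(uniform_rgb(0, 255, 0))
  expect_equal(unname(green[1, 1, ]), c(60L, 255L, 255L))
  gray <- rgb_to_hsv(uniform_rgb(128, 128, 128))
  expect_equal(unname(gray[1, 1, ]), c(0L, 0L, 128L))
  # dimensions preserved, channels within domain
  set.seed(1)
  img <- rgb_image(array(sample(0:255, 12 * 9 * 3, TRUE), c(9, 12, 3)))
  hsv <- rgb_to_hsv(img)
  expect_identical(dim(hsv), dim(img))
  expect_true(all(hsv[, , 1] >= 0 & hsv[, , 1] <= 179))
  expect_true(all(hsv[, , 2:3] >= 0 & hsv[, , 2:3] <= 255))
})

test_that("invalid images are rejected", {
  expect_error(rgb_image(array(0, c(0, 4, 3))), class = "glucopad_error_invalid_image")
  expect_error(rgb_image(array(-1, c(2, 2, 3))), class = "glucopad_error_invalid_image")
  expect_error(rgb_image(matrix(0, 2, 2)), class = "glucopad_error_invalid_image")
  expect_error(hsv_image(array(200, c(2, 2, 3))), class = "glucopad_error_invalid_image")
  expect_error(binary_mask(matrix(7, 2, 2)), class = "glucopad_error_invalid_image")
})

test_that("in_range_mask matches the shipped defaults on uniform images and the brute-force oracle on random ones", {
  ranges <- default_hsv_ranges()
  pure_blue <- hsv_image(array(rep(c(120, 255, 255), each = 20), c(4, 5, 3)))
  m <- in_range_mask(pure_blue, ranges$blue)
  expect_equal(mask_white_count(m), 20L)
  expect_true(all(unclass(m) == 255L))
  pure_red <- hsv_image(array(rep(c(0, 255, 255), each = 20), c(4, 5, 3)))
  expect_equal(mask_white_count(in_range_mask(pure_red, ranges$blue)), 0L)

  set.seed(101)
  for (rep in 1:20) {
    img <- random_hsv_image(16, 16)
    rng <- derive_hsv_range(rbind(c(sample(0:150, 1), sample(0:200, 1), sample(0:200, 1))),
                            margin = c(25, 55, 55))
    m <- in_range_mask(img, rng)
    ref <- oracle_in_range(img, rng)
    expect_identical(unclass(m) == 255L, ref)
    expect_identical(mask_white_count(m), sum(ref))
  }
})

test_that("masks are binary and count-consistent for every generated mask", {
  set.seed(7)
  for (rep in 1:10) {
    img <- random_hsv_image(12, 12)
    m <- in_range_mask(img, default_hsv_ranges()$green)
    expect_true(all(unclass(m) %in% c(0L, 255L)))
    expect_identical(mask_white_count(m), sum(unclass(m) == 255L))
  }
})

test_that("union_mask is idempotent, absorbs all-white, and matches the logical-or loop", {
  set.seed(11)
  a <- random_mask(8, 8)
  expect_identical(unclass(union_mask(list(a, a))), unclass(a))
  white <- binary_mask(matrix(255, 8, 8))
  black <- binary_mask(matrix(0, 8, 8))
  expect_equal(mask_white_count(union_mask(list(white, black))), 64L)
  for (rep in 1:10) {
    m1 <- random_mask(9, 7); m2 <- random_mask(9, 7)
    expect_equal(mask_white_count(union_mask(list(m1, m2))),
                 oracle_union_count(list(m1, m2)))
  }
  expect_error(union_mask(list(a, random_mask(5, 5))),
               class = "glucopad_error_dim_mismatch")
})

test_that("intensity_score is the normalized white fraction on a 0-255 scale", {
  expect_equal(intensity_score(100L, 100)$score, 255)
  expect_equal(intensity_score(0L, 500)$score, 0)
  expect_equal(intensity_score(50L, 100)$score, 127.5)
  expect_error(intensity_score(10L, 0), class = "glucopad_error_degenerate_roi")
  expect_error(intensity_score(10L, 5), class = "glucopad_error_degenerate_roi")
  # strictly monotone in white_count at fixed roi_area
  scores <- vapply(0:60, function(w) intensity_score(w, 60)$score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("hue and saturation are invariant under multiplicative brightness scaling (vivid pixels, +-1 quantization)", {
  set.seed(202)
  for (rep in 1:300) {
    v <- runif(1, 200, 255); s8 <- runif(1, 120, 255); hdeg <- runif(1, 0, 360)
    base <- grDevices::col2rgb(grDevices::hsv(hdeg / 360, s8 / 255, v / 255))[, 1]
    fac <- runif(1, 0.6, 1)
    a <- rgb_to_hsv(uniform_rgb(base[1], base[2], base[3], 1, 1))[1, 1, ]
    sc <- round(fac * base)
    b <- rgb_to_hsv(uniform_rgb(sc[1], sc[2], sc[3], 1, 1))[1, 1, ]
    dh <- abs(a[1] - b[1]); dh <- min(dh, 180 - dh)   # circular hue distance
    expect_lte(dh, 1)
    expect_lte(abs(a[2] - b[2]), 1)
    # V scales by the factor (up to channel rounding)
    expect_lt(abs(b[3] - fac * a[3]), 1)
  }
})

test_that("PNG round trip preserves the image exactly", {
  set.seed(5)
  img <- rgb_image(array(sample(0:255, 10 * 8 * 3, TRUE), c(8, 10, 3)))
  path <- withr::local_tempfile(fileext = ".png")
  write_chip_image(img, path)
  back <- read_chip_image(path)
  expect_identical(unclass(back), unclass(img))
})
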