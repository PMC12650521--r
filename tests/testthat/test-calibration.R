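test_that("collinear pairs are fitted exactly", {
  pairs <- calibration_pairs(c(10, 20, 30, 40), 2 * c(10, 20, 30, 40) + 1)
  m <- fit_calibration(pairs)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$rmse, 0, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_calibration(calibration_pairs(100, 90)),
               class = "glucopad_error_singular_fit")
  expect_error(fit_calibration(calibration_pairs(c(100, 100), c(80, 90))),
               class = "glucopad_error_singular_fit")
})

test_that("the published whole-blood and plasma pairs recover the reference coefficients", {
  wb <- fit_calibration(published_calibration_pairs("whole_blood"), "whole_blood")
  expect_equal(wb$slope, 1.4686, tolerance = 0.005 / 1.4686)
  expect_lt(abs(wb$intercept - (-157.16)), 1)
  pl <- fit_calibration(published_calibration_pairs("plasma"), "plasma")
  expect_equal(pl$slope, 1.5278, tolerance = 0.005 / 1.5278)
  expect_lt(abs(pl$intercept - (-194.35)), 1)
})

test_that("OLS matches the closed-form normal-equations oracle to 1e-9 relative", {
  set.seed(99)
  for (rep in 1:10) {
    x <- runif(10, 100, 250)
    y <- 1.5 * x - 150 + rnorm(10, 0, 8)
    m <- fit_calibration(calibration_pairs(x, pmax(y, 1)))
    ref <- oracle_ols(x, pmax(y, 1))
    expect_equal(m$slope, unname(ref["slope"]), tolerance = 1e-9)
    expect_equal(m$intercept, unname(ref["intercept"]), tolerance = 1e-9)
    # OLS property: zero mean residual on training pairs
    res <- pmax(y, 1) - (m$slope * x + m$intercept)
    expect_lt(abs(mean(res)), 1e-9)
  }
})

test_that("predict_glucose reproduces the published worked examples to one decimal", {
  ref <- reference_models()
  expect_equal(predict_glucose(ref$whole_blood, 140.3)$glucose_mg_dl, 48.9)
  expect_equal(predict_glucose(ref$plasma, 193.0)$glucose_mg_dl, 100.5)
  # the root of the line maps to 0.0, flagged out of range, never clamped
  root <- -ref$whole_blood$intercept / ref$whole_blood$slope
  p <- predict_glucose(ref$whole_blood, root)
  expect_equal(p$glucose_mg_dl, 0)
  expect_false(p$in_detection_range)
  # negative predictions pass through flagged
  neg <- predict_glucose(ref$whole_blood, 50)
  expect_lt(neg$glucose_mg_dl, 0)
  expect_false(neg$in_detection_range)
})

test_that("reference models carry the published coefficients and detection range", {
  ref <- reference_models()
  expect_equal(ref$whole_blood$slope, 1.4686)
  expect_equal(ref$whole_blood$intercept, -157.16)
  expect_equal(ref$plasma$slope, 1.5278)
  expect_equal(ref$plasma$intercept, -194.35)
  expect_equal(ref$plasma$slope - ref$whole_blood$slope, 0.0592)
  expect_equal(ref$whole_blood$detection_range, c(50, 140))
  expect_identical(ref$whole_blood$source, "reference")
})

test_that("reference lines are parallel with a constant negative whole-blood offset", {
  ref <- reference_models()
  cmp <- compare_models(ref$whole_blood, ref$plasma)
  expect_lt(abs(cmp$slope_difference), 0.06)
  # a near-constant vertical offset separates the lines: at matched glucose
  # the plasma model demands the higher color intensity, i.e. the
  # whole-blood line sits above it on the glucose axis
  for (i in c(160, 180, 200))
    expect_gt(ref$whole_blood$slope * i + ref$whole_blood$intercept,
              ref$plasma$slope * i + ref$plasma$intercept)
  expect_gt(cmp$mean_offset, 0)
})

test_that("evaluate_model computes RMSE/R2 as the residual loop does", {
  pairs <- calibration_pairs(c(10, 20, 30), 2 * c(10, 20, 30) + 1)
  m <- fit_calibration(pairs)
  ev <- evaluate_model(m, pairs)
  expect_equal(ev$rmse, 0, tolerance = 1e-10)
  # zero glucose variance -> R2 undefined (reported NA)
  const <- calibration_pairs(c(10, 20, 30), c(90, 90, 90))
  expect_true(is.na(evaluate_model(m, const)$r_squared))
  set.seed(12)
  x <- runif(8, 120, 220); y <- runif(8, 40, 140)
  rp <- calibration_pairs(x, y)
  ev2 <- evaluate_model(m, rp)
  res <- y - (m$slope * x + m$intercept)
  expect_equal(ev2$rmse, sqrt(sum(res^2) / 8), tolerance = 1e-9)
  expect_equal(ev2$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-9)
})

test_that("compare_models: identity gives (0, 0); an intercept shift gives (0, shift)", {
  m <- reference_models()$whole_blood
  self <- compare_models(m, m)
  expect_equal(self$slope_difference, 0)
  expect_equal(self$mean_offset, 0)
  shifted <- m; shifted$intercept <- m$intercept + 10
  cmp <- compare_models(shifted, m)
  expect_equal(cmp$slope_difference, 0)
  expect_equal(cmp$mean_offset, 10)
})

test_that("pairs and models round-trip through their text formats", {
  pairs <- published_calibration_pairs("whole_blood")
  f <- tempfile(fileext = ".csv")
  write_calibration_pairs(pairs, f)
  back <- read_calibration_pairs(f)
  expect_equal(back$intensity, pairs$intensity)
  expect_equal(back$glucose_mg_dl, pairs$glucose_mg_dl)

  m <- fit_calibration(pairs, "whole_blood")
  mf <- tempfile(fileext = ".yml")
  write_calibration_model(m, mf)
  m2 <- read_calibration_model(mf)
  expect_equal(m2$slope, m$slope, tolerance = 1e-12)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_identical(m2$sample_type, m$sample_type)
  expect_equal(m2$detection_range, m$detection_range)
  unlink(c(f, mf))
})
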