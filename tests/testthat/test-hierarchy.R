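grid <- seq(340, 1060, by = 1)

test_that("alpha is the 675/645 band difference over the 660 band", {
  n <- make_nspec(grid, band_values(grid, list(`645` = 0.8, `660` = 1.0,
                                               `675` = 0.9)))
  expect_equal(compute_alpha(n), 0.1)
  # symmetric numerator
  n2 <- make_nspec(grid, band_values(grid, list(`645` = 0.7, `660` = 0.9,
                                                `675` = 0.7)))
  expect_equal(compute_alpha(n2), 0)
  # zero 660 band is undefined
  n3 <- make_nspec(grid, band_values(grid, list(`660` = 0), fill = 0.4))
  expect_error(compute_alpha(n3), "660")
})

test_that("alpha is scale-invariant while beta scales with the spectrum", {
  set.seed(41)
  for (k in 1:20) {
    v <- runif(length(grid), 0.1, 2)
    n <- make_nspec(grid, v)
    scaled <- make_nspec(grid, 3 * v)
    expect_equal(compute_alpha(scaled), compute_alpha(n), tolerance = 1e-12)
    doubled <- make_nspec(grid, 2 * v)
    expect_equal(compute_beta(doubled), 2 * compute_beta(n), tolerance = 1e-12)
  }
})

test_that("beta is the 500-560 slope with the 60 nm divisor", {
  n <- make_nspec(grid, band_values(grid, list(`500` = 0.30, `560` = 0.42)))
  expect_equal(compute_beta(n), 0.002)
  flat <- make_nspec(grid, rep(0.8, length(grid)))
  expect_equal(compute_beta(flat), 0)
})

test_that("stage-1 routing honours the strict and round conventions", {
  p_strict <- default_model_params("strict")
  p_round <- default_model_params("round")
  expect_equal(classify_stage1(-0.0476, p_strict), "LOW")    # sample 1
  expect_equal(classify_stage1(0.04826, p_strict), "GE10")   # sample 8
  # borderline sample 10: below threshold strictly, meets it at 3 s.f.
  expect_equal(classify_stage1(0.01246, p_strict), "LOW")
  expect_equal(classify_stage1(0.01246, p_round), "GE10")
  expect_equal(classify_stage1(0.0125, p_strict), "LOW")     # not >
  expect_equal(classify_stage1(0.0125, p_round), "GE10")
})

test_that("stage-2 routing honours the strict and round conventions", {
  p_strict <- default_model_params("strict")
  p_round <- default_model_params("round")
  expect_equal(classify_stage2(0.00214, p_strict), "HIGH")     # sample 19
  expect_equal(classify_stage2(7.30125e-4, p_strict), "MEDIUM") # sample 8
  # borderline sample 20: rounds up to the threshold at 2 s.f.
  expect_equal(classify_stage2(0.00135, p_strict), "MEDIUM")
  expect_equal(classify_stage2(0.00135, p_round), "HIGH")
  expect_equal(classify_stage2(0.0014, p_strict), "MEDIUM")    # sample 18, not >
  expect_equal(classify_stage2(0.0014, p_round), "HIGH")
})

test_that("the quadratic calibration evaluates exactly", {
  low <- default_model_params()$low_model
  expect_equal(round(predict_quadratic(0.05157, low), 2), 6.61)  # sample 5
  expect_equal(predict_quadratic(0, low), 4.4615)
  # agreement with Horner-scheme evaluation to machine precision
  set.seed(8)
  x <- runif(50, 0, 0.3)
  horner <- (low$a2 * x + low$a1) * x + low$a0
  expect_equal(predict_quadratic(x, low), horner, tolerance = 1e-15)
})

test_that("predict_sample routes through the tree with a full trace", {
  p <- default_model_params()
  base <- list(`605` = 1)
  # low route: alpha -0.05, 492 nm feature at the sample-1 value
  n_low <- make_nspec(grid, band_values(grid, c(base, list(
    `645` = 1.05, `660` = 1.0, `675` = 1.0, `492` = 0.12161))))
  pr <- predict_sample(n_low, p)
  expect_s3_class(pr, "bili_prediction")
  expect_equal(pr$cohort, "LOW")
  expect_equal(round(pr$concentration_mgdl, 2), 8.86)
  expect_length(pr$trace, 1L)
  expect_equal(pr$features$i_ref_check, 1, tolerance = 1e-9)
  # medium route with a zero 468 nm feature: prediction is the intercept
  n_med <- make_nspec(grid, band_values(grid, c(base, list(
    `645` = 1.0, `660` = 1.0, `675` = 1.05,
    `500` = 0.5, `560` = 0.53, `468` = 0))))
  pr <- predict_sample(n_med, p)
  expect_equal(pr$cohort, "MEDIUM")
  expect_equal(pr$concentration_mgdl, p$medium_model$a0)
  expect_length(pr$trace, 2L)
  # high route: no calibration curve, concentration absent
  n_high <- make_nspec(grid, band_values(grid, c(base, list(
    `645` = 1.0, `660` = 1.0, `675` = 1.05,
    `500` = 0.5, `560` = 0.7))))
  pr <- predict_sample(n_high, p)
  expect_equal(pr$cohort, "HIGH")
  expect_true(is.na(pr$concentration_mgdl))
  expect_length(pr$trace, 2L)
  # a configured high-cohort curve is honoured
  p_high <- model_params(high_model = quadratic_model(0, 10, 15, 460))
  pr <- predict_sample(n_high, p_high)
  expect_false(is.na(pr$concentration_mgdl))
  # stage is enforced
  expect_error(predict_sample(make_nspec(grid, rep(0.5, length(grid)),
                                         stage = "minmax", ref = NA_real_)),
               "ref_renormalized")
})

test_that("cohort curves are recovered exactly from noiseless data", {
  # three non-collinear points: exact interpolation
  m <- fit_cohort_model(c(0, 1, 2), c(1, 2, 5), 492)
  expect_equal(predict_quadratic(c(0, 1, 2), m), c(1, 2, 5), tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # 20 noiseless points from the published low-cohort curve
  x <- seq(0.01, 0.25, length.out = 20)
  y <- -78.019 * x^2 + 45.675 * x + 4.4615
  m <- fit_cohort_model(x, y, 492)
  expect_equal(c(m$a2, m$a1, m$a0), c(-78.019, 45.675, 4.4615), tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # degenerate responses follow the documented convention
  mc <- fit_cohort_model(c(1, 2, 3, 4), c(2, 2, 2, 2), 492)
  expect_equal(mc$r_squared, 1)
  expect_error(fit_cohort_model(c(1, 1, 2), c(1, 2, 3), 492), "underdetermined")
})

test_that("quadratic coefficient error shrinks with sample size under noise", {
  err <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 0, 0.3)
    y <- -78.019 * x^2 + 45.675 * x + 4.4615 + rnorm(n, 0, 0.5)
    m <- fit_cohort_model(x, y, 492)
    sum(abs(c(m$a2, m$a1, m$a0) - c(-78.019, 45.675, 4.4615)))
  }
  e_small <- mean(vapply(1:20, function(s) err(12, s), numeric(1)))
  e_large <- mean(vapply(1:20, function(s) err(120, s), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("threshold calibration matches exhaustive search and handles ties", {
  expect_equal(calibrate_threshold(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)), 5)
  # order independence
  expect_equal(calibrate_threshold(c(1, 9, 2, 8), c(FALSE, TRUE, FALSE, TRUE)), 5)
  # perfectly separable data classifies its own training set exactly
  set.seed(13)
  for (k in 1:10) {
    lo <- runif(6, 0, 1); hi <- runif(6, 2, 3)
    th <- calibrate_threshold(c(lo, hi), rep(c(FALSE, TRUE), each = 6))
    expect_true(all((c(lo, hi) > th) == rep(c(FALSE, TRUE), each = 6)))
  }
  # brute-force oracle on small random labelled sets: the returned
  # threshold attains the best accuracy achievable by any midpoint split
  set.seed(14)
  for (k in 1:30) {
    n <- sample(4:12, 1)
    v <- round(runif(n, 0, 10), 2)
    lab <- runif(n) < 0.5
    if (all(lab) || !any(lab)) next
    u <- sort(unique(v))
    if (length(u) < 2) next
    mids <- (u[-length(u)] + u[-1]) / 2
    best_acc <- max(vapply(mids, function(t) mean((v > t) == lab), numeric(1)))
    th <- calibrate_threshold(v, lab)
    expect_equal(mean((v > th) == lab), best_acc)
  }
  expect_warning(th <- calibrate_threshold(c(2, 2, 2), c(TRUE, FALSE, TRUE)),
                 "non-separable")
  expect_equal(th, 2)
  expect_error(calibrate_threshold(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("the medium-curve audit exposes the constant published offset", {
  audit <- evaluate_medium_offset()
  expect_length(audit$residuals, 11L)
  expect_equal(unname(audit$residuals[c("8", "9")]), c(2.00, 2.00),
               tolerance = 0.01)
  expect_equal(audit$mean_residual, 2.0, tolerance = 0.05)
  expect_lt(sd(audit$residuals), 0.05)
  # shifting the intercept by the mean residual flattens the audit
  m <- default_model_params()$medium_model
  m_adj <- quadratic_model(m$a2, m$a1, m$a0 + audit$mean_residual, 468)
  audit2 <- evaluate_medium_offset(model = m_adj)
  expect_equal(unname(audit2$mean_residual), 0, tolerance = 1e-9)
  expect_true(all(abs(audit2$residuals) < 0.05))
})

test_that("clinical band labels split at 10 and 15 inclusive", {
  expect_equal(label_from_concentration(c(9.99, 10, 12, 15, 15.01)),
               c("LOW", "MEDIUM", "MEDIUM", "MEDIUM", "HIGH"))
})
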