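test_that("min-max normalization rescales to [0,1] with exact extrema", {
  s <- new_spectrum("a", 0, c(400, 401, 402), c(2, 4, 6))
  expect_equal(minmax_normalize(s)$norm_intensities, c(0, 0.5, 1))
  s <- new_spectrum("a", 0, c(400, 401, 402), c(10, 30, 20))
  expect_equal(minmax_normalize(s)$norm_intensities, c(0, 1, 0.5))
  expect_error(minmax_normalize(new_spectrum("a", 0, c(400, 401, 402), c(5, 5, 5))),
               "degenerate")
})

test_that("min-max normalization attains 0 and 1 and preserves ordering", {
  set.seed(21)
  for (k in 1:25) {
    s <- random_spectrum(n = 80)
    n <- minmax_normalize(s)
    expect_identical(min(n$norm_intensities), 0)
    expect_identical(max(n$norm_intensities), 1)
    expect_equal(order(n$norm_intensities), order(s$intensities))
    expect_equal(n$stage, "minmax")
  }
})

test_that("band averages are closed-interval arithmetic means", {
  n <- make_nspec(c(600, 605, 610), c(0.1, 0.2, 0.3), stage = "minmax")
  expect_equal(band_average(n, band_spec(605, 5)), 0.2)
  # constant value over the band
  n2 <- make_nspec(test_grid(), rep(0.37, length(test_grid())), stage = "minmax")
  expect_equal(band_average(n2, 480), 0.37)
  expect_error(band_average(n, band_spec(2000, 5)), "empty band")
  expect_error(band_spec(605, 0), "half_width")
})

test_that("band averages are bounded by the in-band extremes", {
  set.seed(5)
  grid <- test_grid()
  for (k in 1:20) {
    v <- runif(length(grid))
    n <- make_nspec(grid, v, stage = "minmax")
    ctr <- runif(1, 350, 1050)
    inside <- grid >= ctr - 5 & grid <= ctr + 5
    b <- band_average(n, ctr)
    expect_gte(b, min(v[inside]))
    expect_lte(b, max(v[inside]))
  }
})

test_that("reference renormalization divides by the 605 band average", {
  grid <- test_grid()
  v <- band_values(grid, list(`605` = 0.5), fill = 0.3)
  n <- make_nspec(grid, v, stage = "minmax", ref = NA_real_)
  r <- renormalize_to_reference(n, band_spec(605, 5))
  expect_equal(r$norm_intensities, v / 0.5)
  expect_equal(r$stage, "ref_renormalized")
  expect_equal(r$ref_wavelength_nm, 605)
  expect_equal(band_average(r, 605), 1, tolerance = 1e-9)
  # applying the renormalization twice with the same band is an identity
  r2 <- renormalize_to_reference(r, band_spec(605, 5))
  expect_equal(r2$norm_intensities, r$norm_intensities, tolerance = 1e-9)
  # a zero reference band is rejected
  vz <- band_values(grid, list(`700` = 0), fill = 0.3)
  nz <- make_nspec(grid, vz, stage = "minmax", ref = NA_real_)
  expect_error(renormalize_to_reference(nz, band_spec(700, 5)), "reference band")
})

test_that("renormalization preserves all intensity ratios", {
  set.seed(31)
  s <- random_spectrum(n = 300)
  n <- minmax_normalize(s)
  r <- renormalize_to_reference(n, band_spec(700, 5))
  pos <- n$norm_intensities > 0
  expect_equal(r$norm_intensities[pos][-1] / r$norm_intensities[pos][1],
               n$norm_intensities[pos][-1] / n$norm_intensities[pos][1])
})

test_that("alpha is unchanged by reference renormalization", {
  grid <- test_grid()
  v <- band_values(grid, list(`645` = 0.8, `660` = 1.0, `675` = 0.9,
                              `605` = 0.4), fill = 0.5)
  n <- make_nspec(grid, v, stage = "minmax", ref = NA_real_)
  r <- renormalize_to_reference(n)
  expect_equal(compute_alpha(n), compute_alpha(r), tolerance = 1e-12)
})

test_that("reference-band selection scores stability and prefers low ties", {
  grid <- test_grid()
  v <- runif(length(grid))
  n0 <- make_nspec(grid, v, stage = "minmax", ref = NA_real_)
  # identical spectra: every score zero, lowest candidate wins the tie
  sel <- select_reference_band(n0, n0, candidate_centers = c(700, 500, 605))
  expect_true(all(sel$scores == 0))
  expect_equal(sel$center_nm, 500)
  # offset everywhere except 600-610: only the 605 band is stable
  v15 <- v + 0.2 * !(grid >= 600 & grid <= 610)
  n15 <- make_nspec(grid, v15, stage = "minmax", ref = NA_real_)
  sel <- select_reference_band(n0, n15, candidate_centers = c(500, 605, 700))
  expect_equal(sel$center_nm, 605)
  expect_equal(unname(sel$scores["605"]), 0)
  expect_true(all(sel$scores[c("500", "700")] > 0))
  # singleton candidate list
  expect_equal(select_reference_band(n0, n15, candidate_centers = 605)$center_nm, 605)
  # grids must agree
  n_bad <- make_nspec(grid + 0.5, v, stage = "minmax", ref = NA_real_)
  expect_error(select_reference_band(n0, n_bad), "grid mismatch")
  # stage is enforced
  expect_error(select_reference_band(renormalize_to_reference(
    minmax_normalize(random_spectrum(50, seed = 1))), n0), "minmax")
})
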