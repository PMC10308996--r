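# Test helpers: construct spectra with prescribed band structure.

# normalized-spectrum object with given values on a grid (bypasses the
# minmax pipeline so band averages can be dictated exactly)
make_nspec <- function(wavelengths, values, stage = "ref_renormalized",
                       ref = if (stage == "ref_renormalized") 605 else NA_real_,
                       sample_id = "test", timepoint = 0) {
  structure(list(sample_id = sample_id, timepoint_min = timepoint,
                 wavelengths_nm = wavelengths, norm_intensities = values,
                 stage = stage, ref_wavelength_nm = ref),
            class = "blood_nspectrum")
}

# piecewise-constant values: `bands` is a named list center -> value on
# [center - 5, center + 5]; everything else `fill`
band_values <- function(wavelengths, bands, fill = 0.5) {
  v <- rep(fill, length(wavelengths))
  for (ctr in names(bands)) {
    c0 <- as.numeric(ctr)
    v[wavelengths >= c0 - 5 & wavelengths <= c0 + 5] <- bands[[ctr]]
  }
  v
}

# default 1 nm test grid covering the instrument range
test_grid <- function() seq(340, 1060, by = 1)

# random raw spectrum for property-style tests
random_spectrum <- function(n = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wl <- sort(stats::runif(n, 340, 1060))
  wl <- wl + seq_len(n) * 1e-9  # guarantee strict increase
  new_spectrum("rand", 0, wl, stats::runif(n, 0, 1000))
}
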