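#' Define a wavelength band
#'
#' A band is the closed interval `[center - half_width, center + half_width]`.
#' The default half-width of 5 nm gives the 10 nm window corresponding to the
#' FWHM of a typical LED, the band convention used throughout the model.
#'
#' @param center_nm Band center in nm.
#' @param half_width_nm Positive half-width in nm (default 5).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center_nm, half_width_nm = 5) {
  stopifnot(is.numeric(center_nm), length(center_nm) == 1L,
            is.numeric(half_width_nm), length(half_width_nm) == 1L)
  if (half_width_nm <= 0) stop("half_width_nm must be > 0", call. = FALSE)
  structure(list(center_nm = as.numeric(center_nm),
                 half_width_nm = as.numeric(half_width_nm)),
            class = "band_spec")
}

#' Min-max normalize a spectrum
#'
#' Rescales the intensity counts to `[0, 1]` over the full recorded range:
#' `I'(lambda) = (I(lambda) - Imin) / (Imax - Imin)`. Every sample is
#' normalized against its own extrema so spectra from different subjects
#' are comparable.
#'
#' @param spec A `blood_spectrum`.
#' @return A `blood_nspectrum` with `stage = "minmax"`; the normalized
#'   values attain 0 and 1 exactly.
#' @export
minmax_normalize <- function(spec) {
  stopifnot(inherits(spec, "blood_spectrum"))
  imin <- min(spec$intensities)
  imax <- max(spec$intensities)
  if (imax <= imin)
    stop("degenerate spectrum: constant intensity (Imax = Imin), min-max ",
         "normalization undefined", call. = FALSE)
  structure(
    list(sample_id = spec$sample_id, timepoint_min = spec$timepoint_min,
         wavelengths_nm = spec$wavelengths_nm,
         norm_intensities = (spec$intensities - imin) / (imax - imin),
         stage = "minmax", ref_wavelength_nm = NA_real_),
    class = "blood_nspectrum")
}

#' @export
print.blood_nspectrum <- function(x, ...) {
  cat(sprintf("<blood_nspectrum> sample %s @ %g min, stage=%s%s\n",
              x$sample_id, x$timepoint_min, x$stage,
              if (!is.na(x$ref_wavelength_nm))
                sprintf(" (ref %g nm)", x$ref_wavelength_nm) else ""))
  invisible(x)
}

#' Band-averaged normalized intensity
#'
#' Arithmetic mean of the normalized intensity over the grid points lying
#' in the closed band interval. No interpolation is performed: on a grid
#' coarser than the band, the single enclosed point is the average.
#'
#' @param nspec A `blood_nspectrum`.
#' @param band A [band_spec()], or a numeric center (with `half_width_nm`).
#' @param half_width_nm Half-width used when `band` is a bare center.
#' @return The band mean, a single number.
#' @export
band_average <- function(nspec, band, half_width_nm = 5) {
  stopifnot(inherits(nspec, "blood_nspectrum"))
  if (!inherits(band, "band_spec")) band <- band_spec(band, half_width_nm)
  lo <- band$center_nm - band$half_width_nm
  hi <- band$center_nm + band$half_width_nm
  inside <- nspec$wavelengths_nm >= lo & nspec$wavelengths_nm <= hi
  if (!any(inside))
    stop(sprintf(
      "empty band: no grid point in [%.6g, %.6g] nm (center %.6g); grid spans %.6g-%.6g nm",
      lo, hi, band$center_nm, min(nspec$wavelengths_nm), max(nspec$wavelengths_nm)),
      call. = FALSE)
  mean(nspec$norm_intensities[inside])
}

#' Renormalize a spectrum to its reference band
#'
#' Divides all normalized intensities by the band average at the reference
#' wavelength (default 605 nm), the photostable region where the 0 and
#' 15 min spectra coincide. After this self-referencing step the band
#' average at the reference equals 1. Ratios between any two wavelengths
#' are unchanged, so scale-invariant statistics (alpha) are unaffected,
#' while absolute-slope statistics (beta) acquire a common scale across
#' subjects.
#'
#' The operation is idempotent: applying it again with the same band
#' divides by 1.
#'
#' @param nspec A `blood_nspectrum` (typically at stage `minmax`).
#' @param ref Reference [band_spec()] (default 605 +/- 5 nm).
#' @return A `blood_nspectrum` with `stage = "ref_renormalized"`.
#' @export
renormalize_to_reference <- function(nspec, ref = band_spec(605, 5)) {
  stopifnot(inherits(nspec, "blood_nspectrum"))
  if (!inherits(ref, "band_spec")) ref <- band_spec(ref)
  # accepting an already-renormalized spectrum makes the operation
  # idempotent: its reference band average is 1, so dividing again is
  # the identity
  denom <- band_average(nspec, ref)
  if (!is.finite(denom) || denom <= 0)
    stop(sprintf("reference band average at %g nm is %.6g; must be > 0",
                 ref$center_nm, denom), call. = FALSE)
  out <- nspec
  out$norm_intensities <- nspec$norm_intensities / denom
  out$stage <- "ref_renormalized"
  out$ref_wavelength_nm <- ref$center_nm
  out
}

#' Select the photostable reference band from a 0/15 min pair
#'
#' Scores every candidate center by the mean absolute difference between
#' the two min-max-normalized spectra over the candidate's band; the most
#' stable (lowest-scoring) candidate is the reference wavelength. Ties are
#' broken toward the lower center.
#'
#' @param nspec_t0,nspec_t15 `blood_nspectrum`s at stage `minmax`, on the
#'   same wavelength grid.
#' @param candidate_centers Numeric vector of candidate centers in nm
#'   (default: 340-1050 nm in 5 nm steps).
#' @param half_width_nm Band half-width (default 5).
#' @return List with `center_nm` (chosen center) and `scores` (named
#'   numeric vector of per-candidate stability scores).
#' @export
select_reference_band <- function(nspec_t0, nspec_t15,
                                  candidate_centers = seq(340, 1050, by = 5),
                                  half_width_nm = 5) {
  stopifnot(inherits(nspec_t0, "blood_nspectrum"),
            inherits(nspec_t15, "blood_nspectrum"),
            length(candidate_centers) >= 1L)
  if (nspec_t0$stage != "minmax" || nspec_t15$stage != "minmax")
    stop("both spectra must be at stage minmax", call. = FALSE)
  if (length(nspec_t0$wavelengths_nm) != length(nspec_t15$wavelengths_nm) ||
      any(nspec_t0$wavelengths_nm != nspec_t15$wavelengths_nm))
    stop("grid mismatch: the two spectra are not on the same wavelength grid",
         call. = FALSE)
  wl <- nspec_t0$wavelengths_nm
  absdiff <- abs(nspec_t0$norm_intensities - nspec_t15$norm_intensities)
  scores <- vapply(candidate_centers, function(cc) {
    inside <- wl >= cc - half_width_nm & wl <= cc + half_width_nm
    if (!any(inside)) return(NA_real_)
    mean(absdiff[inside])
  }, numeric(1))
  names(scores) <- as.character(candidate_centers)
  ok <- which(!is.na(scores))
  if (length(ok) == 0L)
    stop("no candidate band overlaps the wavelength grid", call. = FALSE)
  # which.min on the ordered candidates already prefers the lower center on ties
  o <- ok[order(candidate_centers[ok])]
  best <- o[which.min(scores[o])]
  list(center_nm = candidate_centers[best], scores = scores)
}
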