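#' Construct a whole-blood transmission spectrum
#'
#' A `blood_spectrum` holds one raw transmission measurement: detector
#' intensity counts on a strictly increasing wavelength grid, together with
#' the sample identifier and the acquisition timepoint in minutes (the
#' protocol records each sample at 0 and 15 min).
#'
#' @param sample_id Character scalar naming the sample.
#' @param timepoint_min Non-negative number; minutes since first exposure,
#'   typically 0 or 15.
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths
#'   in nm.
#' @param intensities Numeric vector of non-negative detector counts, same
#'   length as `wavelengths_nm`.
#' @return An object of class `blood_spectrum`.
#' @export
new_spectrum <- function(sample_id, timepoint_min, wavelengths_nm, intensities) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  timepoint_min <- as.numeric(timepoint_min)
  if (length(timepoint_min) != 1L || is.na(timepoint_min) || timepoint_min < 0)
    stop("timepoint_min must be a single non-negative number", call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) != length(intensities))
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(wavelengths_nm) || anyNA(intensities))
    stop("wavelengths and intensities must not contain NA", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(
    list(sample_id = sample_id, timepoint_min = timepoint_min,
         wavelengths_nm = wavelengths_nm, intensities = intensities),
    class = "blood_spectrum")
}

#' @export
print.blood_spectrum <- function(x, ...) {
  cat(sprintf("<blood_spectrum> sample %s @ %g min: %d points, %.1f-%.1f nm\n",
              x$sample_id, x$timepoint_min, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses delimited text as exported by spectrometer acquisition software:
#' column 1 wavelength (nm), column 2 intensity (counts). The delimiter is
#' sniffed per line (tab, comma, semicolon or whitespace). Lines starting
#' with `#` and non-numeric header lines are skipped. Rows sharing a
#' wavelength (re-scans) are collapsed by averaging their intensities, and
#' the result is sorted by wavelength.
#'
#' @param path Path to the spectrum file.
#' @param sample_id Sample identifier to attach (not parsed from the file).
#' @param timepoint_min Acquisition timepoint in minutes to attach.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, sample_id, timepoint_min) {
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  wl <- numeric(0); it <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[\t,;[:space:]]+")[[1]]
    fields <- fields[fields != ""]
    if (length(fields) < 2L) next
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) next  # header or other non-numeric line
    if (vals[2] < 0)
      stop(sprintf("negative intensity on line %d of %s", i, path), call. = FALSE)
    wl <- c(wl, vals[1]); it <- c(it, vals[2])
  }
  if (length(wl) < 2L)
    stop("fewer than 2 valid data rows in ", path, call. = FALSE)
  # collapse duplicate wavelengths by averaging, then sort
  agg <- tapply(it, wl, mean)
  wls <- as.numeric(names(agg))
  o <- order(wls)
  new_spectrum(sample_id, timepoint_min, wls[o], as.numeric(agg)[o])
}

#' Write a spectrum as tab-delimited text
#'
#' Writes one header line followed by wavelength/intensity pairs at 6
#' decimal places, the dialect [read_spectrum()] reads back.
#'
#' @param spec A `blood_spectrum`.
#' @param path Destination file path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "blood_spectrum"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  writeLines("wavelength_nm\tintensity", con)
  writeLines(sprintf("%.6f\t%.6f", spec$wavelengths_nm, spec$intensities), con)
  invisible(path)
}

#' Read a labeled sample manifest
#'
#' The manifest is one delimited text file with columns `sample_id`,
#' `lab_total_bilirubin_mgdl`, `path_t0`, `path_t15`. Relative spectrum
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "lab_total_bilirubin_mgdl", "path_t0", "path_t15")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- !is.na(df$lab_total_bilirubin_mgdl) &
    (df$lab_total_bilirubin_mgdl <= 0 | df$lab_total_bilirubin_mgdl >= 50)
  if (any(bad))
    stop("lab_total_bilirubin_mgdl must be in (0, 50); offending sample(s): ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  base <- dirname(path)
  for (col in c("path_t0", "path_t15")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}

#' Load the packaged 20-sample test table
#'
#' Returns the published test-set table: for each of 20 samples the
#' laboratory total bilirubin, the alpha statistic, the beta statistic
#' (samples 7-20 only), the band-averaged normalized intensity at
#' 492 +/- 5 nm (low-cohort samples 1-6) or 468 +/- 5 nm (medium-cohort
#' samples 7-17), and the model-predicted concentration where a cohort
#' calibration curve exists (samples 1-17; the high cohort has none).
#'
#' @return A data.frame with columns `serial`, `lab_conc_mgdl`, `alpha`,
#'   `beta`, `i492`, `i468`, `predicted_mgdl`; absent entries are `NA`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "test_samples_table.tsv", package = "bilispec",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 20L)
  df
}
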