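#' Extract the feature vector from one sample's 0-min spectrum
#'
#' Runs the preprocessing chain and returns the statistics the hierarchy
#' consumes: alpha, beta, and the band features at the low (492 nm) and
#' medium (468 nm) regression wavelengths, plus the reference-band check
#' value (1 by construction after renormalization).
#'
#' @param spec A raw `blood_spectrum`.
#' @param params A [model_params()] supplying band conventions.
#' @param feature_stage Stage the regression features are read from.
#' @return List with `alpha`, `beta`, `i492`, `i468`, `i_ref_check`.
#' @export
extract_features <- function(spec, params = default_model_params(),
                             feature_stage = c("ref_renormalized", "minmax")) {
  feature_stage <- match.arg(feature_stage)
  nm <- minmax_normalize(spec)
  nr <- renormalize_to_reference(nm, band_spec(params$ref_center_nm,
                                               params$band_half_width_nm))
  fsrc <- if (feature_stage == "minmax") nm else nr
  hw <- params$band_half_width_nm
  list(alpha = compute_alpha(nr, hw),
       beta = compute_beta(nr, hw),
       i492 = band_average(fsrc, params$low_model$feature_band_center_nm, hw),
       i468 = band_average(fsrc, params$medium_model$feature_band_center_nm, hw),
       i_ref_check = band_average(nr, params$ref_center_nm, hw))
}

#' Train the hierarchical model from a labeled manifest
#'
#' For each manifest row the 0-min spectrum is preprocessed and its
#' features extracted; then
#' * the alpha threshold is calibrated to separate lab < 10 from
#'   lab >= 10 mg/dl,
#' * the beta threshold is calibrated within the >= 10 mg/dl samples to
#'   separate lab > 15 mg/dl,
#' * the low-cohort curve is fitted to (492 nm feature, lab) pairs of the
#'   < 10 mg/dl samples and the medium-cohort curve to (468 nm feature,
#'   lab) pairs of the 10-15 mg/dl samples.
#'
#' No high-cohort curve is fitted: the model mirrors the published
#' design, which leaves that cohort without a calibration curve.
#'
#' @param manifest Data.frame from [read_manifest()], or a path to one.
#' @param base_params Band conventions and comparison mode to carry over.
#' @param feature_stage Stage the regression features are read from.
#' @return A fitted [model_params()] with attribute `training` holding
#'   the per-sample feature table.
#' @export
train_model <- function(manifest, base_params = default_model_params(),
                        feature_stage = c("ref_renormalized", "minmax")) {
  feature_stage <- match.arg(feature_stage)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (anyNA(manifest$lab_total_bilirubin_mgdl))
    stop("training manifest requires a laboratory concentration for every sample",
         call. = FALSE)
  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    spec <- read_spectrum(manifest$path_t0[i], manifest$sample_id[i], 0)
    extract_features(spec, base_params, feature_stage)
  })
  tab <- data.frame(
    sample_id = manifest$sample_id,
    lab = manifest$lab_total_bilirubin_mgdl,
    alpha = vapply(feats, `[[`, numeric(1), "alpha"),
    beta = vapply(feats, `[[`, numeric(1), "beta"),
    i492 = vapply(feats, `[[`, numeric(1), "i492"),
    i468 = vapply(feats, `[[`, numeric(1), "i468"))
  tab$cohort <- label_from_concentration(tab$lab)
  for (coh in c("LOW", "MEDIUM")) {
    if (sum(tab$cohort == coh) < 3L)
      stop(sprintf("insufficient samples in cohort %s (%d; need >= 3) to fit its curve",
                   coh, sum(tab$cohort == coh)), call. = FALSE)
  }
  alpha_thr <- calibrate_threshold(tab$alpha, tab$lab >= 10)
  ge10 <- tab[tab$lab >= 10, ]
  beta_thr <- calibrate_threshold(ge10$beta, ge10$lab > 15)
  low <- tab[tab$cohort == "LOW", ]
  med <- tab[tab$cohort == "MEDIUM", ]
  fitted <- model_params(
    alpha_threshold = alpha_thr, beta_threshold = beta_thr,
    comparison_mode = base_params$comparison_mode,
    low_model = fit_cohort_model(low$i492, low$lab,
                                 base_params$low_model$feature_band_center_nm),
    medium_model = fit_cohort_model(med$i468, med$lab,
                                    base_params$medium_model$feature_band_center_nm),
    high_model = NULL,
    ref_center_nm = base_params$ref_center_nm,
    band_half_width_nm = base_params$band_half_width_nm)
  attr(fitted, "training") <- tab
  fitted
}
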