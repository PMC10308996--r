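#' Quadratic calibration curve for one cohort
#'
#' Maps the band-averaged normalized intensity `x` at the cohort's
#' characteristic wavelength to total bilirubin in mg/dl via
#' `y = a2 x^2 + a1 x + a0`.
#'
#' @param a2,a1,a0 Polynomial coefficients.
#' @param feature_band_center_nm Wavelength (nm) the feature is read at.
#' @param r_squared Coefficient of determination of the fit, or `NA`.
#' @return A `quadratic_model` list.
#' @export
quadratic_model <- function(a2, a1, a0, feature_band_center_nm, r_squared = NA_real_) {
  structure(list(a2 = as.numeric(a2), a1 = as.numeric(a1), a0 = as.numeric(a0),
                 feature_band_center_nm = as.numeric(feature_band_center_nm),
                 r_squared = as.numeric(r_squared)),
            class = "quadratic_model")
}

#' Evaluate a cohort calibration curve
#'
#' @param x Band-averaged normalized intensity (finite, >= 0).
#' @param model A [quadratic_model()].
#' @return Predicted concentration in mg/dl.
#' @export
predict_quadratic <- function(x, model) {
  stopifnot(inherits(model, "quadratic_model"), is.numeric(x))
  model$a2 * x^2 + model$a1 * x + model$a0
}

#' Model parameters for the hierarchical decision tree
#'
#' Bundles everything the predictor needs: the alpha and beta thresholds,
#' the threshold comparison convention, the per-cohort quadratic curves,
#' and the band conventions. The defaults are the published model: alpha
#' threshold 0.0125, beta threshold 0.0014, low-cohort curve
#' `y = -78.019 x^2 + 45.675 x + 4.4615` read at 492 nm (R^2 0.88),
#' medium-cohort curve `y = -79.709 x^2 + 88.443 x + 7.4801` read at
#' 468 nm (R^2 0.92), reference band 605 +/- 5 nm. No high-cohort curve
#' is shipped (that cohort had too few participants to fit one).
#'
#' `comparison_mode` governs how a statistic meets its threshold:
#' * `"strict"` - branch to the upper cohort iff statistic > threshold;
#' * `"round"` - round the statistic first (alpha to 3 significant
#'   figures, beta to 2) and branch iff rounded value >= threshold,
#'   matching how borderline printed values behave in the published
#'   test table.
#'
#' @param alpha_threshold,beta_threshold Decision thresholds.
#' @param comparison_mode `"strict"` or `"round"`.
#' @param low_model,medium_model,high_model Cohort [quadratic_model()]s;
#'   `high_model` may be `NULL`.
#' @param ref_center_nm,band_half_width_nm Reference band convention.
#' @return A `model_params` list.
#' @export
model_params <- function(alpha_threshold = 0.0125,
                         beta_threshold = 0.0014,
                         comparison_mode = c("strict", "round"),
                         low_model = quadratic_model(-78.019, 45.675, 4.4615, 492, 0.88),
                         medium_model = quadratic_model(-79.709, 88.443, 7.4801, 468, 0.92),
                         high_model = NULL,
                         ref_center_nm = 605,
                         band_half_width_nm = 5) {
  comparison_mode <- match.arg(comparison_mode)
  # infinite thresholds are allowed: they express the degenerate
  # route-everything rules used when auditing the threshold tests
  stopifnot(is.numeric(alpha_threshold), !is.na(alpha_threshold),
            is.numeric(beta_threshold), !is.na(beta_threshold))
  for (m in list(low_model, medium_model)) stopifnot(inherits(m, "quadratic_model"))
  if (!is.null(high_model)) stopifnot(inherits(high_model, "quadratic_model"))
  chk <- c(low_model$feature_band_center_nm, medium_model$feature_band_center_nm,
           ref_center_nm)
  if (any(chk < 340 | chk > 1060))
    stop("band centers must lie within the 340-1060 nm recorded range", call. = FALSE)
  structure(list(alpha_threshold = alpha_threshold,
                 beta_threshold = beta_threshold,
                 comparison_mode = comparison_mode,
                 low_model = low_model, medium_model = medium_model,
                 high_model = high_model,
                 ref_center_nm = ref_center_nm,
                 band_half_width_nm = band_half_width_nm),
            class = "model_params")
}

#' Default (published) model parameters
#' @param comparison_mode Threshold convention, see [model_params()].
#' @return A `model_params` object with the published values.
#' @export
default_model_params <- function(comparison_mode = "strict") {
  model_params(comparison_mode = comparison_mode)
}

#' Cohort label from a laboratory concentration
#'
#' Clinical bands: LOW < 10 mg/dl, MEDIUM 10-15 mg/dl inclusive,
#' HIGH > 15 mg/dl.
#'
#' @param conc_mgdl Concentration(s) in mg/dl.
#' @return Character vector in `{"LOW","MEDIUM","HIGH"}`.
#' @export
label_from_concentration <- function(conc_mgdl) {
  ifelse(conc_mgdl < 10, "LOW", ifelse(conc_mgdl <= 15, "MEDIUM", "HIGH"))
}

#' Alpha statistic: differential slope around the deoxyhemoglobin band
#'
#' `alpha = (Ibar[675] - Ibar[645]) / Ibar[660]` where `Ibar` is the
#' 10 nm band average of the reference-renormalized intensity. The
#' statistic compares the slope into and out of the 660 nm region and is
#' invariant under any positive rescaling of the spectrum.
#'
#' @param nspec A `blood_nspectrum` (stage `ref_renormalized` for the
#'   canonical pipeline; any stage is accepted since alpha is
#'   scale-invariant).
#' @param half_width_nm Band half-width (default 5).
#' @return The alpha value.
#' @export
compute_alpha <- function(nspec, half_width_nm = 5) {
  i645 <- band_average(nspec, 645, half_width_nm)
  i660 <- band_average(nspec, 660, half_width_nm)
  i675 <- band_average(nspec, 675, half_width_nm)
  if (i660 == 0)
    stop("alpha undefined: band average at 660 nm is zero", call. = FALSE)
  (i675 - i645) / i660
}

#' Beta statistic: slope across the methemoglobin band
#'
#' `beta = (Ibar[560] - Ibar[500]) / 60`, the slope of the
#' reference-renormalized intensity over the 500-560 nm range (divisor
#' fixed at the 60 nm span). Unlike alpha, beta scales linearly with the
#' spectrum, which is why the reference renormalization stage matters.
#'
#' @inheritParams compute_alpha
#' @return The beta value.
#' @export
compute_beta <- function(nspec, half_width_nm = 5) {
  i500 <- band_average(nspec, 500, half_width_nm)
  i560 <- band_average(nspec, 560, half_width_nm)
  (i560 - i500) / 60
}

# threshold comparison under the two conventions
.meets_threshold <- function(value, threshold, mode, sig_digits) {
  if (mode == "strict") return(value > threshold)
  signif(value, sig_digits) >= threshold - 1e-12
}

#' First-stage routing on alpha
#'
#' Routes a sample to the `LOW` (< 10 mg/dl) branch or the `GE10`
#' (>= 10 mg/dl) branch by comparing alpha with its threshold. In round
#' mode alpha is rounded to 3 significant figures and compared with `>=`.
#'
#' @param alpha Finite alpha value.
#' @param params A [model_params()].
#' @return `"LOW"` or `"GE10"`.
#' @export
classify_stage1 <- function(alpha, params = default_model_params()) {
  stopifnot(is.finite(alpha))
  if (.meets_threshold(alpha, params$alpha_threshold, params$comparison_mode, 3L))
    "GE10" else "LOW"
}

#' Second-stage routing on beta
#'
#' Splits the >= 10 mg/dl branch into `MEDIUM` (10-15 mg/dl) and `HIGH`
#' (> 15 mg/dl). In round mode beta is rounded to 2 significant figures
#' and compared with `>=`.
#'
#' @param beta Finite beta value.
#' @param params A [model_params()].
#' @return `"MEDIUM"` or `"HIGH"`.
#' @export
classify_stage2 <- function(beta, params = default_model_params()) {
  stopifnot(is.finite(beta))
  if (.meets_threshold(beta, params$beta_threshold, params$comparison_mode, 2L))
    "HIGH" else "MEDIUM"
}

#' Route one spectrum through the hierarchical decision tree
#'
#' Computes alpha on the reference-renormalized spectrum; if it falls on
#' the low side of the threshold the low-cohort curve is evaluated at the
#' 492 nm band feature, otherwise beta decides between the medium branch
#' (468 nm feature through the medium curve) and the high branch (no
#' concentration unless a high-cohort curve is configured). Every
#' threshold comparison is recorded in the decision trace.
#'
#' @param nspec A `blood_nspectrum` at stage `ref_renormalized`.
#' @param params A [model_params()].
#' @param feature_nspec Optional `blood_nspectrum` to read the regression
#'   features from (e.g. the minmax-stage spectrum when
#'   `feature_stage = "minmax"`); defaults to `nspec`.
#' @return A `bili_prediction`: list with `cohort`, `concentration_mgdl`
#'   (`NA` when no curve exists for the cohort), `features` (alpha, beta,
#'   feature value) and `trace` (one record per threshold comparison).
#' @export
predict_sample <- function(nspec, params = default_model_params(),
                           feature_nspec = NULL) {
  stopifnot(inherits(nspec, "blood_nspectrum"))
  if (nspec$stage != "ref_renormalized")
    stop("predict_sample expects a ref_renormalized spectrum; see ",
         "renormalize_to_reference()", call. = FALSE)
  if (is.null(feature_nspec)) feature_nspec <- nspec
  hw <- params$band_half_width_nm
  alpha <- compute_alpha(nspec, hw)
  branch1 <- classify_stage1(alpha, params)
  trace <- list(list(statistic = "alpha", value = alpha,
                     threshold = params$alpha_threshold,
                     mode = params$comparison_mode, branch = branch1))
  beta <- NA_real_; feature <- NA_real_; conc <- NA_real_
  if (branch1 == "LOW") {
    cohort <- "LOW"
    feature <- band_average(feature_nspec, params$low_model$feature_band_center_nm, hw)
    conc <- predict_quadratic(feature, params$low_model)
  } else {
    beta <- compute_beta(nspec, hw)
    cohort <- classify_stage2(beta, params)
    trace <- c(trace, list(list(statistic = "beta", value = beta,
                                threshold = params$beta_threshold,
                                mode = params$comparison_mode, branch = cohort)))
    if (cohort == "MEDIUM") {
      feature <- band_average(feature_nspec, params$medium_model$feature_band_center_nm, hw)
      conc <- predict_quadratic(feature, params$medium_model)
    } else if (!is.null(params$high_model)) {
      feature <- band_average(feature_nspec, params$high_model$feature_band_center_nm, hw)
      conc <- predict_quadratic(feature, params$high_model)
    }
  }
  structure(list(cohort = cohort, concentration_mgdl = conc,
                 features = list(alpha = alpha, beta = beta, feature = feature,
                                 i_ref_check = band_average(nspec, params$ref_center_nm, hw)),
                 trace = trace),
            class = "bili_prediction")
}

#' @export
print.bili_prediction <- function(x, ...) {
  cat(sprintf("<bili_prediction> cohort %s, concentration %s mg/dl\n", x$cohort,
              if (is.na(x$concentration_mgdl)) "--"
              else sprintf("%.2f", x$concentration_mgdl)))
  for (tr in x$trace)
    cat(sprintf("  %s = %.6g vs threshold %.6g (%s) -> %s\n",
                tr$statistic, tr$value, tr$threshold, tr$mode, tr$branch))
  invisible(x)
}

#' Full pipeline: raw spectrum to prediction
#'
#' Convenience wrapper: min-max normalization, reference renormalization,
#' then [predict_sample()]. `feature_stage` selects which stage the
#' regression features (the 492/468 nm band averages) are read from; the
#' slope statistics are always computed on the reference-renormalized
#' spectrum.
#'
#' @param spec A raw `blood_spectrum` covering at least 460-680 nm.
#' @param params A [model_params()].
#' @param feature_stage `"ref_renormalized"` (default) or `"minmax"`.
#' @return A `bili_prediction`.
#' @export
predict_spectrum <- function(spec, params = default_model_params(),
                             feature_stage = c("ref_renormalized", "minmax")) {
  feature_stage <- match.arg(feature_stage)
  nm <- minmax_normalize(spec)
  nr <- renormalize_to_reference(nm, band_spec(params$ref_center_nm,
                                               params$band_half_width_nm))
  predict_sample(nr, params,
                 feature_nspec = if (feature_stage == "minmax") nm else nr)
}

#' Fit a cohort calibration curve
#'
#' Ordinary least-squares degree-2 polynomial of concentration on the
#' band feature. `r_squared = 1 - SSres/SStot` with `SStot` about the
#' mean of `y`; when `SStot` is 0 the convention is `R^2 = 1` for a
#' perfect fit and 0 otherwise.
#'
#' @param x Band-averaged normalized intensities.
#' @param y Laboratory concentrations (mg/dl), same length as `x`.
#' @param band_center_nm Wavelength the feature is read at, recorded in
#'   the returned model.
#' @return A [quadratic_model()].
#' @export
fit_cohort_model <- function(x, y, band_center_nm) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L || length(unique(x)) < 3L)
    stop("underdetermined fit: need at least 3 distinct feature values",
         call. = FALSE)
  fit <- stats::lm(y ~ stats::poly(x, 2, raw = TRUE))
  cf <- stats::coef(fit)
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    if (ssres < 1e-12) 1 else 0
  } else 1 - ssres / sstot
  quadratic_model(cf[[3]], cf[[2]], cf[[1]], band_center_nm, r2)
}

#' Calibrate a decision threshold from labeled statistic values
#'
#' Exhaustive search over the midpoints of adjacent sorted unique values:
#' the returned threshold maximizes training accuracy of the rule
#' `value > threshold -> upper cohort`; among equally accurate splits the
#' one with the largest margin (gap between the flanking values) wins,
#' and remaining ties go to the smallest threshold. Deterministic and
#' order-independent.
#'
#' @param values Numeric statistic values (alpha or beta).
#' @param is_upper_cohort Logical, `TRUE` for samples in the upper cohort.
#' @return The threshold, a single number.
#' @export
calibrate_threshold <- function(values, is_upper_cohort) {
  stopifnot(length(values) == length(is_upper_cohort),
            is.logical(is_upper_cohort))
  if (!any(is_upper_cohort) || all(is_upper_cohort))
    stop("both cohorts must be non-empty to calibrate a threshold", call. = FALSE)
  u <- sort(unique(values))
  if (length(u) == 1L) {
    warning("all statistic values identical: cohorts are non-separable")
    return(u)
  }
  cand_mid <- (u[-length(u)] + u[-1]) / 2
  margin <- diff(u)
  acc <- vapply(cand_mid, function(th)
    mean((values > th) == is_upper_cohort), numeric(1))
  best <- which(acc == max(acc))
  best <- best[order(-margin[best], cand_mid[best])][1]
  cand_mid[best]
}

#' Audit the medium-cohort curve against the published predictions
#'
#' Evaluates a medium-cohort quadratic at each published 468 nm feature
#' value and reports the residual (published prediction minus curve
#' output) per row plus the mean. With the shipped coefficients the
#' residual is a constant close to +2.0 mg/dl for all eleven medium rows
#' of the packaged test table - an internal inconsistency of the source
#' data that this package surfaces rather than silently corrects.
#'
#' @param rows Medium-cohort rows of [load_table1()] (must carry `i468`
#'   and `predicted_mgdl`).
#' @param model The medium-cohort [quadratic_model()] (default: shipped).
#' @return List with `residuals` (named by serial) and `mean_residual`.
#' @export
evaluate_medium_offset <- function(rows = NULL, model = default_model_params()$medium_model) {
  if (is.null(rows)) {
    t1 <- load_table1()
    rows <- t1[!is.na(t1$i468) & !is.na(t1$predicted_mgdl), ]
  }
  stopifnot(all(!is.na(rows$i468)), all(!is.na(rows$predicted_mgdl)))
  res <- rows$predicted_mgdl - predict_quadratic(rows$i468, model)
  names(res) <- rows$serial
  list(residuals = res, mean_residual = mean(res))
}
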