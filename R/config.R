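#' Read model parameters from a YAML config file
#'
#' The file mirrors [model_params()]: top-level keys `alpha_threshold`,
#' `beta_threshold`, `comparison_mode`, `ref_center_nm`,
#' `band_half_width_nm`, and per-cohort blocks `low_model`,
#' `medium_model`, optionally `high_model`, each with `a2`, `a1`, `a0`,
#' `band_center_nm` and optional `r_squared`. A `synthetic:` block, if
#' present, is returned unchanged in the `synthetic` attribute for the
#' generator. The packaged default config (the published model) is at
#' `system.file("extdata", "default_params.yaml", package = "bilispec")`.
#'
#' @param path YAML file path; default loads the packaged published model.
#' @return A [model_params()] object; any `synthetic` block is attached
#'   as `attr(, "synthetic")`.
#' @export
read_model_params <- function(path = system.file("extdata", "default_params.yaml",
                                                 package = "bilispec", mustWork = TRUE)) {
  cfg <- yaml::read_yaml(path)
  qm <- function(block) {
    if (is.null(block)) return(NULL)
    quadratic_model(block$a2, block$a1, block$a0, block$band_center_nm,
                    if (is.null(block$r_squared)) NA_real_ else block$r_squared)
  }
  p <- model_params(
    alpha_threshold = cfg$alpha_threshold,
    beta_threshold = cfg$beta_threshold,
    comparison_mode = if (is.null(cfg$comparison_mode)) "strict" else cfg$comparison_mode,
    low_model = qm(cfg$low_model),
    medium_model = qm(cfg$medium_model),
    high_model = qm(cfg$high_model),
    ref_center_nm = if (is.null(cfg$ref_center_nm)) 605 else cfg$ref_center_nm,
    band_half_width_nm = if (is.null(cfg$band_half_width_nm)) 5 else cfg$band_half_width_nm)
  attr(p, "synthetic") <- cfg$synthetic
  p
}

#' Write model parameters to a YAML config file
#'
#' @param params A [model_params()].
#' @param path Destination path.
#' @param synthetic Optional list written under the `synthetic:` key.
#' @export
write_model_params <- function(params, path, synthetic = NULL) {
  stopifnot(inherits(params, "model_params"))
  qm <- function(m) if (is.null(m)) NULL else
    list(a2 = m$a2, a1 = m$a1, a0 = m$a0,
         band_center_nm = m$feature_band_center_nm,
         r_squared = if (is.na(m$r_squared)) NULL else m$r_squared)
  out <- list(alpha_threshold = params$alpha_threshold,
              beta_threshold = params$beta_threshold,
              comparison_mode = params$comparison_mode,
              ref_center_nm = params$ref_center_nm,
              band_half_width_nm = params$band_half_width_nm,
              low_model = qm(params$low_model),
              medium_model = qm(params$medium_model),
              high_model = qm(params$high_model))
  if (!is.null(synthetic)) out$synthetic <- synthetic
  yaml::write_yaml(out, path)
  invisible(path)
}

# md5 of the canonical JSON serialization of a params object, for the
# provenance block in CLI outputs (tools::md5sum needs a file)
.params_hash <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}
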