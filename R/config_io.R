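#' Read a simulation config from a YAML or JSON file
#'
#' The file holds the [sim_config()] fields by name. `covariate_specs` is a
#' list of maps with at least `name` and `kind` plus the distribution
#' parameters; `implanted_profiles` a list of maps with `criteria` (each
#' `variable` / `operator` / `bound`) and `extra_treatment_log_or`;
#' `confounding_coefficients` and `baseline_outcome_coefficients` are named
#' maps. Fields left out fall back to the `study_preset()` defaults, so a
#' file can override just a few knobs.
#'
#' @param path Path to a `.yaml`/`.yml` (needs the yaml package) or
#'   `.json` file.
#' @param base Config supplying defaults for unset fields.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path, base = study_preset()) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  cfg <- unclass(base)
  simple <- intersect(names(raw),
                      c("n_patients", "treated_fraction_target",
                        "base_treatment_log_or", "rfp_target_rate",
                        "hba1c_effect", "hba1c_mean_change", "hba1c_sd",
                        "measurement_noise_sd", "ineligible_fraction",
                        "seed"))
  cfg[simple] <- raw[simple]
  for (fld in c("confounding_coefficients", "baseline_outcome_coefficients"))
    if (!is.null(raw[[fld]])) cfg[[fld]] <- unlist(raw[[fld]])
  if (!is.null(raw$covariate_specs))
    cfg$covariate_specs <- lapply(raw$covariate_specs, function(sp) {
      sp$probs <- unlist(sp$probs); sp$levels <- unlist(sp$levels)
      do.call(cov_spec, sp)
    })
  if (!is.null(raw$implanted_profiles))
    cfg$implanted_profiles <- lapply(raw$implanted_profiles, function(pr) {
      true_profile(lapply(pr$criteria, function(cr)
        criterion(cr$variable, cr$operator, cr$bound)),
        extra_treatment_log_or = pr$extra_treatment_log_or)
    })
  unknown <- setdiff(names(raw), c(simple, "confounding_coefficients",
                                   "baseline_outcome_coefficients",
                                   "covariate_specs", "implanted_profiles"))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, cfg)
}
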