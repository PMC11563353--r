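#' Simulate, preprocess and featurize a cohort, one patient at a time
#'
#' Streams each simulated patient through preprocessing and feature
#' extraction, retaining only the per-patient lesion feature stack (18
#' features), histopathology and metadata — never the raw decay cubes, whose
#' memory footprint dominates at realistic image sizes.
#'
#' @param sim_config A [simulation_config()].
#' @param prep_config A [preprocess_config()]; defaults to
#'   [auto_preprocess_config()] resolved from `sim_config`.
#' @param keep_healthy Keep the 9-feature healthy stacks (default `FALSE`;
#'   they are only needed to form the reference medians, which are always
#'   retained).
#' @return List of cohort entries: `patient_id`, `histopathology`, `site`,
#'   `lesion` ([feature_stack()]), `reference`, optionally `healthy`.
#' @export
cohort_feature_stacks <- function(sim_config,
                                  prep_config = auto_preprocess_config(sim_config),
                                  keep_healthy = FALSE) {
  stopifnot(inherits(sim_config, "simulation_config"),
            inherits(prep_config, "preprocess_config"))
  labels <- cohort_labels(sim_config)
  lapply(seq_len(sim_config$n_patients), function(i) {
    sample <- simulate_patient(sim_config, i, labels = labels)
    prep <- preprocess_sample(sample, prep_config)
    fs <- build_feature_stacks(prep,
                               meta = list(patient_id = sample$patient_id))
    entry <- list(patient_id = sample$patient_id,
                  histopathology = sample$histopathology,
                  site = sample$site,
                  lesion = fs$lesion,
                  reference = fs$reference)
    if (keep_healthy) entry$healthy <- fs$healthy
    entry
  })
}
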