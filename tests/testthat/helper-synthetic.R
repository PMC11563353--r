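# Desk-scale simulator configurations used across the test files: small
# images and a coarse time grid keep each cohort fast while preserving the
# >= 99%-of-decay-area window invariant (27.5 ns post-onset window).

small_sim_config <- function(n_patients = 8, positive_fraction = 0.5,
                             image_shape = c(16, 16), seed = 1, ...) {
  simulation_config(n_patients = n_patients,
                    positive_fraction = positive_fraction,
                    image_shape = image_shape, n_samples = 64,
                    time_dt = 0.5, prepulse_samples = 8, seed = seed, ...)
}

# Noise-free, artifact-free variant: the exact-recovery limit.
clean_sim_config <- function(...) {
  small_sim_config(noise_sd = 0, offset_level = 0, fraction_jitter_sd = 0,
                   patient_fraction_sd = 0, saturation_fraction = 0, ...)
}

small_cohort <- function(seed = 1, n_patients = 8, ...) {
  cohort_feature_stacks(small_sim_config(n_patients = n_patients,
                                         seed = seed, ...))
}

# A cube built directly from per-pixel traces: one band per element of
# `traces`, each a function(t) or a constant matrix-of-traces.
cube_from_traces <- function(trace_list, dt = 0.5) {
  multispectral_cube(trace_list, time_dt = dt)
}
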