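# Fast synthetic worlds for unit tests: small grid, small tumours, narrow
# windows. These are compute reductions only - generator mechanics and
# pipeline code paths are identical to the default world.

fast_cohort_config <- function(n_patients = 40L,
                               planted = list(density_stat = "mean",
                                              density_cm = 0.05,
                                              dose_stat = "dose_sd",
                                              dose_cm = 2.05,
                                              b1 = 0.24, b2 = 0.19,
                                              b3 = 0.47),
                               ...) {
  cohort_config(
    n_patients = n_patients,
    dims = c(40L, 40L, 30L),
    spacing = c(1, 1, 3),
    volume_range_cc = c(0.3, 3),
    n_phases = 1L,
    density_window = c(-0.5, 0.5),
    dose_window = c(1.5, 2.5),
    planted = planted,
    ...)
}

# memoised shared cohort so several test files can reuse one simulation
.cohort_cache <- new.env(parent = emptyenv())

shared_fast_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- simulate_cohort(
      fast_cohort_config(n_patients = 60L), seed = 42L)
  }
  .cohort_cache$cohort
}

# tiny toy survival data used by several Cox tests
toy_records <- function() {
  data.frame(
    patient_id = sprintf("T%d", 1:6),
    time = c(2, 4, 5, 7, 9, 12),
    event = c(1, 1, 0, 1, 0, 1),
    x = c(1, 0, 1, 0, 1, 0))
}
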