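# Shared fixtures, all generated in code.

# small random trial with optional gaps
toy_trial <- function(T = 20L, n_markers = 2L, seed = 1L, gaps = 0L) {
  set.seed(seed)
  N <- 3L * n_markers
  m <- matrix(rnorm(T * N), T, N)
  tr <- marker_dataset(m, sprintf("m%d", seq_len(n_markers)), 100,
                       subject_id = "S1", trial_id = paste0("toy", seed))
  if (gaps > 0L) {
    idx <- cbind(sample(T, gaps, replace = TRUE),
                 sample(N, gaps, replace = TRUE))
    tr$missing_mask[idx] <- TRUE
    tr$data[tr$missing_mask] <- NA_real_
  }
  tr
}

# standard planted cohort: 3 orthonormal modes, amplitude variances 10:3:1,
# sinusoids with integer cycle counts over the trial, noise at 1% of the
# smallest mode's RMS (the stated synthetic world)
planted_cohort_model <- function(noise_sd = 0.01, duration = 10,
                                 sampling_rate = 100, seed = 7L,
                                 mode_seed = 42L) {
  lay <- humanoid_layout()
  N <- length(lay$posture)
  modes <- random_orthonormal_modes(N, 3L, seed = mode_seed)
  planted_model(
    lay$posture, modes,
    list(amp_sinusoid(0.5, sqrt(20)),   # var 10
         amp_sinusoid(1.3, sqrt(6)),    # var 3
         amp_sinusoid(2.7, sqrt(2))),   # var 1 -> RMS 1
    noise_sd = noise_sd, sampling_rate = sampling_rate,
    duration = duration, seed = seed, marker_labels = lay$labels)
}

planted_cohort <- function(n_trials = 5L, ...) {
  model <- planted_cohort_model(...)
  list(model = model,
       trials = lapply(seq_len(n_trials), function(i)
         generate_trial(model, "S1", sprintf("T%02d", i))))
}

# preprocess a list of raw trials with centering only
prep_plain <- function(trials)
  lapply(trials, preprocess_trial, config = preprocess_config())

expect_equal_mat <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
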