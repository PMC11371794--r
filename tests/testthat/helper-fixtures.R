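# Fixtures built in code: tiny recordings, separable classes, small cohorts.

make_epochs <- function(n_trials = 6, n_channels = 3, n_samples = 20,
                        labels = NULL, sample_rate = 40,
                        window_ms = c(0, n_samples / sample_rate * 1000),
                        seed = 1) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = n_trials)
  epoched_recording(array(rnorm(n_trials * n_channels * n_samples),
                          c(n_trials, n_channels, n_samples)),
                    labels, sample_rate, window_ms)
}

# linearly separable two-class epochs: class 1 carries a fixed pattern
make_separable <- function(n0 = 30, n1 = 15, n_channels = 4,
                           n_samples = 20, shift = 4, seed = 1,
                           sample_rate = 40) {
  set.seed(seed)
  n <- n0 + n1
  d <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
  pattern <- sin(seq(0, pi, length.out = n_samples))
  for (k in n0 + seq_len(n1)) d[k, 1, ] <- d[k, 1, ] + shift * pattern
  epoched_recording(d, c(rep(0L, n0), rep(1L, n1)), sample_rate,
                    c(0, n_samples / sample_rate * 1000))
}

# small simulated cohort at desk scale; epochs at 250 Hz, preprocessed
small_cohort_config <- function(n_subjects = 5, n_sessions = 1,
                                n_blocks = 1, seed = 1, n_sequences = 6,
                                targets_per_sequence = 4, ...) {
  sim_config(n_subjects = n_subjects, n_channels = 8, sample_rate = 250,
             n_sessions = n_sessions, n_blocks = n_blocks,
             n_sequences = n_sequences, images_per_sequence = 50,
             targets_per_sequence = targets_per_sequence, seed = seed, ...)
}

cropped_block <- function(sim, session = 1, block = 1)
  lapply(cohort_block(sim$cohort, session, block), crop_window, 0, 500)

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
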