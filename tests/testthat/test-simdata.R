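test_that("the default schedule reproduces the RSVP block structure", {
  sched <- generate_schedule(seed = 1)
  ev <- sched$events
  expect_equal(nrow(ev), 1400)
  expect_equal(sum(ev$label == 1), 56)
  expect_equal(sum(ev$label == 0), 1344)
  expect_equal(unique(diff(ev$onset_ms)), 100)  # 10 Hz presentation
  expect_equal(as.integer(table(ev$sequence)), rep(100, 14))
  per_seq <- tapply(ev$label, ev$sequence, sum)
  expect_true(all(per_seq == 4))
  gaps <- diff(ev$onset_ms[ev$label == 1])
  expect_gte(min(gaps), 500)
})

test_that("schedules honour the target-gap constraint across seeds", {
  for (seed in 0:19) {
    ev <- generate_schedule(n_sequences = 5, images_per_sequence = 40,
                            targets_per_sequence = 4, seed = seed)$events
    expect_gte(min(diff(ev$onset_ms[ev$label == 1])), 500)
    expect_true(all(tapply(ev$label, ev$sequence, sum) == 4))
  }
})

test_that("degenerate and infeasible schedules are handled", {
  none <- generate_schedule(targets_per_sequence = 0, seed = 1)
  expect_true(all(none$events$label == 0))
  expect_error(generate_schedule(n_sequences = 2, images_per_sequence = 10,
                                 targets_per_sequence = 4,
                                 min_target_gap_ms = 500, seed = 1),
               "infeasible")
})

test_that("cohort generation is deterministic and correctly shaped", {
  cfg <- small_cohort_config(n_subjects = 3, n_sessions = 2, n_blocks = 2,
                             seed = 9)
  sim1 <- generate_cohort(cfg)
  sim2 <- generate_cohort(cfg)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$profiles, sim2$profiles)
  expect_equal(length(sim1$cohort$members), 3)
  expect_equal(length(sim1$cohort$recordings), 3 * 2 * 2)
  ep <- cohort_block(sim1$cohort, 1, 1)[[1]]
  expect_equal(dim(ep$data), c(6 * 50, 8, 300))
  expect_equal(ep$sample_rate, 250)
  # per-subject topographies are unit-norm
  expect_all_equal(colSums(sim1$topographies^2), rep(1, 3), tol = 1e-10)
})

test_that("noise-free identical-template subjects are perfectly correlated", {
  cfg <- small_cohort_config(n_subjects = 2, seed = 3, noise_scale = 0,
                             shared_weights = c(1, 1), topo_var = 0,
                             preprocess = FALSE)
  sim <- generate_cohort(cfg)
  block <- cohort_block(sim$cohort, 1, 1)
  expect_equal(collaborative_capability(block[[1]], block[[2]]), 1,
               tolerance = 1e-12)
  t1 <- class_templates(block[[1]])$p1
  t2 <- class_templates(block[[2]])$p1
  # averaged target epochs proportional across subjects
  ratio <- t1[abs(t2) > 1e-9] / t2[abs(t2) > 1e-9]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("planted amplitude controls the ERP peak and noise its RMS", {
  # pure-noise block: empirical RMS within 10% of the configured scale
  cfg_n <- small_cohort_config(n_subjects = 1, seed = 4, noise_scale = 5,
                               targets_per_sequence = 0, preprocess = FALSE)
  sim_n <- generate_cohort(cfg_n)
  ep <- cohort_block(sim_n$cohort, 1, 1)[[1]]
  expect_equal(sqrt(mean(ep$data^2)), 5, tolerance = 0.1)
  # noise-free block: target-epoch peak equals the planted amplitude
  cfg_s <- small_cohort_config(n_subjects = 1, seed = 5, noise_scale = 0,
                               erp_amplitudes = 7, shared_weights = 1,
                               topo_var = 0, preprocess = FALSE)
  sim_s <- generate_cohort(cfg_s)
  eps <- cohort_block(sim_s$cohort, 1, 1)[[1]]
  expect_equal(max(abs(eps$data)), 7, tolerance = 1e-6)
})

test_that("pairwise ERP correlation increases with the shared weights", {
  cfg <- small_cohort_config(n_subjects = 3, n_sequences = 10, seed = 6,
                             erp_amplitudes = c(12, 12, 12),
                             shared_weights = c(0.95, 0.9, 0.05))
  sim <- generate_cohort(cfg)
  b <- cropped_block(sim)
  hi <- collaborative_capability(b[[1]], b[[2]])  # both high w
  lo <- collaborative_capability(b[[1]], b[[3]])  # high vs low w
  expect_gt(hi, lo)
})

test_that("session 2 carries a covariance shift when the gain is not identity", {
  cfg <- small_cohort_config(n_subjects = 1, n_sessions = 2, seed = 7)
  sim <- generate_cohort(cfg)
  r1 <- ea_reference(cohort_block(sim$cohort, 1, 1)[[1]])$mean_cov
  r2 <- ea_reference(cohort_block(sim$cohort, 2, 1)[[1]])$mean_cov
  expect_gt(norm(r1 - r2, "F") / norm(r1, "F"), 0.01)
  expect_lte(kappa(sim$transforms[[1]]$gain), 100)
})

test_that("explicit topographies are honoured and mismatches rejected", {
  topo <- cbind(c(1, rep(0, 7)), c(0, 1, rep(0, 6)))
  cfg <- small_cohort_config(n_subjects = 2, seed = 8, topographies = topo)
  sim <- generate_cohort(cfg)
  expect_all_equal(sim$topographies, topo, tol = 1e-12)
  cfg_bad <- small_cohort_config(n_subjects = 2, seed = 8,
                                 topographies = topo[1:5, ])
  expect_error(generate_cohort(cfg_bad), "topography length")
})
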