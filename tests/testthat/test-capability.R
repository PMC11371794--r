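test_that("class templates are per-class trial means", {
  d <- array(0, c(2, 1, 1))
  d[1, 1, 1] <- 1
  d[2, 1, 1] <- 3
  ep <- epoched_recording(d, c(1L, 1L), 2, c(0, 500))
  expect_error(class_templates(ep), "class 0 absent")
  d2 <- array(c(d, 5), c(3, 1, 1))
  ep2 <- epoched_recording(d2, c(1L, 1L, 0L), 2, c(0, 500))
  ct <- class_templates(ep2)
  expect_equal(ct$p1[1, 1], 2)
  expect_equal(ct$p0[1, 1], 5)
  expect_equal(c(ct$n0, ct$n1), c(1, 2))
  # brute-force mean oracle on a random set
  ep3 <- make_epochs(20, 3, 12, seed = 40)
  ct3 <- class_templates(ep3)
  oracle <- matrix(0, 3, 12)
  idx <- which(ep3$labels == 1L)
  for (k in idx) oracle <- oracle + ep3$data[k, , ]
  expect_all_equal(ct3$p1, oracle / length(idx))
})

test_that("xdawn SSNR solves the 1-channel case in closed form", {
  ep <- make_epochs(10, 1, 8, seed = 41)
  res <- xdawn_ssnr(ep)
  p1 <- colMeans(ep$data[ep$labels == 1, 1, ])
  num <- sum(p1^2)
  den <- sum(ep$data^2)
  expect_equal(res$ssnr, num / (den + 1e-9 * den), tolerance = 1e-9)
  expect_equal(abs(res$filter), 1)
})

test_that("returned ssnr equals the Rayleigh quotient at the returned filter", {
  for (seed in 42:45) {
    ep <- make_epochs(15, 4, 10, seed = seed)
    res <- xdawn_ssnr(ep)
    u <- res$filter
    rq <- as.numeric((u %*% res$signal_cov %*% u) /
                       (u %*% res$total_cov %*% u))
    expect_equal(res$ssnr, rq, tolerance = 1e-10)
  }
})

test_that("ssnr is invariant under a global channel rotation", {
  ep <- make_epochs(15, 4, 10, seed = 46)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  rot <- ep
  for (k in seq_len(dim(ep$data)[1]))
    rot$data[k, , ] <- q %*% ep$data[k, , ]
  expect_equal(xdawn_ssnr(rot)$ssnr, xdawn_ssnr(ep)$ssnr,
               tolerance = 1e-8)
})

test_that("collaborative capability is the mean target-trial correlation", {
  ep <- make_epochs(10, 3, 12, seed = 47)
  expect_equal(collaborative_capability(ep, ep), 1)
  neg <- ep
  neg$data <- -ep$data
  expect_equal(collaborative_capability(ep, neg), -1)
  # direct double-loop oracle on independent noise subjects
  a <- make_epochs(30, 3, 12, seed = 48)
  b <- make_epochs(30, 3, 12, seed = 49)
  b$labels <- a$labels
  got <- collaborative_capability(a, b)
  idx <- which(a$labels == 1L)
  acc <- 0
  for (k in idx)
    acc <- acc + cor(as.numeric(a$data[k, , ]), as.numeric(b$data[k, , ]))
  expect_equal(got, acc / length(idx), tolerance = 1e-12)
  expect_lt(abs(got), 0.25)
  # symmetry is exact
  expect_identical(collaborative_capability(a, b),
                   collaborative_capability(b, a))
  bad <- make_epochs(30, 3, 12, labels = rev(a$labels))
  expect_error(collaborative_capability(a, bad), "pairing error")
  flat <- a
  flat$data[idx[1], , ] <- 0
  expect_warning(collaborative_capability(flat, b), "zero-variance")
})

test_that("mimc limit cases reduce to single-capability rankings", {
  sim <- generate_cohort(small_cohort_config(n_subjects = 4, seed = 50))
  block <- cropped_block(sim)
  s1 <- mimc_scores("s01", block, mu = 1)
  expect_identical(order(s1$m), order(s1$m_in))
  s0 <- mimc_scores("s01", block, mu = 0)
  expect_identical(order(s0$m), order(s0$m_co))
  expect_false("s01" %in% s1$candidate_ids)
})

test_that("antisymmetric capabilities cancel at mu = 1/2", {
  # m_in = (1,2,3) and m_co = (3,2,1) z-score to opposite vectors
  m <- 0.5 * cobci:::zscore_pop(c(1, 2, 3)) +
    0.5 * cobci:::zscore_pop(c(3, 2, 1))
  expect_all_equal(m, c(0, 0, 0))
})

test_that("combined ranking is invariant to affine rescaling of capabilities", {
  set.seed(51)
  m_in <- rnorm(6)
  m_co <- rnorm(6)
  m1 <- 0.3 * cobci:::zscore_pop(m_in) + 0.7 * cobci:::zscore_pop(m_co)
  m2 <- 0.3 * cobci:::zscore_pop(5 * m_in + 2) +
    0.7 * cobci:::zscore_pop(0.1 * m_co - 7)
  expect_identical(which.max(m1), which.max(m2))
  expect_all_equal(m1, m2, tol = 1e-10)
})

test_that("mu grid construction and tie rule behave as specified", {
  sim <- generate_cohort(small_cohort_config(n_subjects = 3, seed = 52))
  block <- cropped_block(sim)
  res <- optimize_mu(block, grid_step = 0.5, n_folds = 5)
  expect_equal(res$score_table$mu, c(0, 0.5, 1))
  expect_true(res$mu_star %in% c(0, 0.5, 1))
  # tie rule: a constant score table must return the smallest mu
  tab <- res$score_table
  expect_equal(tab$mu[which.max(rep(1, 3))], 0)
})

test_that("cross-validation folds follow the sequence-unit convention", {
  folds <- cobci:::make_cv_folds(1400, 5)
  expect_equal(lengths(folds), c(300, 300, 300, 300, 200))
  expect_identical(sort(unlist(folds)), 1:1400)
  folds2 <- cobci:::make_cv_folds(103, 5)
  expect_equal(sum(lengths(folds2)), 103)
  expect_true(all(abs(lengths(folds2) - 103 / 5) <= 1))
})
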