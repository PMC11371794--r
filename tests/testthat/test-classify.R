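test_that("HDCA separates linearly separable classes perfectly", {
  ep <- make_separable(seed = 1)
  model <- hdca_fit(ep, window_count = 4)
  sv <- hdca_score(model, ep)
  expect_equal(auc(sv$scores, ep$labels), 1)
  bm <- binary_metrics(ep$labels, sv$labels)
  expect_equal(bm$tpr, 1)
  expect_equal(bm$fpr, 0)
  # all targets above, all non-targets below the threshold
  expect_true(all(sv$scores[ep$labels == 1] > sv$threshold))
  expect_true(all(sv$scores[ep$labels == 0] < sv$threshold))
})

test_that("with one window and one channel the score is affine in the trial mean", {
  set.seed(21)
  n <- 40
  d <- array(rnorm(n * 1 * 10), c(n, 1, 10))
  labels <- rep(c(0L, 1L), n / 2)
  d[labels == 1, 1, ] <- d[labels == 1, 1, ] + 1.5
  ep <- epoched_recording(d, labels, 20, c(0, 500))
  model <- hdca_fit(ep, window_count = 1)
  sv <- hdca_score(model, ep)
  xbar <- apply(d[, 1, ], 1, mean)
  slope <- model$temporal_weights * model$spatial_filters[1, 1]
  expect_all_equal(sv$scores, slope * xbar, tol = 1e-10)
  expect_gt(slope, 0)  # sign convention: target class mean is high
})

test_that("scores equal a naive per-trial loop implementation", {
  ep <- make_separable(n0 = 20, n1 = 10, n_channels = 3, n_samples = 20,
                       seed = 3)
  w_count <- 4
  model <- hdca_fit(ep, w_count)
  sv <- hdca_score(model, ep)
  nw <- dim(ep$data)[3] / w_count
  naive <- sapply(seq_len(dim(ep$data)[1]), function(k) {
    y <- sapply(seq_len(w_count), function(w) {
      xw <- ep$data[k, , (w - 1) * nw + seq_len(nw), drop = TRUE]
      mean(model$spatial_filters[, w] %*% xw)
    })
    sum(y * model$temporal_weights)
  })
  expect_all_equal(sv$scores, naive)
})

test_that("model ranks its own class templates correctly", {
  ep <- make_separable(seed = 5)
  model <- hdca_fit(ep, 4)
  expect_gt(sum(model$proj_template_1 * model$temporal_weights),
            sum(model$proj_template_0 * model$temporal_weights))
})

test_that("HDCA AUC is invariant under common affine scaling of trials", {
  ep <- make_separable(seed = 6)
  sv1 <- hdca_score(hdca_fit(ep, 4), ep)
  ep2 <- ep
  ep2$data <- 3 * ep$data + 2
  sv2 <- hdca_score(hdca_fit(ep2, 4), ep2)
  expect_equal(auc(sv1$scores, ep$labels), auc(sv2$scores, ep$labels),
               tolerance = 1e-10)
})

test_that("HDCA validates class presence and window divisibility", {
  ep <- make_epochs(6, 2, 20, labels = rep(1L, 6))
  expect_error(hdca_fit(ep, 4), "class 0 absent")
  ep2 <- make_epochs(6, 2, 20)
  expect_error(hdca_fit(ep2, 7), "not divisible")
  model <- hdca_fit(ep2, 4)
  bad <- make_epochs(6, 3, 20)
  expect_error(hdca_score(model, bad), "shape mismatch")
})

test_that("EA reference satisfies the matrix-function identities", {
  set.seed(31)
  ep <- make_epochs(12, 3, 15)
  ref <- ea_reference(ep)
  expect_lt(norm(ref$inv_sqrt %*% ref$mean_cov %*% ref$inv_sqrt -
                   diag(3), "F"), 1e-8)
  expect_lt(norm(ref$inv_sqrt %*% ref$inv_sqrt %*% ref$mean_cov -
                   diag(3), "F"), 1e-8)
  # single-trial alignment whitens that trial exactly
  one <- make_epochs(1, 3, 15, labels = 1L)
  al <- ea_align(one, ea_reference(one))
  x <- al$data[1, , ]
  expect_lt(norm(x %*% t(x) - diag(3), "F"), 1e-8)
})

test_that("alignment with own reference yields identity mean covariance", {
  set.seed(32)
  ep <- make_epochs(20, 4, 25)
  al <- ea_align(ep, ea_reference(ep))
  mc <- ea_reference(al)$mean_cov
  expect_lt(norm(mc - diag(4), "F"), 1e-8)
  # and is a fixed point: re-aligning changes almost nothing
  al2 <- ea_align(al, ea_reference(al))
  expect_lt(max(abs(al2$data - al$data)), 1e-6)
  # identity reference leaves data untouched
  id_ref <- structure(list(mean_cov = diag(4), inv_sqrt = diag(4),
                           n_trials = 1L), class = "ea_reference")
  expect_equal(ea_align(ep, id_ref)$data, ep$data, tolerance = 1e-14)
  expect_error(ea_align(make_epochs(3, 2, 10), ea_reference(ep)),
               "dimension mismatch")
})

test_that("ea_hdca with a common domain equals align-then-HDCA", {
  ep <- make_separable(seed = 8)
  got <- ea_hdca(ep, ep, window_count = 4)
  al <- ea_align(ep, ea_reference(ep))
  manual <- hdca_score(hdca_fit(al, 4), al)
  expect_all_equal(got$scores, manual$scores)
})
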