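#' @title HDCA single-trial classification and Euclidean alignment
#' @name cobci-classify
#' @description
#' Hierarchical discriminant component analysis (HDCA) splits each trial
#' into `W` non-overlapping time windows, learns a Fisher linear
#' discriminant (FLD) spatial filter per window from the sample-level
#' channel vectors, reduces each window to one feature per trial (the mean
#' projected value), and learns a second FLD across the `W` window features.
#' The decision threshold is the midpoint of the projected class templates.
#' For cross-session transfer, Euclidean-space alignment (EA) whitens each
#' domain by the inverse square root of its mean trial covariance, so every
#' domain's mean covariance becomes the identity before HDCA is applied.
NULL

fld_direction <- function(rows, row_labels, diff_1_minus_0 = TRUE) {
  p0 <- colMeans(rows[row_labels == 0L, , drop = FALSE])
  p1 <- colMeans(rows[row_labels == 1L, , drop = FALSE])
  r0 <- sweep(rows[row_labels == 0L, , drop = FALSE], 2, p0)
  r1 <- sweep(rows[row_labels == 1L, , drop = FALSE], 2, p1)
  s_w <- crossprod(r0) + crossprod(r1)
  s_w <- s_w + diag(1e-6 * sum(diag(s_w)) / ncol(rows), ncol(rows))
  dvec <- if (diff_1_minus_0) p1 - p0 else p0 - p1
  u <- tryCatch(solve(s_w, dvec), error = function(e) {
    ev <- eigen(s_w, symmetric = TRUE)
    keep <- ev$values > 1e-12 * max(ev$values)
    ev$vectors[, keep, drop = FALSE] %*%
      ((t(ev$vectors[, keep, drop = FALSE]) %*% dvec) / ev$values[keep])
  })
  list(u = as.numeric(u), p0 = p0, p1 = p1)
}

# trials x channels x samples window -> rows (trial, sample) x channels
window_rows <- function(data, cols) {
  d <- dim(data)
  matrix(aperm(data[, , cols, drop = FALSE], c(1, 3, 2)),
         nrow = d[1] * length(cols))
}

#' Fit an HDCA model
#'
#' @param x a [fuse()]d epochs object or an [epoched_recording()] with both
#'   classes present
#' @param window_count number of non-overlapping time windows `W`; must
#'   divide the sample count (default 5, i.e. each window is a fifth of the
#'   analysis interval)
#' @return object of class `hdca_model`: per-window spatial filters (columns
#'   of `spatial_filters`), temporal weights `v`, decision `threshold`, and
#'   the projected class templates
#' @export
hdca_fit <- function(x, window_count = 5) {
  d <- dim(x$data)
  labels <- as.integer(x$labels)
  for (cls in 0:1)
    if (!any(labels == cls))
      stop(sprintf("class %d absent: cannot train HDCA", cls), call. = FALSE)
  if (d[3] %% window_count != 0)
    stop(sprintf("%d samples not divisible into %d windows", d[3],
                 window_count), call. = FALSE)
  nw <- d[3] %/% window_count
  u_mat <- matrix(0, d[2], window_count)
  y <- matrix(0, d[1], window_count)
  for (w in seq_len(window_count)) {
    cols <- (w - 1L) * nw + seq_len(nw)
    rows <- window_rows(x$data, cols)
    fld <- fld_direction(rows, rep(labels, times = nw),
                         diff_1_minus_0 = FALSE)
    yw <- rowMeans(matrix(rows %*% fld$u, d[1], nw))
    # sign convention: target-class mean projection is the larger one
    if (mean(yw[labels == 1L]) < mean(yw[labels == 0L])) {
      fld$u <- -fld$u
      yw <- -yw
    }
    u_mat[, w] <- fld$u
    y[, w] <- yw
  }
  tf <- fld_direction(y, labels, diff_1_minus_0 = TRUE)
  v <- tf$u
  if (sum((tf$p1 - tf$p0) * v) < 0) v <- -v
  structure(list(window_count = window_count, window_samples = nw,
                 n_channels = d[2],
                 spatial_filters = u_mat, temporal_weights = v,
                 threshold = as.numeric(0.5 * (tf$p0 + tf$p1) %*% v),
                 proj_template_0 = tf$p0, proj_template_1 = tf$p1),
            class = "hdca_model")
}

#' Score trials with an HDCA model
#'
#' @param model an [hdca_fit()] result
#' @param x fused epochs or epoched recording with the model's channel and
#'   sample counts
#' @return object of class `score_vector`: continuous per-trial `scores`,
#'   the model `threshold`, and hard `labels` (`scores > threshold`)
#' @export
hdca_score <- function(model, x) {
  d <- dim(x$data)
  if (d[2] != model$n_channels ||
      d[3] != model$window_count * model$window_samples)
    stop(sprintf("shape mismatch: model expects %d ch x %d samples, got %d x %d",
                 model$n_channels, model$window_count * model$window_samples,
                 d[2], d[3]), call. = FALSE)
  y <- matrix(0, d[1], model$window_count)
  for (w in seq_len(model$window_count)) {
    cols <- (w - 1L) * model$window_samples + seq_len(model$window_samples)
    rows <- window_rows(x$data, cols)
    y[, w] <- rowMeans(matrix(rows %*% model$spatial_filters[, w],
                              d[1], model$window_samples))
  }
  scores <- as.numeric(y %*% model$temporal_weights)
  structure(list(scores = scores, threshold = model$threshold,
                 labels = as.integer(scores > model$threshold)),
            class = "score_vector")
}

#' Euclidean-alignment reference of a domain
#'
#' The reference is the mean trial covariance `R = (1/n) sum_k X_k X_k^T`
#' over all trials (labels unused, so it is test-time legal) and its
#' symmetric inverse square root, computed by eigendecomposition. Eigenvalues
#' below `1e-10 * lambda_max` are treated as exact zeros (pseudo-inverse
#' semantics): their directions carry no data — e.g. the direction removed
#' by a common average reference — and are left unamplified, so whitening is
#' exact on the occupied subspace.
#'
#' @param x fused epochs or epoched recording with at least one trial
#' @return object of class `ea_reference`: `mean_cov`, `inv_sqrt`, `n_trials`
#' @export
ea_reference <- function(x) {
  d <- dim(x$data)
  stopifnot(d[1] >= 1)
  flat <- matrix(aperm(x$data, c(2, 3, 1)), nrow = d[2])
  r <- flat %*% t(flat) / d[1]
  ev <- eigen((r + t(r)) / 2, symmetric = TRUE)
  if (max(ev$values) <= 0)
    stop("degenerate covariance: data are identically zero", call. = FALSE)
  w_inv <- ifelse(ev$values > 1e-10 * max(ev$values),
                  1 / sqrt(pmax(ev$values, 0)), 0)
  structure(list(mean_cov = r,
                 inv_sqrt = ev$vectors %*% (t(ev$vectors) * w_inv),
                 n_trials = d[1]),
            class = "ea_reference")
}

#' Align trials with an EA reference
#'
#' Applies `X_k -> R^{-1/2} X_k` to every trial. When the reference was
#' computed from the same trials, the aligned mean trial covariance equals
#' the identity.
#'
#' @param x fused epochs or epoched recording
#' @param reference an [ea_reference()]
#' @return `x` with aligned data
#' @export
ea_align <- function(x, reference) {
  d <- dim(x$data)
  if (nrow(reference$inv_sqrt) != d[2])
    stop(sprintf("dimension mismatch: reference has %d channels, data %d",
                 nrow(reference$inv_sqrt), d[2]), call. = FALSE)
  flat <- matrix(aperm(x$data, c(2, 3, 1)), nrow = d[2])
  x$data <- aperm(array(reference$inv_sqrt %*% flat, c(d[2], d[3], d[1])),
                  c(3, 1, 2))
  x
}

#' Cross-domain HDCA with Euclidean alignment
#'
#' Training data are aligned with their own domain reference and the test
#' data with the test domain's reference (computed from unlabeled trials);
#' HDCA is then fit on the aligned training data and applied to the aligned
#' test data.
#'
#' @param train_x,test_x fused epochs (or epoched recordings) with equal
#'   channel counts
#' @param window_count HDCA window count
#' @return a `score_vector` for the test trials, with the fitted model
#'   attached as element `model`
#' @export
ea_hdca <- function(train_x, test_x, window_count = 5) {
  train_a <- ea_align(train_x, ea_reference(train_x))
  test_a <- ea_align(test_x, ea_reference(test_x))
  model <- hdca_fit(train_a, window_count)
  out <- hdca_score(model, test_a)
  out$model <- model
  out
}
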