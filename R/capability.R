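#' @title Individual and collaborative capability scoring (MIMC)
#' @name cobci-capability
#' @description
#' Two complementary scores drive group-member selection. The *individual*
#' capability of a candidate is the signal to signal-plus-noise ratio (SSNR)
#' of their target ERP, i.e. the largest generalized eigenvalue of the xDAWN
#' pair (target-template covariance, total data covariance) in channel space.
#' The *collaborative* capability between a user and a candidate is the mean
#' Pearson correlation of their flattened target trials. MIMC combines the
#' two after z-scoring with a weight `mu` in `[0, 1]`; `mu` is chosen by
#' cross-validated collaborative classification performance.
NULL

subset_trials <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  epochs
}

#' Per-class template signals
#'
#' Arithmetic mean of all trials of each class.
#'
#' @param epochs an [epoched_recording()] (or fused epochs) with both classes
#' @return list with channels x samples matrices `p0`, `p1` and trial counts
#'   `n0`, `n1`
#' @export
class_templates <- function(epochs) {
  for (cls in 0:1)
    if (!any(epochs$labels == cls))
      stop(sprintf("class %d absent: cannot form its template", cls),
           call. = FALSE)
  avg <- function(cls) {
    idx <- which(epochs$labels == cls)
    m <- epochs$data[idx[1], , , drop = TRUE]
    if (length(idx) > 1)
      m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    matrix(m, dim(epochs$data)[2], dim(epochs$data)[3])
  }
  list(p0 = avg(0L), p1 = avg(1L),
       n0 = sum(epochs$labels == 0L), n1 = sum(epochs$labels == 1L))
}

#' xDAWN SSNR of a recording
#'
#' Solves the generalized eigenproblem of the target-template covariance
#' `P1 %*% t(P1)` against the total data covariance `sum_k X_k %*% t(X_k)`
#' (channel-space convention). The largest generalized eigenvalue is the
#' SSNR score; its eigenvector is the leading xDAWN spatial filter. A ridge
#' of `1e-9 * trace / n_channels` stabilizes the total covariance.
#'
#' @param epochs an epoched recording with at least one target trial
#' @return list with `ssnr` (largest generalized eigenvalue), `filter`
#'   (unit-norm channel vector), `signal_cov`, `total_cov`
#' @export
xdawn_ssnr <- function(epochs) {
  if (!any(epochs$labels == 1L))
    stop("no target trials: SSNR undefined", call. = FALSE)
  d <- dim(epochs$data)
  idx1 <- which(epochs$labels == 1L)
  p1 <- epochs$data[idx1[1], , , drop = TRUE]
  if (length(idx1) > 1)
    p1 <- apply(epochs$data[idx1, , , drop = FALSE], c(2, 3), mean)
  p1 <- matrix(p1, d[2], d[3])
  s_sig <- p1 %*% t(p1)
  flat <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = d[2])
  s_tot <- flat %*% t(flat)
  ridge <- 1e-9 * sum(diag(s_tot)) / d[2]
  s_tot_r <- s_tot + diag(ridge, d[2])
  eg <- eigen(s_tot_r, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop(sprintf(
      "total covariance rank-deficient beyond ridge repair (min eigenvalue %.3e, max %.3e)",
      min(eg$values), max(eg$values)), call. = FALSE)
  wht <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  k <- wht %*% s_sig %*% wht
  ek <- eigen((k + t(k)) / 2, symmetric = TRUE)
  u <- wht %*% ek$vectors[, 1]
  u <- u / sqrt(sum(u^2))
  list(ssnr = ek$values[1], filter = as.numeric(u),
       signal_cov = s_sig, total_cov = s_tot_r)
}

#' Collaborative capability of a user/candidate pair
#'
#' Mean over target trials of the Pearson correlation between the two
#' subjects' flattened (channels x samples) trials. Symmetric in its
#' arguments; a zero-variance trial contributes 0 with a warning.
#'
#' @param user_epochs,cand_epochs epoched recordings with identical trial
#'   counts, shapes and label sequences
#' @return a number in `[-1, 1]`
#' @export
collaborative_capability <- function(user_epochs, cand_epochs) {
  if (!identical(dim(user_epochs$data), dim(cand_epochs$data)))
    stop("pairing error: recordings have different shapes", call. = FALSE)
  if (!identical(user_epochs$labels, cand_epochs$labels))
    stop("pairing error: label sequences differ", call. = FALSE)
  idx1 <- which(user_epochs$labels == 1L)
  if (length(idx1) == 0)
    stop("no target trials: collaborative capability undefined", call. = FALSE)
  r <- vapply(idx1, function(k) {
    a <- as.numeric(user_epochs$data[k, , ])
    b <- as.numeric(cand_epochs$data[k, , ])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance trial: correlation taken as 0", call. = FALSE)
      return(0)
    }
    stats::cor(a, b)
  }, 0)
  mean(r)
}

# z-score with population standard deviation (divide by n); constant input
# maps to all zeros with a warning
zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    warning("zero spread in capability vector: z-scores set to 0",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' MIMC capability scores for one predefined user
#'
#' For every candidate (all cohort members except the user), computes the
#' individual capability `m_in` (candidate SSNR), the collaborative
#' capability `m_co` (mean target-trial ERP correlation with the user), and
#' the combined score `m = mu * z(m_in) + (1 - mu) * z(m_co)` where `z` is
#' the population z-score across candidates.
#'
#' @param user_id member id of the predefined user
#' @param block named list of epoched recordings, one per member (see
#'   [cohort_block()])
#' @param mu weight in `[0, 1]` on individual capability
#' @return object of class `capability_scores`
#' @export
mimc_scores <- function(user_id, block, mu) {
  stopifnot(mu >= 0, mu <= 1, user_id %in% names(block))
  cand <- setdiff(names(block), user_id)
  if (length(cand) < 2)
    stop("need at least 2 candidates to z-score capabilities", call. = FALSE)
  m_in <- vapply(cand, function(j) xdawn_ssnr(block[[j]])$ssnr, 0)
  m_co <- vapply(cand, function(j)
    collaborative_capability(block[[user_id]], block[[j]]), 0)
  structure(list(user_id = user_id, candidate_ids = cand,
                 m_in = m_in, m_co = m_co, mu = mu,
                 m = mu * zscore_pop(m_in) + (1 - mu) * zscore_pop(m_co)),
            class = "capability_scores")
}

#' @export
print.capability_scores <- function(x, ...) {
  cat(sprintf("<capability_scores> user %s, %d candidates, mu = %.2f\n",
              x$user_id, length(x$candidate_ids), x$mu))
  print(data.frame(candidate = x$candidate_ids, m_in = x$m_in,
                   m_co = x$m_co, m = x$m, row.names = NULL))
  invisible(x)
}

# Contiguous cross-validation folds. When the trial count is a multiple of
# `unit` (the 100-presentation sequence structure), whole units are dealt so
# e.g. 1400 trials in 5 folds gives 300/300/300/300/200; otherwise a plain
# near-equal contiguous split.
make_cv_folds <- function(n, n_folds = 5, unit = 100) {
  sizes <- if (n %% unit == 0 && n %/% unit >= n_folds) {
    u <- n %/% unit
    per <- ceiling(u / n_folds)
    s <- rep(per, n_folds - 1)
    c(s, u - sum(s)) * unit
  } else {
    s <- rep(n %/% n_folds, n_folds)
    s + c(rep(1, n %% n_folds), rep(0, n_folds - n %% n_folds))
  }
  if (any(sizes <= 0)) stop("degenerate cross-validation folds", call. = FALSE)
  ends <- cumsum(sizes)
  mapply(function(a, b) seq.int(a, b), c(1, ends[-n_folds] + 1), ends,
         SIMPLIFY = FALSE)
}

#' Optimize the MIMC weight by cross-validated pair performance
#'
#' For each fold and each `mu` on a grid, every member is paired with their
#' argmax-MIMC candidate using capabilities computed on the training folds
#' only; the pair is fused by average ERP, an HDCA model is trained on the
#' training folds and scored on the held-out fold, and the score of `mu` in
#' that fold is the mean AUC over members. `mu_star` is the grid value with
#' the highest mean score over folds (ties broken toward the smallest `mu`).
#'
#' @param block named list of epoched recordings, one per member
#' @param grid_step spacing of the `mu` grid on `[0, 1]`
#' @param n_folds number of contiguous cross-validation folds
#' @param window_count HDCA window count
#' @return list with `mu_star` and `score_table` (one row per grid value:
#'   per-fold scores and their mean)
#' @export
optimize_mu <- function(block, grid_step = 0.01, n_folds = 5,
                        window_count = 5) {
  if (length(block) < 2)
    stop("need at least 2 members to optimize mu", call. = FALSE)
  members <- names(block)
  n <- dim(block[[1]]$data)[1]
  folds <- make_cv_folds(n, n_folds)
  grid <- seq(0, 1, by = grid_step)
  scores <- matrix(NA_real_, length(grid), n_folds)
  auc_cache <- new.env(parent = emptyenv())
  pair_auc <- function(i, j, train_idx, test_idx, f) {
    key <- paste(i, j, f, sep = "|")
    if (!is.null(auc_cache[[key]])) return(auc_cache[[key]])
    tr <- fuse(list(subset_trials(block[[i]], train_idx),
                    subset_trials(block[[j]], train_idx)), "average_erp")
    te <- fuse(list(subset_trials(block[[i]], test_idx),
                    subset_trials(block[[j]], test_idx)), "average_erp")
    model <- hdca_fit(tr, window_count)
    a <- auc(hdca_score(model, te)$scores, te$labels)
    auc_cache[[key]] <- a
    a
  }
  for (f in seq_len(n_folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    ssnr <- vapply(members, function(j)
      xdawn_ssnr(subset_trials(block[[j]], train_idx))$ssnr, 0)
    n_m <- length(members)
    co <- matrix(0, n_m, n_m, dimnames = list(members, members))
    for (a_i in seq_len(n_m - 1)) for (b_i in (a_i + 1):n_m) {
      v <- collaborative_capability(
        subset_trials(block[[a_i]], train_idx),
        subset_trials(block[[b_i]], train_idx))
      co[a_i, b_i] <- v
      co[b_i, a_i] <- v
    }
    for (g in seq_along(grid)) {
      mu <- grid[g]
      aucs <- vapply(seq_len(n_m), function(i) {
        cand <- setdiff(seq_len(n_m), i)
        m <- mu * zscore_pop(ssnr[cand]) + (1 - mu) * zscore_pop(co[i, cand])
        j <- cand[which.max(m)]
        pair_auc(i, j, train_idx, test_idx, f)
      }, 0)
      scores[g, f] <- mean(aucs)
    }
  }
  tab <- data.frame(mu = grid, scores, mean_score = rowMeans(scores))
  names(tab)[1 + seq_len(n_folds)] <- paste0("fold", seq_len(n_folds))
  list(mu_star = grid[which.max(tab$mean_score)], score_table = tab)
}
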