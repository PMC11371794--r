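#' @title Group-member selection strategies
#' @name cobci-grouping
#' @description
#' Two-user matching pairs each predefined user with one collaborator, by
#' MIMC score or by one of the baseline rules (random draw, individual
#' performance dissimilarity, best individual performance, best
#' collaborative performance). Sub-group selection runs sequential forward
#' floating selection (SFFS) with the MIMC objective: greedy inclusion of
#' the member that scores highest against the fused current sub-group, with
#' conditional backward exclusion guarded by cross-validated AUC, stopping
#' when the cross-validated AUC no longer improves.
NULL

#' Cross-validated AUC of a fused member set
#'
#' Contiguous k-fold cross-validation (same partition convention as
#' [optimize_mu()]): for each fold, the remaining folds' trials of every
#' member are fused by average ERP, an HDCA model is trained and the
#' held-out trials are scored. Returns the mean AUC over folds.
#'
#' @param epochs_list list of epoched recordings (one member each)
#' @param n_folds number of folds
#' @param window_count HDCA window count
#' @return mean cross-validated AUC
#' @export
cv_auc_fused <- function(epochs_list, n_folds = 5, window_count = 5) {
  n <- dim(epochs_list[[1]]$data)[1]
  folds <- make_cv_folds(n, n_folds)
  mean(vapply(folds, function(test_idx) {
    train_idx <- setdiff(seq_len(n), test_idx)
    tr <- fuse(lapply(epochs_list, subset_trials, train_idx), "average_erp")
    te <- fuse(lapply(epochs_list, subset_trials, test_idx), "average_erp")
    auc(hdca_score(hdca_fit(tr, window_count), te)$scores, te$labels)
  }, 0))
}

#' Pair a user with a collaborator
#'
#' @param block named list of epoched recordings, one per member
#' @param user member id of the predefined user
#' @param strategy one of `"mimc"` (argmax MIMC score), `"random"` (uniform
#'   draw), `"ipd"` (argmin absolute difference of single-subject
#'   cross-validated AUCs), `"bip"` (argmax single-subject cross-validated
#'   AUC), `"bcp"` (argmax fused-pair cross-validated AUC)
#' @param mu MIMC weight (used by `"mimc"` only)
#' @param seed RNG seed (used by `"random"` only)
#' @param n_folds,window_count cross-validation parameters for the
#'   AUC-based strategies
#' @return object of class `pair_assignment`: `user_id`, `collaborator_id`,
#'   `strategy`, `score`
#' @export
match_collaborator <- function(block, user,
                               strategy = c("mimc", "random", "ipd", "bip",
                                            "bcp"),
                               mu = 0.5, seed = 1, n_folds = 5,
                               window_count = 5) {
  strategy <- match.arg(strategy)
  stopifnot(user %in% names(block))
  cand <- setdiff(names(block), user)
  if (length(cand) == 0) stop("no candidate collaborators", call. = FALSE)
  pick <- if (length(cand) == 1) {
    list(id = cand, score = NA_real_)
  } else switch(strategy,
    mimc = {
      sc <- mimc_scores(user, block, mu)
      i <- which.max(sc$m)
      list(id = sc$candidate_ids[i], score = sc$m[i])
    },
    random = {
      id <- with_seed(seed, cand[sample.int(length(cand), 1)])
      list(id = id, score = NA_real_)
    },
    ipd = {
      a_user <- cv_auc_fused(block[user], n_folds, window_count)
      a_cand <- vapply(cand, function(j)
        cv_auc_fused(block[j], n_folds, window_count), 0)
      i <- which.min(abs(a_cand - a_user))
      list(id = cand[i], score = abs(a_cand - a_user)[i])
    },
    bip = {
      a_cand <- vapply(cand, function(j)
        cv_auc_fused(block[j], n_folds, window_count), 0)
      i <- which.max(a_cand)
      list(id = cand[i], score = a_cand[i])
    },
    bcp = {
      a_pair <- vapply(cand, function(j)
        cv_auc_fused(block[c(user, j)], n_folds, window_count), 0)
      i <- which.max(a_pair)
      list(id = cand[i], score = a_pair[i])
    })
  structure(list(user_id = user, collaborator_id = pick$id,
                 strategy = strategy, score = unname(pick$score)),
            class = "pair_assignment")
}

#' Match every member of a cohort block
#'
#' One independent [match_collaborator()] call per member; pairings need not
#' be mutual.
#'
#' @inheritParams match_collaborator
#' @return named list of `pair_assignment`, one per member
#' @export
match_all <- function(block, strategy = "mimc", mu = 0.5, seed = 1,
                      n_folds = 5, window_count = 5) {
  out <- lapply(seq_along(block), function(i)
    match_collaborator(block, names(block)[i], strategy, mu,
                       seed = seed + i - 1L, n_folds = n_folds,
                       window_count = window_count))
  stats::setNames(out, names(block))
}

#' SFFS with the MIMC objective for sub-group selection
#'
#' Initializes with the member of highest SSNR, then repeats: (i)
#' *inclusion* — treat the average-ERP fusion of the current sub-group as a
#' predefined user and add the outside member with the highest MIMC score
#' against it; (ii) *conditional exclusion* — score each included member
#' against the fusion of the others and remove the argmin, but only if it is
#' not the member just added and removal strictly improves on the best
#' cross-validated AUC previously recorded at the smaller size (repeating
#' while that holds); (iii) *termination* — stop when the cross-validated
#' AUC of the grown sub-group does not exceed the current sub-group's by
#' more than `epsilon`, returning the current sub-group, or when the size
#' cap is reached. Every decision is recorded in the trace.
#'
#' @param block named list of epoched recordings, one per member
#' @param mu MIMC weight, normally the [optimize_mu()] result
#' @param epsilon minimum cross-validated AUC improvement to accept a grown
#'   sub-group (default 0: strict improvement required)
#' @param max_size optional size cap (default: all members)
#' @param n_folds,window_count cross-validation parameters
#' @return object of class `subgroup`: ordered `members` and a `trace` list
#'   recording inclusions, exclusions, objective values and AUCs
#' @export
sffs_subgroup <- function(block, mu, epsilon = 0, max_size = NULL,
                          n_folds = 5, window_count = 5) {
  members <- names(block)
  n_m <- length(members)
  cap <- min(max_size %||% n_m, n_m)
  ssnr <- vapply(members, function(j) xdawn_ssnr(block[[j]])$ssnr, 0)
  s <- members[which.max(ssnr)]
  cur_auc <- cv_auc_fused(block[s], n_folds, window_count)
  best_at_size <- c(cur_auc)  # indexed by sub-group size
  trace <- list(list(action = "init", member = s, ssnr = unname(ssnr),
                     cv_auc = cur_auc))
  mimc_vs_fused <- function(inside, outside) {
    # MIMC score of each `outside` member against the fused `inside` set
    fused <- fuse(block[inside], "average_erp")
    m_in <- ssnr[outside]
    m_co <- vapply(outside, function(j)
      collaborative_capability(fused, block[[j]]), 0)
    if (length(outside) == 1) return(stats::setNames(0, outside))
    stats::setNames(mu * zscore_pop(m_in) + (1 - mu) * zscore_pop(m_co),
                    outside)
  }
  while (length(s) < cap) {
    outside <- setdiff(members, s)
    j_incl <- mimc_vs_fused(s, outside)
    s_star <- outside[which.max(j_incl)]
    s_new <- c(s, s_star)
    auc_new <- cv_auc_fused(block[s_new], n_folds, window_count)
    trace[[length(trace) + 1]] <- list(action = "include", member = s_star,
                                       J = unname(j_incl),
                                       candidates = outside,
                                       cv_auc = auc_new)
    # conditional exclusion: argmin of each member scored against the rest
    repeat {
      if (length(s_new) < 2) break
      # score each member against the fusion of the others, z-scored across
      # the sub-group's members
      m_in <- ssnr[s_new]
      m_co <- vapply(s_new, function(m) collaborative_capability(
        fuse(block[setdiff(s_new, m)], "average_erp"), block[[m]]), 0)
      j_excl <- mu * zscore_pop(m_in) + (1 - mu) * zscore_pop(m_co)
      s_minus <- s_new[which.min(j_excl)]
      if (s_minus == s_star) break
      smaller <- setdiff(s_new, s_minus)
      auc_wo <- cv_auc_fused(block[smaller], n_folds, window_count)
      if (length(smaller) <= length(best_at_size) &&
          auc_wo > best_at_size[length(smaller)]) {
        trace[[length(trace) + 1]] <- list(action = "exclude",
                                           member = s_minus,
                                           J = unname(j_excl),
                                           candidates = s_new,
                                           cv_auc = auc_wo)
        s_new <- smaller
        auc_new <- auc_wo
        best_at_size[length(s_new)] <- auc_wo
      } else break
    }
    if (auc_new <= cur_auc + epsilon) {
      trace[[length(trace) + 1]] <- list(action = "stop",
                                         reason = "no AUC improvement",
                                         rejected = s_new,
                                         cv_auc = auc_new)
      break
    }
    s <- s_new
    cur_auc <- auc_new
    if (length(s) > length(best_at_size) ||
        auc_new > best_at_size[length(s)])
      best_at_size[length(s)] <- auc_new
  }
  structure(list(members = s, cv_auc = cur_auc, mu = mu, trace = trace),
            class = "subgroup")
}

#' @export
print.subgroup <- function(x, ...) {
  cat(sprintf("<subgroup> {%s} cv_auc = %.3f (mu = %.2f, %d trace steps)\n",
              paste(x$members, collapse = ", "), x$cv_auc, x$mu,
              length(x$trace)))
  invisible(x)
}
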