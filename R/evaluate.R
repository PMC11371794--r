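#' @title Metrics and experiment protocols
#' @name cobci-evaluate
#' @description
#' AUC (Mann-Whitney with tie correction), TPR/FPR at the HDCA threshold,
#' and the within-/cross-session evaluation protocol: all selection and
#' training (the MIMC weight, capabilities, HDCA, thresholds, alignment
#' references) use block 1 of the training session only; blocks 2 and 3 of
#' the test session are pooled for testing. Cross-session runs use
#' EA-HDCA.
NULL

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random target trial
#' scores above a random non-target trial, with ties counted one half.
#'
#' @param scores numeric per-trial scores
#' @param labels 0/1 per-trial labels; both classes must be present
#' @return AUC in `[0, 1]`
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("undefined metric: AUC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True and false positive rates
#'
#' @param labels true 0/1 labels
#' @param predicted predicted 0/1 labels
#' @return list with `tpr = TP / (TP + FN)` and `fpr = FP / (FP + TN)`
#' @export
binary_metrics <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  if (!any(labels == 1L))
    stop("undefined metric: TPR needs positive trials", call. = FALSE)
  if (!any(labels == 0L))
    stop("undefined metric: FPR needs negative trials", call. = FALSE)
  list(tpr = sum(predicted == 1L & labels == 1L) / sum(labels == 1L),
       fpr = sum(predicted == 1L & labels == 0L) / sum(labels == 0L))
}

# concatenate trials of several epoched recordings of one subject
concat_trials <- function(epochs_list) {
  if (length(epochs_list) == 1) return(epochs_list[[1]])
  out <- epochs_list[[1]]
  out$data <- do.call(function(...) {
    arrs <- list(...)
    d <- dim(arrs[[1]])
    res <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)),
                      d[2], d[3]))
    at <- 0L
    for (a in arrs) {
      res[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    res
  }, lapply(epochs_list, function(e) e$data))
  out$labels <- unlist(lapply(epochs_list, function(e) e$labels))
  out
}

# polynomial rolling hash of a serialized object, for report provenance
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%010.0f", h)
}

score_one_group <- function(ids, train_block, test_block, fusion_strategy,
                            cross, window_count) {
  if (fusion_strategy == "weighted_vote") {
    per <- lapply(ids, function(m) {
      tr <- train_block[[m]]
      te <- test_block[[m]]
      if (cross) {
        sv <- ea_hdca(tr, te, window_count)
        tr_scores <- hdca_score(sv$model, ea_align(tr, ea_reference(tr)))
        list(test = sv, th = sv$model$threshold,
             w = auc(tr_scores$scores, tr$labels))
      } else {
        model <- hdca_fit(tr, window_count)
        list(test = hdca_score(model, te), th = model$threshold,
             w = auc(hdca_score(model, tr)$scores, tr$labels))
      }
    })
    wv <- weighted_vote(lapply(per, function(p) p$test$scores),
                        vapply(per, function(p) p$th, 0),
                        vapply(per, function(p) p$w, 0))
    list(scores = wv$combined_scores, predicted = wv$labels,
         labels = test_block[[ids[1]]]$labels)
  } else {
    tr <- fuse(train_block[ids], fusion_strategy)
    te <- fuse(test_block[ids], fusion_strategy)
    sv <- if (cross) ea_hdca(tr, te, window_count)
    else hdca_score(hdca_fit(tr, window_count), te)
    list(scores = sv$scores, predicted = sv$labels, labels = te$labels)
  }
}

#' Run a within- or cross-session evaluation protocol
#'
#' @param x a [cohort_index()] or [generate_cohort()] result
#' @param grouping group-member selection mode: `"single"`, `"fixed"`
#'   (members paired in cohort order), `"random"`, `"mimc"`, `"matched"`
#'   (test-set oracle: each user's best test-AUC pair, reported for
#'   comparison only and flagged non-deployable), `"ipd"`, `"bip"`, `"bcp"`,
#'   `"sffs"`, `"all_member"`
#' @param train_session,test_session session indices; when they differ the
#'   protocol is cross-session and EA-HDCA is used
#' @param fusion_strategy `"average_erp"`, `"parallel"`, `"serial"` or
#'   `"weighted_vote"`
#' @param mu MIMC weight; if `NULL` and the grouping needs one, it is chosen
#'   by [optimize_mu()] on the training block with grid step `mu_grid_step`
#' @param mu_grid_step grid step for the `mu` search
#' @param analysis_window half-open analysis crop in ms (default 0-500)
#' @param window_count HDCA window count
#' @param n_folds cross-validation folds for the AUC-based strategies
#' @param epsilon,max_size SFFS parameters (see [sffs_subgroup()])
#' @param seed seed for the random grouping
#' @return object of class `eval_report` with per-group metrics, aggregate
#'   mean/sd, archived per-trial scores, the protocol descriptor, a config
#'   hash and the seed
#' @export
run_protocol <- function(x, grouping = c("single", "fixed", "random", "mimc",
                                         "matched", "ipd", "bip", "bcp",
                                         "sffs", "all_member"),
                         train_session = 1, test_session = 1,
                         fusion_strategy = "average_erp",
                         mu = NULL, mu_grid_step = 0.1,
                         analysis_window = c(0, 500), window_count = 5,
                         n_folds = 5, epsilon = 0, max_size = NULL,
                         seed = 1) {
  grouping <- match.arg(grouping)
  cohort <- if (inherits(x, "sim_cohort")) x$cohort else x
  stopifnot(inherits(cohort, "cohort_index"))
  cross <- train_session != test_session
  members <- cohort$members
  crop <- function(e) {
    if (all(e$window_ms == analysis_window)) e
    else crop_window(e, analysis_window[1], analysis_window[2])
  }
  train_block <- lapply(cohort_block(cohort, train_session, 1), crop)
  blocks_present <- sort(unique(vapply(cohort$recordings,
                                       function(r) r$block_id, 0L)))
  test_blocks <- setdiff(blocks_present, 1L)
  if (length(test_blocks) == 0)
    stop("protocol needs test blocks beyond block 1", call. = FALSE)
  test_block <- stats::setNames(lapply(members, function(m)
    concat_trials(lapply(test_blocks, function(b)
      crop(cohort$recordings[[cohort_key(m, test_session, b)]])))), members)

  needs_mu <- grouping %in% c("mimc", "sffs")
  mu_eff <- if (needs_mu)
    mu %||% optimize_mu(train_block, grid_step = mu_grid_step,
                        n_folds = n_folds,
                        window_count = window_count)$mu_star
  else mu

  eval_group <- function(ids) score_one_group(ids, train_block, test_block,
                                              fusion_strategy, cross,
                                              window_count)
  groups <- switch(grouping,
    single = stats::setNames(lapply(members, identity), members),
    fixed = stats::setNames(lapply(seq_along(members), function(i) {
      partner <- if (i %% 2 == 1) min(i + 1, length(members)) else i - 1
      unique(c(members[i], members[partner]))
    }), members),
    all_member = list(group = members),
    sffs = {
      sg <- sffs_subgroup(train_block, mu_eff, epsilon, max_size, n_folds,
                          window_count)
      list(group = sg$members)
    },
    matched = stats::setNames(lapply(members, function(m) {
      cand <- setdiff(members, m)
      aucs <- vapply(cand, function(j) {
        g <- eval_group(c(m, j))
        auc(g$scores, g$labels)
      }, 0)
      c(m, cand[which.max(aucs)])
    }), members),
    {
      assignments <- match_all(train_block, grouping,
                               mu = mu_eff %||% 0.5, seed = seed,
                               n_folds = n_folds,
                               window_count = window_count)
      stats::setNames(lapply(assignments, function(a)
        c(a$user_id, a$collaborator_id)), members)
    })

  rows <- lapply(names(groups), function(g) {
    res <- eval_group(groups[[g]])
    bm <- binary_metrics(res$labels, res$predicted)
    list(user = g, group = paste(groups[[g]], collapse = "+"),
         auc = auc(res$scores, res$labels), tpr = bm$tpr, fpr = bm$fpr,
         scores = res$scores, labels = res$labels)
  })
  per_user <- do.call(rbind, lapply(rows, function(r)
    data.frame(user = r$user, group = r$group, auc = r$auc, tpr = r$tpr,
               fpr = r$fpr)))
  agg <- list(auc_mean = mean(per_user$auc), auc_sd = stats::sd(per_user$auc),
              tpr_mean = mean(per_user$tpr), tpr_sd = stats::sd(per_user$tpr),
              fpr_mean = mean(per_user$fpr), fpr_sd = stats::sd(per_user$fpr))
  protocol <- list(grouping = grouping, train_session = train_session,
                   test_session = test_session,
                   mode = if (cross) "cross-session" else "within-session",
                   classifier = if (cross) "ea-hdca" else "hdca",
                   fusion_strategy = fusion_strategy, mu = mu_eff,
                   analysis_window = analysis_window,
                   window_count = window_count,
                   test_blocks = test_blocks,
                   test_set_oracle = grouping == "matched")
  structure(list(protocol = protocol, per_user = per_user, aggregate = agg,
                 scores = stats::setNames(lapply(rows, function(r)
                   list(scores = r$scores, labels = r$labels)),
                   per_user$user),
                 seed = seed, config_hash = config_hash(protocol)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("<eval_report> %s, grouping '%s', fusion '%s', S%d-S%d%s\n",
              p$mode, p$grouping, p$fusion_strategy, p$train_session,
              p$test_session,
              if (isTRUE(p$test_set_oracle))
                " [test-set oracle - not deployable]" else ""))
  cat(sprintf("  AUC %.4f (%.4f)  TPR %.4f  FPR %.4f  over %d group(s)\n",
              x$aggregate$auc_mean, x$aggregate$auc_sd %||% NA,
              x$aggregate$tpr_mean, x$aggregate$fpr_mean,
              nrow(x$per_user)))
  invisible(x)
}
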