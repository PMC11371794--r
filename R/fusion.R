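#' @title Multi-user EEG fusion strategies
#' @name cobci-fusion
#' @description
#' Centralized collaborative BCIs fuse members' signals before a single
#' classifier: `average_erp` averages them element-wise, `parallel`
#' concatenates along the channel axis, `serial` along the time axis.
#' Distributed collaboration instead combines per-member classifier outputs
#' by weighted voting ([weighted_vote()]).
NULL

#' Fuse epochs from several members
#'
#' @param epochs_list list of epoched recordings with equal trial counts and
#'   identical label sequences (equal channel and sample counts as each
#'   strategy requires)
#' @param strategy `"average_erp"`, `"parallel"` (channel concatenation) or
#'   `"serial"` (temporal concatenation); members are combined in list order
#' @return object of class `fused_epochs` with fields `data`, `labels`,
#'   `member_ids`, `strategy`, `sample_rate`
#' @export
fuse <- function(epochs_list, strategy = c("average_erp", "parallel",
                                           "serial")) {
  strategy <- match.arg(strategy)
  stopifnot(length(epochs_list) >= 1)
  labs <- epochs_list[[1]]$labels
  for (e in epochs_list) {
    if (!identical(e$labels, labs))
      stop("pairing error: label sequences differ across members",
           call. = FALSE)
    if (dim(e$data)[1] != dim(epochs_list[[1]]$data)[1] ||
        dim(e$data)[3] != dim(epochs_list[[1]]$data)[3])
      stop("pairing error: trial/sample counts differ across members",
           call. = FALSE)
  }
  d1 <- dim(epochs_list[[1]]$data)
  same_ch <- length(unique(vapply(epochs_list,
                                  function(e) dim(e$data)[2], 0L))) == 1
  data <- switch(strategy,
    average_erp = {
      if (!same_ch) stop("average_erp needs equal channel counts",
                         call. = FALSE)
      Reduce(`+`, lapply(epochs_list, function(e) e$data)) /
        length(epochs_list)
    },
    parallel = {
      nc <- vapply(epochs_list, function(e) dim(e$data)[2], 0L)
      out <- array(0, c(d1[1], sum(nc), d1[3]))
      at <- 0L
      for (e in epochs_list) {
        out[, at + seq_len(dim(e$data)[2]), ] <- e$data
        at <- at + dim(e$data)[2]
      }
      out
    },
    serial = {
      if (!same_ch) stop("serial fusion needs equal channel counts",
                         call. = FALSE)
      out <- array(0, c(d1[1], d1[2], d1[3] * length(epochs_list)))
      for (i in seq_along(epochs_list))
        out[, , (i - 1L) * d1[3] + seq_len(d1[3])] <- epochs_list[[i]]$data
      out
    })
  structure(list(data = data, labels = labs,
                 member_ids = vapply(epochs_list,
                                     function(e) e$subject_id %||% "?", ""),
                 strategy = strategy,
                 sample_rate = epochs_list[[1]]$sample_rate),
            class = "fused_epochs")
}

#' @export
print.fused_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fused_epochs> %s of {%s}: %d trials x %d ch x %d samples\n",
              x$strategy, paste(x$member_ids, collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

#' Weighted voting over per-member classifier scores
#'
#' Combines threshold-centred continuous scores:
#' `combined_k = sum_i w_i * (Z_{k,i} - Zth_i) / sum_i w_i`, with predicted
#' label 1 where the combined score exceeds 0. Keeping the scores continuous
#' (rather than hard votes) preserves a ROC/AUC analysis for the distributed
#' mode; the conventional choice weights members by their training AUC.
#'
#' @param member_scores trials x members matrix (or list of equal-length
#'   score vectors)
#' @param member_thresholds per-member decision thresholds
#' @param weights non-negative per-member weights, not all zero
#' @return list with `combined_scores` and 0/1 `labels`
#' @export
weighted_vote <- function(member_scores, member_thresholds, weights) {
  if (is.list(member_scores)) member_scores <- do.call(cbind, member_scores)
  stopifnot(ncol(member_scores) == length(member_thresholds),
            ncol(member_scores) == length(weights), all(weights >= 0))
  if (sum(weights) == 0)
    stop("all-zero vote weights", call. = FALSE)
  centred <- sweep(member_scores, 2, member_thresholds)
  combined <- as.numeric(centred %*% weights) / sum(weights)
  list(combined_scores = combined, labels = as.integer(combined > 0))
}
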