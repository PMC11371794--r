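#' @title Core data containers for collaborative RSVP-BCI analysis
#' @name cobci-core
#' @description
#' The package passes EEG around in three containers: `raw_recording`
#' (continuous channels x samples data with event triggers),
#' `epoched_recording` (a trials x channels x samples array with binary
#' target/non-target labels) and `cohort_index` (all members of a
#' collaborative group, indexed by member, session and block). All sample
#' indices are 0-based and epoch windows are half-open `[start, end)` in
#' milliseconds relative to the trigger, so sample-count arithmetic is exact.
#' Amplitudes are microvolts throughout.
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(field, msg) {
  stop(sprintf("validation error in field '%s': %s", field, msg), call. = FALSE)
}

#' Construct an event table
#'
#' Events mark stimulus onsets in a continuous recording. `onset_sample` is a
#' 0-based index into the data, `label` is 0 (non-target) or 1 (target) and
#' `sequence` identifies the stimulus sequence the presentation belongs to.
#'
#' @param onset_sample integer vector of 0-based sample indices
#' @param label integer vector of 0/1 class labels
#' @param sequence integer vector of sequence indices
#' @return a `data.frame` with columns `onset_sample`, `label`, `sequence`
#' @export
event_table <- function(onset_sample, label, sequence) {
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   label = as.integer(label),
                   sequence = as.integer(sequence))
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  if (!is.data.frame(ev) ||
      !all(c("onset_sample", "label", "sequence") %in% names(ev)))
    stop_validation("events", "need columns onset_sample, label, sequence")
  if (nrow(ev) > 0) {
    if (any(ev$onset_sample < 0))
      stop_validation("onset_sample", "must be >= 0")
    if (!all(ev$label %in% c(0L, 1L)))
      stop_validation("label", "must be 0 or 1")
  }
  invisible(ev)
}

#' Construct a continuous (raw) recording
#'
#' @param data numeric matrix, channels x samples, in microvolts
#' @param sample_rate sampling rate in Hz
#' @param events event table (see [event_table()])
#' @param channel_labels character vector, one label per data row
#' @param subject_id,session_id,block_id identifiers
#' @return object of class `raw_recording`
#' @export
raw_recording <- function(data, sample_rate, events, channel_labels = NULL,
                          subject_id = "s1", session_id = 1L, block_id = 1L) {
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  x <- structure(list(subject_id = as.character(subject_id),
                      session_id = as.integer(session_id),
                      block_id = as.integer(block_id),
                      sample_rate = as.numeric(sample_rate),
                      channel_labels = as.character(channel_labels),
                      data = data, events = events),
                 class = "raw_recording")
  validate_raw_recording(x)
  x
}

validate_raw_recording <- function(x) {
  if (!is.matrix(x$data) || !is.numeric(x$data))
    stop_validation("data", "must be a numeric channels x samples matrix")
  if (nrow(x$data) != length(x$channel_labels))
    stop_validation("channel_labels",
                    sprintf("%d labels for %d data rows",
                            length(x$channel_labels), nrow(x$data)))
  if (!is.numeric(x$sample_rate) || length(x$sample_rate) != 1 ||
      x$sample_rate <= 0)
    stop_validation("sample_rate", "must be a single positive number")
  validate_events(x$events)
  if (nrow(x$events) > 0 && any(x$events$onset_sample >= ncol(x$data)))
    stop_validation("events", "event onset beyond end of data")
  invisible(x)
}

#' Construct an epoched recording
#'
#' @param data numeric array, trials x channels x samples, in microvolts
#' @param labels integer vector of per-trial 0/1 labels
#' @param sample_rate sampling rate in Hz
#' @param window_ms numeric length-2, epoch window `[start, end)` in ms
#'   relative to the trigger
#' @param channel_labels character vector of channel names
#' @param subject_id,session_id,block_id identifiers
#' @return object of class `epoched_recording`
#' @export
epoched_recording <- function(data, labels, sample_rate, window_ms,
                              channel_labels = NULL,
                              subject_id = "s1", session_id = 1L,
                              block_id = 1L) {
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(dim(data)[2]))
  x <- structure(list(subject_id = as.character(subject_id),
                      session_id = as.integer(session_id),
                      block_id = as.integer(block_id),
                      data = data, labels = as.integer(labels),
                      sample_rate = as.numeric(sample_rate),
                      window_ms = as.numeric(window_ms),
                      channel_labels = as.character(channel_labels)),
                 class = "epoched_recording")
  validate_epoched_recording(x)
  x
}

validate_epoched_recording <- function(x) {
  d <- dim(x$data)
  if (!is.array(x$data) || length(d) != 3)
    stop_validation("data", "must be a trials x channels x samples array")
  if (length(x$labels) != d[1])
    stop_validation("labels", sprintf("%d labels for %d trials",
                                      length(x$labels), d[1]))
  if (length(x$labels) > 0 && !all(x$labels %in% c(0L, 1L)))
    stop_validation("labels", "must be 0 or 1")
  if (length(x$window_ms) != 2 || x$window_ms[2] <= x$window_ms[1])
    stop_validation("window_ms", "must be (start, end) with end > start")
  n_expected <- round(diff(x$window_ms) / 1000 * x$sample_rate)
  if (d[3] != n_expected)
    stop_validation("data", sprintf(
      "%d samples but window %g..%g ms at %g Hz implies %d",
      d[3], x$window_ms[1], x$window_ms[2], x$sample_rate, n_expected))
  if (d[2] != length(x$channel_labels))
    stop_validation("channel_labels", "length must equal channel count")
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Construct a cohort index
#'
#' Indexes one [epoched_recording()] per (member, session, block). All members
#' must be present for every indexed (session, block), with a common sampling
#' rate, epoch window and per-(session, block) trial count, because
#' collaborative fusion pairs trials one-to-one across members.
#'
#' @param members character vector of unique member ids (canonical order)
#' @param recordings named list of `epoched_recording`, names
#'   `"member|session|block"` (see [cohort_key()])
#' @return object of class `cohort_index`
#' @export
cohort_index <- function(members, recordings) {
  x <- structure(list(members = as.character(members),
                      recordings = recordings),
                 class = "cohort_index")
  validate_cohort_index(x)
  x
}

#' @rdname cohort_index
#' @param member,session,block index components
#' @export
cohort_key <- function(member, session, block) {
  paste(member, session, block, sep = "|")
}

validate_cohort_index <- function(x) {
  if (anyDuplicated(x$members))
    stop_validation("members", "member ids must be unique")
  for (r in x$recordings) validate_epoched_recording(r)
  sb <- unique(do.call(rbind, lapply(x$recordings, function(r)
    data.frame(session = r$session_id, block = r$block_id))))
  for (i in seq_len(nrow(sb))) {
    keys <- cohort_key(x$members, sb$session[i], sb$block[i])
    if (!all(keys %in% names(x$recordings)))
      stop_validation("recordings", sprintf(
        "missing members for session %d block %d", sb$session[i], sb$block[i]))
    recs <- x$recordings[keys]
    if (length(unique(vapply(recs, function(r) r$sample_rate, 0))) != 1)
      stop_validation("sample_rate", "must be shared across the cohort")
    if (length(unique(vapply(recs, n_trials, 0L))) != 1)
      stop_validation("recordings", sprintf(
        "trial counts differ within session %d block %d",
        sb$session[i], sb$block[i]))
    wins <- vapply(recs, function(r) r$window_ms, numeric(2))
    if (any(wins != wins[, 1]))
      stop_validation("window_ms", "must be shared across the cohort")
  }
  invisible(x)
}

#' Extract one (session, block) slice of a cohort
#'
#' @param cohort a [cohort_index()]
#' @param session,block which slice
#' @return named list of `epoched_recording`, one per member, in cohort order
#' @export
cohort_block <- function(cohort, session, block) {
  keys <- cohort_key(cohort$members, session, block)
  missing <- setdiff(keys, names(cohort$recordings))
  if (length(missing) > 0)
    stop(sprintf("cohort has no recordings for session %s block %s",
                 session, block), call. = FALSE)
  stats::setNames(cohort$recordings[keys], cohort$members)
}

.container_validators <- list(
  raw_recording = validate_raw_recording,
  epoched_recording = validate_epoched_recording,
  cohort_index = validate_cohort_index
)

#' Write a recording or cohort to a single-file container
#'
#' The container is a self-describing single file (R serialization of a tagged
#' list carrying the object plus format/version metadata). Reading back a
#' written container reproduces the object bit-exactly; all container
#' invariants are validated both before writing and after reading.
#'
#' @param x a `raw_recording`, `epoched_recording` or `cohort_index`
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [read_container()]
#' @export
write_container <- function(x, path) {
  type <- intersect(class(x), names(.container_validators))
  if (length(type) != 1)
    stop("x must be a raw_recording, epoched_recording or cohort_index",
         call. = FALSE)
  .container_validators[[type]](x)
  saveRDS(list(format = "cobci_container", container_version = 1L,
               type = type, object = x),
          path, compress = FALSE)
  invisible(path)
}

#' Read a container written by [write_container()]
#'
#' @param path file path
#' @return the stored object, re-validated
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("format error reading '%s': not a readable container (%s)",
                 path, conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "cobci_container"))
    stop(sprintf("format error reading '%s': missing or wrong 'format' tag",
                 path), call. = FALSE)
  if (!obj$type %in% names(.container_validators))
    stop(sprintf("format error reading '%s': unknown container type '%s'",
                 path, obj$type), call. = FALSE)
  .container_validators[[obj$type]](obj$object)
  obj$object
}

#' Read / write an events CSV
#'
#' The on-disk event format is a CSV with header `onset_ms,label,sequence`,
#' onsets in milliseconds from the start of the recording.
#'
#' @param path CSV path
#' @return `read_events_csv`: a data.frame with columns `onset_ms`, `label`,
#'   `sequence`
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("onset_ms", "label", "sequence") %in% names(ev)))
    stop(sprintf("format error in '%s': need header onset_ms,label,sequence",
                 path), call. = FALSE)
  if (nrow(ev) > 0 && !all(ev$label %in% c(0, 1)))
    stop_validation("label", "must be 0 or 1")
  ev
}

#' @rdname read_events_csv
#' @param events data.frame with columns `onset_ms`, `label`, `sequence`
#' @export
write_events_csv <- function(events, path) {
  stopifnot(all(c("onset_ms", "label", "sequence") %in% names(events)))
  utils::write.csv(events[c("onset_ms", "label", "sequence")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert millisecond event onsets to a sample-indexed event table
#'
#' @param events data.frame with `onset_ms`, `label`, `sequence`
#' @param sample_rate Hz
#' @return event table as from [event_table()]
#' @export
events_to_samples <- function(events, sample_rate) {
  event_table(round(events$onset_ms / 1000 * sample_rate),
              events$label, events$sequence)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s session %d block %d: %d ch x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$session_id, x$block_id, nrow(x$data),
              ncol(x$data), x$sample_rate, nrow(x$events)))
  invisible(x)
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> subject %s session %d block %d: %d trials x %d ch x %d samples @ %g Hz, window [%g, %g) ms, %d targets\n",
              x$subject_id, x$session_id, x$block_id, n_trials(x),
              n_channels(x), n_samples(x), x$sample_rate, x$window_ms[1],
              x$window_ms[2], sum(x$labels == 1L)))
  invisible(x)
}

#' @export
print.cohort_index <- function(x, ...) {
  cat(sprintf("<cohort_index> %d members, %d recordings\n",
              length(x$members), length(x$recordings)))
  invisible(x)
}
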