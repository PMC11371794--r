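#' @title Preprocessing chain for RSVP EEG
#' @name cobci-preprocess
#' @description
#' The standard single-trial ERP chain: down-sample to 250 Hz, segment into
#' [-200, 1000) ms epochs around each trigger, zero-phase band-pass at
#' 2-30 Hz, common average reference, and crop to the 0-500 ms analysis
#' window. All filtering is zero-phase (forward-backward 4th-order
#' Butterworth), so ERP latencies are not shifted.
NULL

# Zero-phase IIR filtering of many equal-length signals at once.
# x: samples x signals matrix. Signals are reflection-padded, the squared
# magnitude response |H(w)|^2 of (b, a) is applied in the frequency domain
# (identical in effect to forward-backward filtering, without direction-
# dependent edge transients), and the pad removed.
zero_phase_filter <- function(x, b, a, pad = NULL) {
  x <- as.matrix(x)
  ns <- nrow(x)
  if (is.null(pad)) pad <- min(ns - 1L, 3L * ns %/% 4L)
  ref_top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[pad:1 + 1L, , drop = FALSE]
  ref_bot <- 2 * x[rep(ns, pad), , drop = FALSE] -
    x[ns - seq_len(pad), , drop = FALSE]
  n_tot <- ns + 2L * pad
  w <- 2 * pi * (seq_len(n_tot) - 1L) / n_tot
  z <- exp(-1i * outer(w, seq_along(b) - 1L))
  h2 <- as.numeric(Mod(z %*% b)^2 /
                     Mod(z[, seq_along(a), drop = FALSE] %*% a)^2)
  out <- matrix(0, ns, ncol(x))
  chunk <- max(1L, 2e6 %/% n_tot)
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    jj <- j0:min(ncol(x), j0 + chunk - 1L)
    xp <- rbind(ref_top[, jj, drop = FALSE], x[, jj, drop = FALSE],
                ref_bot[, jj, drop = FALSE])
    y <- Re(stats::mvfft(stats::mvfft(xp) * h2, inverse = TRUE)) / n_tot
    out[, jj] <- y[pad + seq_len(ns), , drop = FALSE]
  }
  out
}

#' Down-sample a continuous recording
#'
#' Integer decimation preceded by a zero-phase anti-alias low-pass at 0.8x
#' the target Nyquist frequency. Event onsets are rescaled to the new rate.
#'
#' @param raw a [raw_recording()]
#' @param target_rate new sampling rate in Hz; must divide `sample_rate`
#' @return a [raw_recording()] at `target_rate`
#' @export
downsample <- function(raw, target_rate = 250) {
  validate_raw_recording(raw)
  factor <- raw$sample_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf(
      "non-integer decimation factor %.3f; nearest valid target rate is %g Hz",
      factor, raw$sample_rate / round(factor)), call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(raw)
  bf <- signal::butter(4, 0.8 * (target_rate / 2) / (raw$sample_rate / 2),
                       type = "low")
  filtered <- t(zero_phase_filter(t(raw$data), bf$b, bf$a))
  keep <- seq(1L, ncol(raw$data), by = factor)
  raw_recording(filtered[, keep, drop = FALSE], target_rate,
                event_table(raw$events$onset_sample %/% factor,
                            raw$events$label, raw$events$sequence),
                raw$channel_labels, raw$subject_id, raw$session_id,
                raw$block_id)
}

#' Segment a continuous recording into epochs
#'
#' One epoch per event, covering the half-open window `[tmin_ms, tmax_ms)`
#' relative to the trigger.
#'
#' @param raw a [raw_recording()]
#' @param tmin_ms,tmax_ms epoch window in ms relative to the trigger
#' @return an [epoched_recording()]
#' @export
segment <- function(raw, tmin_ms = -200, tmax_ms = 1000) {
  validate_raw_recording(raw)
  n_ep <- round((tmax_ms - tmin_ms) / 1000 * raw$sample_rate)
  start <- raw$events$onset_sample + round(tmin_ms / 1000 * raw$sample_rate)
  bad <- which(start < 0 | start + n_ep > ncol(raw$data))
  if (length(bad) > 0)
    stop(sprintf("epochs exceed data bounds for events: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  dat <- array(0, c(nrow(raw$events), nrow(raw$data), n_ep))
  for (k in seq_len(nrow(raw$events)))
    dat[k, , ] <- raw$data[, start[k] + seq_len(n_ep), drop = FALSE]
  epoched_recording(dat, raw$events$label, raw$sample_rate,
                    c(tmin_ms, tmax_ms), raw$channel_labels,
                    raw$subject_id, raw$session_id, raw$block_id)
}

#' Zero-phase band-pass filter epochs
#'
#' @param epochs an [epoched_recording()]
#' @param low_hz,high_hz pass-band edges in Hz
#' @return filtered [epoched_recording()], same shape
#' @export
bandpass <- function(epochs, low_hz = 2, high_hz = 30) {
  validate_epoched_recording(epochs)
  nyq <- epochs$sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("invalid band %g-%g Hz for Nyquist %g Hz",
                 low_hz, high_hz, nyq), call. = FALSE)
  d <- dim(epochs$data)
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  out <- zero_phase_filter(flat, bf$b, bf$a)
  epochs$data <- aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, per
#' trial and sample. Idempotent; requires at least two channels (with one
#' channel it would zero the data).
#'
#' @param epochs an [epoched_recording()]
#' @return re-referenced [epoched_recording()]
#' @export
rereference_car <- function(epochs) {
  validate_epoched_recording(epochs)
  if (dim(epochs$data)[2] < 2)
    stop("common average reference needs at least 2 channels", call. = FALSE)
  means <- apply(epochs$data, c(1, 3), mean)  # trials x samples
  epochs$data <- epochs$data -
    aperm(array(means, c(dim(means), dim(epochs$data)[2])), c(1, 3, 2))
  epochs
}

#' Crop epochs to a sub-window
#'
#' @param epochs an [epoched_recording()]
#' @param start_ms,end_ms half-open sub-window `[start, end)` in ms relative
#'   to the trigger; must lie within the epoch window
#' @return cropped [epoched_recording()]
#' @export
crop_window <- function(epochs, start_ms = 0, end_ms = 500) {
  validate_epoched_recording(epochs)
  if (start_ms < epochs$window_ms[1] || end_ms > epochs$window_ms[2] ||
      end_ms <= start_ms)
    stop(sprintf("crop window [%g, %g) outside epoch window [%g, %g)",
                 start_ms, end_ms, epochs$window_ms[1], epochs$window_ms[2]),
         call. = FALSE)
  i0 <- round((start_ms - epochs$window_ms[1]) / 1000 * epochs$sample_rate)
  n <- round((end_ms - start_ms) / 1000 * epochs$sample_rate)
  epochs$data <- epochs$data[, , i0 + seq_len(n), drop = FALSE]
  epochs$window_ms <- c(start_ms, end_ms)
  epochs
}

#' Run the full preprocessing chain on one block
#'
#' Composition down-sample -> segment -> band-pass -> common average
#' reference, with defaults 250 Hz, [-200, 1000) ms, 2-30 Hz. The 0-500 ms
#' analysis crop is applied separately at analysis time (see
#' [crop_window()]).
#'
#' @param raw a [raw_recording()]
#' @param target_rate,tmin_ms,tmax_ms,low_hz,high_hz stage parameters
#' @return an [epoched_recording()]
#' @export
preprocess_block <- function(raw, target_rate = 250, tmin_ms = -200,
                             tmax_ms = 1000, low_hz = 2, high_hz = 30) {
  raw |>
    downsample(target_rate) |>
    segment(tmin_ms, tmax_ms) |>
    bandpass(low_hz, high_hz) |>
    rereference_car()
}
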