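#' @title Synthetic multi-subject RSVP EEG
#' @name cobci-simdata
#' @description
#' Generates cohorts of synthetic RSVP EEG with planted ground truth: each
#' subject has a known ERP amplitude (individual signal strength), a known
#' mixing weight between a shared P300-like template and an idiosyncratic
#' waveform (inter-subject ERP similarity), and a known rank-1 scalp
#' topography. Session 2 data pass through a near-identity channel mixing so
#' cross-session alignment has a controlled covariance shift to remove.
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate an RSVP stimulus schedule
#'
#' Images are presented back-to-back at `rate_hz` in `n_sequences` contiguous
#' sequences of `images_per_sequence` presentations each. Every sequence
#' contains exactly `targets_per_sequence` target presentations, placed
#' uniformly at random among the placements that keep consecutive target
#' onsets (including across sequence boundaries) at least `min_target_gap_ms`
#' apart.
#'
#' @param n_sequences number of stimulus sequences
#' @param images_per_sequence presentations per sequence
#' @param targets_per_sequence target presentations per sequence
#' @param rate_hz presentation rate (presentations per second)
#' @param min_target_gap_ms minimum onset-to-onset gap between consecutive
#'   targets, in ms
#' @param seed integer RNG seed
#' @return object of class `stimulus_schedule` with an `events` data.frame
#'   (`onset_ms`, `label`, `sequence`)
#' @export
generate_schedule <- function(n_sequences = 14, images_per_sequence = 100,
                              targets_per_sequence = 4, rate_hz = 10,
                              min_target_gap_ms = 500, seed = 1) {
  step_ms <- round(1000 / rate_hz)
  gap_steps <- round(min_target_gap_ms * rate_hz / 1000)
  if (targets_per_sequence * gap_steps > images_per_sequence)
    stop(sprintf(
      "infeasible schedule: %d targets with a %d-presentation gap do not fit in %d presentations",
      targets_per_sequence, gap_steps, images_per_sequence), call. = FALSE)
  with_seed(seed, {
    labels <- integer(n_sequences * images_per_sequence)
    prev_last <- -Inf  # global index of last target in preceding sequences
    for (s in seq_len(n_sequences) - 1L) {
      if (targets_per_sequence == 0) next
      base <- s * images_per_sequence
      for (it in seq_len(100000)) {
        pos <- sort(sample.int(images_per_sequence, targets_per_sequence) - 1L)
        ok <- all(diff(pos) >= gap_steps) &&
          (base + pos[1] - prev_last) >= gap_steps
        if (ok) break
        if (it == 100000)
          stop("infeasible schedule: no valid target placement found",
               call. = FALSE)
      }
      labels[base + pos + 1L] <- 1L
      prev_last <- base + pos[targets_per_sequence]
    }
    idx <- seq_len(n_sequences * images_per_sequence) - 1L
    structure(list(
      events = data.frame(onset_ms = idx * step_ms, label = labels,
                          sequence = idx %/% images_per_sequence),
      rate_hz = rate_hz, step_ms = step_ms,
      n_sequences = n_sequences,
      images_per_sequence = images_per_sequence,
      targets_per_sequence = targets_per_sequence,
      min_target_gap_ms = min_target_gap_ms),
      class = "stimulus_schedule")
  })
}

#' Simulation configuration
#'
#' Defaults reproduce the cross-session collaborative RSVP protocol the
#' package targets: 14 subjects, 62 channels at 1000 Hz, 2 sessions of 3
#' blocks, each block 14 sequences of 100 images at 10 Hz with 4 targets per
#' sequence and a 500 ms minimum target gap.
#'
#' @param n_subjects,n_channels,sample_rate,n_sessions,n_blocks cohort shape
#' @param n_sequences,images_per_sequence,targets_per_sequence,rate_hz,min_target_gap_ms
#'   schedule parameters (see [generate_schedule()])
#' @param lead_in_ms,tail_ms silence before the first / after the last
#'   presentation, so epochs fit inside the continuous data
#' @param erp_amplitude_range range of per-subject ERP peak-channel
#'   amplitudes (uV); ignored if `erp_amplitudes` gives explicit values
#' @param shared_weight_range range of per-subject shared-template weights in
#'   `[0, 1]`; ignored if `shared_weights` gives explicit values
#' @param erp_amplitudes,shared_weights optional explicit per-subject values
#' @param topo_var relative weight of the subject-specific topography
#'   component mixed into the shared base topography (0 = identical
#'   topographies for all subjects)
#' @param topographies optional explicit channels x subjects topography
#'   matrix (columns are normalized to unit Euclidean norm)
#' @param noise_scale background EEG RMS per channel (uV)
#' @param pink_fraction fraction of noise power with a 1/f spectrum (rest is
#'   white)
#' @param spatial_corr_length e-folding length (in channel index) of the
#'   inter-channel noise correlation
#' @param session_gain_strength spectral norm of the random perturbation added
#'   to the identity to form each subject's session-2 channel mixing
#' @param session_noise_factor session-2 noise RMS multiplier
#' @param preprocess logical; if `TRUE` (default) apply the standard chain
#'   (down-sample to `target_rate`, segment, band-pass, common average
#'   reference) to produce the epoched cohort; if `FALSE` epochs are plain
#'   segments of the unfiltered data at the native rate
#' @param target_rate,tmin_ms,tmax_ms,low_hz,high_hz preprocessing parameters
#' @param seed master seed; the whole cohort is a deterministic function of
#'   the configuration including this seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_subjects = 14, n_channels = 62, sample_rate = 1000,
                       n_sessions = 2, n_blocks = 3,
                       n_sequences = 14, images_per_sequence = 100,
                       targets_per_sequence = 4, rate_hz = 10,
                       min_target_gap_ms = 500,
                       lead_in_ms = 1000, tail_ms = 1500,
                       erp_amplitude_range = c(8, 20),
                       shared_weight_range = c(0.3, 0.9),
                       erp_amplitudes = NULL, shared_weights = NULL,
                       topo_var = 0.2, topographies = NULL,
                       noise_scale = 12, pink_fraction = 0.7,
                       spatial_corr_length = 3,
                       session_gain_strength = 0.25,
                       session_noise_factor = 1.2,
                       preprocess = TRUE, target_rate = 250,
                       tmin_ms = -200, tmax_ms = 1000,
                       low_hz = 2, high_hz = 30, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, n_channels >= 1, n_sessions >= 1, n_blocks >= 1,
            sample_rate > 0, noise_scale >= 0,
            pink_fraction >= 0, pink_fraction <= 1)
  if (!is.null(cfg$erp_amplitudes))
    stopifnot(length(cfg$erp_amplitudes) == n_subjects)
  if (!is.null(cfg$shared_weights))
    stopifnot(length(cfg$shared_weights) == n_subjects,
              all(cfg$shared_weights >= 0), all(cfg$shared_weights <= 1))
  structure(cfg, class = "sim_config")
}

# Shared P300-like template on 0..600 ms after onset: positive peak at
# 300 ms (sd 35 ms) preceded by a smaller negative deflection at 200 ms
# (sd 25 ms). Scaled to unit peak so erp_amplitude is the peak in uV.
erp_shared_template <- function(sample_rate, duration_ms = 600) {
  t_ms <- (seq_len(round(duration_ms / 1000 * sample_rate)) - 1) /
    sample_rate * 1000
  p <- exp(-(t_ms - 300)^2 / (2 * 35^2)) -
    0.4 * exp(-(t_ms - 200)^2 / (2 * 25^2))
  p / max(abs(p))
}

# Smooth unit-matched idiosyncratic waveform, orthogonal to the shared
# template so inter-subject ERP correlation is governed by w_s * w_s'.
# Supported on the first 500 ms (the analysis window), like the shared
# template, so the in-window ERP energy does not depend on the
# shared/idiosyncratic split.
erp_idio_waveform <- function(shared, sample_rate, idio_seed) {
  n <- length(shared)
  n_sup <- min(n, round(0.5 * sample_rate))
  with_seed(idio_seed, {
    z <- stats::rnorm(n + 400)
    smooth_g <- function(x, sd_s) {
      k_sd <- sd_s * sample_rate
      kern <- stats::dnorm(seq(-3 * k_sd, 3 * k_sd), sd = k_sd)
      stats::filter(x, kern / sum(kern), sides = 2)
    }
    # band-limited (roughly 2-8 Hz, like the shared template) so the
    # preprocessing band-pass removes a comparable energy fraction
    # whatever the shared/idiosyncratic split
    q <- smooth_g(z, 0.02) - smooth_g(z, 0.08)
    q <- as.numeric(q[201:(200 + n)])
    taper <- c((sin(pi * (seq_len(n_sup) - 0.5) / n_sup))^2,
               rep(0, n - n_sup))
    q <- q * taper
    q <- q - sum(q * shared) / sum(shared * shared) * shared
    q / sqrt(sum(q^2)) * sqrt(sum(shared^2))
  })
}

# channels x samples unit-RMS noise with 1/f + white spectrum and
# exponentially decaying inter-channel correlation
make_noise <- function(n_channels, n_samples, sample_rate, pink_fraction,
                       spatial_corr_length) {
  white <- matrix(stats::rnorm(n_channels * n_samples), n_channels)
  pink <- white
  if (pink_fraction > 0) {
    f <- c(1, seq_len(n_samples - 1))  # DC bin reused, negligible
    f <- pmin(f, n_samples - f + 1)
    amp <- 1 / sqrt(pmax(f / n_samples * sample_rate, 0.5))
    ft <- t(stats::mvfft(t(white)))
    pink <- Re(t(stats::mvfft(t(ft * rep(amp, each = n_channels)),
                              inverse = TRUE))) / n_samples
    pink <- pink / apply(pink, 1, stats::sd)
  }
  z <- sqrt(pink_fraction) * pink +
    sqrt(1 - pink_fraction) * matrix(stats::rnorm(n_channels * n_samples),
                                     n_channels)
  z <- z / apply(z, 1, stats::sd)
  if (n_channels > 1 && spatial_corr_length > 0) {
    idx <- seq_len(n_channels)
    C <- exp(-abs(outer(idx, idx, "-")) / spatial_corr_length)
    z <- t(chol(C)) %*% z
  }
  z
}

# near-identity invertible channel mixing with spectral perturbation `strength`
make_session_gain <- function(n_channels, strength) {
  B <- matrix(stats::rnorm(n_channels^2), n_channels)
  B <- B / norm(B, "2") * strength
  G <- diag(n_channels) + B
  stopifnot(kappa(G, exact = FALSE) <= 100)
  G
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Each subject's target trials carry the rank-1 ERP
#' `a_s * (w_s * p(t) + (1 - w_s) * q_s(t))` on their scalp topography, where
#' `p` is the shared P300-like template and `q_s` a subject-specific smooth
#' waveform orthogonal to `p`; non-target trials carry noise only. All
#' subjects in a block share one stimulus schedule (pseudo-collaboration).
#' Session 2 data are passed through a near-identity channel mixing and a
#' noise-scale change, the covariance-shift class Euclidean alignment removes.
#'
#' @param config a [sim_config()]
#' @param raw if `TRUE`, also return the continuous recordings (nested list
#'   `raw[[subject]][[session]][[block]]`)
#' @return object of class `sim_cohort`: a list with elements `cohort`
#'   (a [cohort_index()] of epoched recordings), `profiles` (data.frame of
#'   planted per-subject ground truth), `topographies` (channels x subjects),
#'   `transforms` (per-subject session gains), `schedules`
#'   (`schedules[[session]][[block]]`) and `config`
#' @export
generate_cohort <- function(config, raw = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  members <- sprintf("s%02d", seq_len(cfg$n_subjects))
  # deterministic sub-seed table drawn from the master seed
  n_seeds <- 4 + cfg$n_subjects * 3 + cfg$n_sessions * cfg$n_blocks +
    cfg$n_subjects * cfg$n_sessions * cfg$n_blocks
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max, n_seeds))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  s_amp <- next_seed()
  amp <- cfg$erp_amplitudes %||% with_seed(s_amp, stats::runif(
    cfg$n_subjects, cfg$erp_amplitude_range[1], cfg$erp_amplitude_range[2]))
  s_w <- next_seed()
  w <- cfg$shared_weights %||% with_seed(s_w, stats::runif(
    cfg$n_subjects, cfg$shared_weight_range[1], cfg$shared_weight_range[2]))

  shared <- erp_shared_template(cfg$sample_rate)
  idio_seeds <- integer(cfg$n_subjects)
  topo <- matrix(0, cfg$n_channels, cfg$n_subjects)
  gains <- vector("list", cfg$n_subjects)
  # Shared base topography: a two-lobe (positive/negative) pattern, roughly
  # zero-mean so the common average reference preserves it; every subject's
  # ERP topography is stereotyped around it (as P300 topographies are), with
  # a smooth subject-specific deviation of relative weight topo_var.
  ch <- seq_len(cfg$n_channels)
  base_topo <- {
    width <- max(1.5, cfg$n_channels / 8)
    v <- exp(-(ch - 0.65 * cfg$n_channels)^2 / (2 * width^2)) -
      exp(-(ch - 0.30 * cfg$n_channels)^2 / (2 * (1.4 * width)^2))
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  for (m in seq_len(cfg$n_subjects)) {
    idio_seeds[m] <- next_seed()
    topo[, m] <- with_seed(next_seed(), {
      if (!is.null(cfg$topographies)) {
        v <- cfg$topographies[, m]
        if (length(v) != cfg$n_channels)
          stop("topography length does not match channel count",
               call. = FALSE)
      } else {
        dev <- stats::rnorm(cfg$n_channels)
        if (cfg$n_channels > 2)
          dev <- stats::filter(dev, rep(1 / 3, 3), sides = 2,
                               circular = TRUE)
        dev <- dev - mean(dev)
        dev <- dev / sqrt(sum(dev^2))
        v <- base_topo + cfg$topo_var * dev
      }
      v / sqrt(sum(v^2))
    })
    gains[[m]] <- with_seed(next_seed(),
                            make_session_gain(cfg$n_channels,
                                              cfg$session_gain_strength))
  }
  idio <- lapply(seq_len(cfg$n_subjects), function(m)
    erp_idio_waveform(shared, cfg$sample_rate, idio_seeds[m]))

  schedules <- lapply(seq_len(cfg$n_sessions), function(se)
    lapply(seq_len(cfg$n_blocks), function(b)
      generate_schedule(cfg$n_sequences, cfg$images_per_sequence,
                        cfg$targets_per_sequence, cfg$rate_hz,
                        cfg$min_target_gap_ms, seed = next_seed())))

  step_samp <- round(round(1000 / cfg$rate_hz) / 1000 * cfg$sample_rate)
  n_images <- cfg$n_sequences * cfg$images_per_sequence
  lead <- round(cfg$lead_in_ms / 1000 * cfg$sample_rate)
  n_cont <- lead + n_images * step_samp +
    round(cfg$tail_ms / 1000 * cfg$sample_rate)

  recordings <- list()
  raw_out <- if (raw) stats::setNames(vector("list", cfg$n_subjects), members)
  # reference pattern energy: base topography at unit peak x shared template;
  # every subject's planted pattern is scaled to this energy per uV of
  # erp_amplitude, so amplitude is the *only* planted energy factor and for
  # the base topography with w = 1 the peak-channel peak equals erp_amplitude
  ref_energy <- sqrt(sum((base_topo / max(abs(base_topo)))^2) *
                       sum(shared^2))
  for (m in seq_len(cfg$n_subjects)) {
    mix <- w[m] * shared + (1 - w[m]) * idio[[m]]
    erp_block <- topo[, m, drop = FALSE] %*% matrix(mix, nrow = 1)
    erp_block <- amp[m] * ref_energy * erp_block /
      sqrt(sum(erp_block^2))
    for (se in seq_len(cfg$n_sessions)) for (b in seq_len(cfg$n_blocks)) {
      sched <- schedules[[se]][[b]]
      onset_samp <- lead + round(sched$events$onset_ms / 1000 *
                                   cfg$sample_rate)
      s_noise <- next_seed()
      dat <- matrix(0, cfg$n_channels, n_cont)
      if (cfg$noise_scale > 0)
        dat <- cfg$noise_scale *
          (if (se >= 2) cfg$session_noise_factor else 1) *
          with_seed(s_noise,
                    make_noise(cfg$n_channels, n_cont, cfg$sample_rate,
                               cfg$pink_fraction, cfg$spatial_corr_length))
      L <- ncol(erp_block)
      for (k in which(sched$events$label == 1L)) {
        j <- onset_samp[k] + seq_len(L)
        dat[, j] <- dat[, j] + erp_block
      }
      if (se >= 2) dat <- gains[[m]] %*% dat
      rr <- raw_recording(dat, cfg$sample_rate,
                          event_table(onset_samp, sched$events$label,
                                      sched$events$sequence),
                          subject_id = members[m], session_id = se,
                          block_id = b)
      if (raw) raw_out[[members[m]]][[se]][[b]] <- rr
      ep <- if (cfg$preprocess)
        preprocess_block(rr, target_rate = cfg$target_rate,
                         tmin_ms = cfg$tmin_ms, tmax_ms = cfg$tmax_ms,
                         low_hz = cfg$low_hz, high_hz = cfg$high_hz)
      else segment(rr, cfg$tmin_ms, cfg$tmax_ms)
      recordings[[cohort_key(members[m], se, b)]] <- ep
    }
  }

  structure(list(
    cohort = cohort_index(members, recordings),
    profiles = data.frame(member_id = members, erp_amplitude = amp,
                          shared_weight = w, idio_seed = idio_seeds),
    topographies = topo,
    transforms = lapply(seq_len(cfg$n_subjects), function(m)
      list(gain = gains[[m]],
           noise_scale = cfg$noise_scale * cfg$session_noise_factor)),
    schedules = schedules,
    raw = if (raw) raw_out,
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects x %d sessions x %d blocks, %d ch\n",
              x$config$n_subjects, x$config$n_sessions, x$config$n_blocks,
              x$config$n_channels))
  invisible(x)
}
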