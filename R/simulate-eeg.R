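#' Construct an EEG recording object
#'
#' Light container for a multichannel recording: a channels-by-samples signal
#' matrix in microvolts plus identifiers and the true PMA. Synthetic
#' recordings additionally carry the generative burst log (`truth_bursts`)
#' and artefact log (`truth_artefacts`), both tibbles of half-open
#' `[start, end)` intervals in seconds.
#'
#' @param signal Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling frequency (Hz).
#' @param channel_labels Character vector, one label per row of `signal`.
#' @param infant_id,recording_id Identifiers.
#' @param pma_weeks True postmenstrual age in weeks (22-44), or `NA`.
#' @param truth_bursts,truth_artefacts Optional interval tibbles
#'   (`start`, `end` in seconds).
#' @param annotations Character vector of free-form flags.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels,
                          infant_id = NA_character_,
                          recording_id = NA_character_,
                          pma_weeks = NA_real_,
                          truth_bursts = NULL,
                          truth_artefacts = NULL,
                          annotations = character()) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (fs <= 0) stop_input("fs must be > 0")
  if (length(channel_labels) != nrow(signal))
    stop_input("one channel label per signal row is required")
  if (!is.na(pma_weeks) && (pma_weeks < 22 || pma_weeks > 44))
    stop_domain("pma_weeks must lie in [22, 44]")
  rownames(signal) <- channel_labels
  structure(list(
    infant_id = infant_id, recording_id = recording_id,
    pma_weeks = pma_weeks, fs = fs,
    channel_labels = as.character(channel_labels), signal = signal,
    truth_bursts = truth_bursts, truth_artefacts = truth_artefacts,
    annotations = annotations
  ), class = "eeg_recording")
}

#' Duration of a recording in seconds
#' @param x An `eeg_recording`.
#' @return Length in seconds.
#' @export
eeg_duration <- function(x) ncol(x$signal) / x$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s: %d ch x %.1f s @ %g Hz, PMA %.1f wk\n",
              x$infant_id, x$recording_id, nrow(x$signal), eeg_duration(x),
              x$fs, x$pma_weeks))
  invisible(x)
}

# Alternating suppression/burst state sequence with lognormal durations
# (positive, right-skewed, as in discontinuous EEG). Returns the burst log.
draw_burst_log <- function(duration, ibi_mean, burst_mean, sdlog = 0.5) {
  meanlog_ibi <- log(ibi_mean) - sdlog^2 / 2
  meanlog_b <- log(burst_mean) - sdlog^2 / 2
  t <- runif(1, 0, ibi_mean)   # random phase: start mid-suppression
  starts <- numeric(); ends <- numeric()
  while (t < duration) {
    b <- rlnorm(1, meanlog_b, sdlog)
    starts <- c(starts, t); ends <- c(ends, min(t + b, duration))
    t <- t + b + rlnorm(1, meanlog_ibi, sdlog)
  }
  merge_intervals(starts, ends)
}

#' Simulate one discontinuous preterm EEG recording
#'
#' Generates burst-suppression EEG whose discontinuity, amplitude and
#' spectral content follow the maturation curve in [sim_params()]:
#' amplitude-modulated 1/f^gamma noise with synchronous bursts across
#' channels, a common process mixed with channel-independent noise at
#' `channel_correlation`, plus occasional high-amplitude artefact events.
#' The generative burst log is returned in `truth_bursts` so detector and
#' feature layers can be validated against ground truth.
#'
#' @param pma Postmenstrual age in weeks; must lie within `params$pma_range`.
#' @param duration Recording length in seconds (>= 10).
#' @param fs Sampling frequency in Hz (>= 64).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the RNG stream is derived from
#'   `(seed, recording_id)` so cohorts are reproducible recording by
#'   recording.
#' @param infant_id,recording_id Identifiers stored in the recording.
#' @return An [eeg_recording()].
#' @examples
#' rec <- simulate_preterm_eeg(28, duration = 60, fs = 128, seed = 1)
#' eeg_duration(rec)
#' @export
simulate_preterm_eeg <- function(pma, duration = 600, fs = 256,
                                 params = sim_params(), seed = 1,
                                 infant_id = "inf001",
                                 recording_id = "inf001_r1") {
  validate_sim_params(params)
  if (pma < params$pma_range[1] || pma > params$pma_range[2])
    stop_domain(sprintf("pma %.1f outside supported range [%g, %g]",
                        pma, params$pma_range[1], params$pma_range[2]))
  if (duration < 10) stop_input("duration must be >= 10 s")
  if (fs < 64) stop_input("fs must be >= 64 Hz")

  n <- round(duration * fs)
  nch <- params$n_channels
  labels <- neonatal_channels(nch)

  ibi_mean <- lerp_pma(params$ibi_mean_at_25wk, params$ibi_mean_at_38wk, pma)
  burst_mean <- lerp_pma(params$burst_dur_mean_at_25wk,
                         params$burst_dur_mean_at_38wk, pma)
  # amplitude parameters are approx. peak-to-peak; per-sample SD = amp / 4
  burst_sd <- lerp_pma(params$burst_amp_at_25wk, params$burst_amp_at_38wk, pma) / 4
  inter_sd <- lerp_pma(params$interburst_amp_at_25wk,
                       params$interburst_amp_at_38wk, pma) / 4

  stream <- derive_seed(seed, recording_id)
  with_seed(stream, {
    bursts <- draw_burst_log(duration, ibi_mean, burst_mean)

    # smooth burst indicator -> amplitude envelope shared by all channels
    ind <- numeric(n)
    idx_start <- pmax(floor(bursts$start * fs) + 1L, 1L)
    idx_end <- pmin(ceiling(bursts$end * fs), n)
    for (i in seq_len(nrow(bursts))) ind[idx_start[i]:idx_end[i]] <- 1
    ramp <- max(1L, round(0.25 * fs))
    ind <- as.numeric(stats::filter(ind, rep(1 / ramp, ramp), sides = 2))
    ind[is.na(ind)] <- 0
    amp <- inter_sd + (burst_sd - inter_sd) * ind

    rho <- params$channel_correlation
    common <- colored_noise(n, fs, params$spectral_slope)
    signal <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      own <- colored_noise(n, fs, params$spectral_slope)
      signal[ch, ] <- amp * (sqrt(rho) * common + sqrt(1 - rho) * own)
    }

    # movement-like artefact events: 1-s, ~800 uV, all channels
    n_events <- rpois(1, params$artefact_rate * duration / 3600)
    art <- tibble::tibble(start = numeric(), end = numeric())
    if (n_events > 0) {
      ev_start <- sort(runif(n_events, 0, max(duration - 1, 0)))
      art <- merge_intervals(ev_start, ev_start + 1)
      for (i in seq_len(nrow(art))) {
        i0 <- floor(art$start[i] * fs) + 1L
        i1 <- min(ceiling(art$end[i] * fs), n)
        tt <- seq(i0, i1) / fs
        signal[, i0:i1] <- sweep(signal[, i0:i1, drop = FALSE], 2,
                                 800 * sin(2 * pi * 2 * tt), `+`)
      }
    }

    eeg_recording(signal, fs, labels, infant_id = infant_id,
                  recording_id = recording_id, pma_weeks = pma,
                  truth_bursts = bursts, truth_artefacts = art)
  })
}

#' Simulate a serial-recording cohort
#'
#' Each infant is recorded every `interval` weeks from an initial PMA drawn
#' uniformly from `start_pma_range`, mimicking the fortnightly serial
#' recording schedule of preterm monitoring studies; the schedule truncates
#' at the upper end of `params$pma_range`.
#'
#' @param n_infants Number of infants (>= 1).
#' @param recordings_per_infant Planned recordings per infant.
#' @param start_pma_range Range (weeks) the first recording's PMA is drawn from.
#' @param interval Weeks between serial recordings (> 0).
#' @param duration,fs,params,seed Passed to [simulate_preterm_eeg()].
#' @return A list of [eeg_recording()] objects.
#' @examples
#' cohort <- simulate_cohort(2, recordings_per_infant = 2, duration = 30,
#'                           fs = 64, seed = 1)
#' length(cohort)
#' @export
simulate_cohort <- function(n_infants, recordings_per_infant = 3,
                            start_pma_range = c(25, 34), interval = 2,
                            duration = 600, fs = 256,
                            params = sim_params(), seed = 1) {
  if (n_infants < 1) stop_input("n_infants must be >= 1")
  if (interval <= 0) stop_input("interval must be > 0")
  starts <- with_seed(derive_seed(seed, "cohort-schedule"),
                      runif(n_infants, start_pma_range[1], start_pma_range[2]))
  out <- list()
  for (i in seq_len(n_infants)) {
    infant <- sprintf("inf%03d", i)
    for (k in seq_len(recordings_per_infant)) {
      pma <- starts[i] + (k - 1) * interval
      if (pma > params$pma_range[2]) break
      rec_id <- sprintf("%s_r%d", infant, k)
      out[[rec_id]] <- simulate_preterm_eeg(
        pma, duration = duration, fs = fs, params = params, seed = seed,
        infant_id = infant, recording_id = rec_id)
    }
  }
  out
}

#' Cohort manifest
#'
#' One row per recording with ids and true PMA; the truth table consumed by
#' [simulate_rater_panel()] and written next to EDF exports.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @return A tibble with `recording_id`, `infant_id`, `pma_weeks`,
#'   `duration_s`, `fs`.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(r) {
    tibble::tibble(recording_id = r$recording_id, infant_id = r$infant_id,
                   pma_weeks = r$pma_weeks, duration_s = eeg_duration(r),
                   fs = r$fs)
  })
}
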