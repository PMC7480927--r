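#' Range-EEG (rEEG) amplitude percentiles
#'
#' Peak-to-peak amplitude in consecutive half-open windows (2 s by default),
#' summarised by the 5th, 50th and 95th percentiles — the standard rEEG
#' description of EEG amplitude.
#'
#' @param x Numeric vector: one derivation in microvolts.
#' @param fs Sampling frequency (Hz).
#' @param window_s Window length (s); the signal must cover one window.
#' @return A one-row tibble: `reeg_p5`, `reeg_p50`, `reeg_p95` (uV).
#' @export
reeg_features <- function(x, fs, window_s = 2) {
  wlen <- round(window_s * fs)
  n_win <- floor(length(x) / wlen)
  if (n_win < 1) stop_input("signal shorter than one rEEG window")
  idx <- rep(seq_len(n_win), each = wlen)
  xx <- x[seq_len(n_win * wlen)]
  pp <- as.numeric(tapply(xx, idx, function(v) max(v) - min(v)))
  q <- quantile(pp, c(0.05, 0.5, 0.95), names = FALSE)
  tibble::tibble(reeg_p5 = q[1], reeg_p50 = q[2], reeg_p95 = q[3])
}

# Welch power spectral density: Hann-windowed segments, 50% overlap,
# averaged periodograms. Returns one-sided freq/psd (arbitrary power units;
# relative band powers are scale-free).
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  nperseg <- min(nperseg %||% round(4 * fs), n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  norm <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(fft(seg))^2 / (norm * fs)
    psd <- psd + p[seq_len(nf)]
  }
  psd <- psd / length(starts)
  if (nf > 2) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd)
}

#' Relative spectral band powers
#'
#' Welch power spectrum, integrated over the delta (0.5-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz) bands and normalised by
#' total 0.5-30 Hz power, so the four values sum to one.
#'
#' @param x Numeric vector: one derivation.
#' @param fs Sampling frequency (Hz), >= 60 so the beta band is resolvable.
#' @return A one-row tibble: `relpow_delta`, `relpow_theta`, `relpow_alpha`,
#'   `relpow_beta`.
#' @export
band_powers <- function(x, fs) {
  if (fs < 60)
    abort("fs below 60 Hz cannot resolve the 13-30 Hz beta band",
          class = "neofba_band_error")
  if (length(x) < 8 * fs) stop_input("signal must be at least 8 s long")
  spec <- welch_psd(x, fs)
  bp <- function(lo, hi) {
    sel <- spec$freq >= lo & spec$freq < hi
    sum(spec$psd[sel])
  }
  total <- bp(0.5, 30)
  if (total <= 0) {
    return(tibble::tibble(relpow_delta = NA_real_, relpow_theta = NA_real_,
                          relpow_alpha = NA_real_, relpow_beta = NA_real_))
  }
  tibble::tibble(relpow_delta = bp(0.5, 4) / total,
                 relpow_theta = bp(4, 8) / total,
                 relpow_alpha = bp(8, 13) / total,
                 relpow_beta = bp(13, 30) / total)
}

#' Sample entropy
#'
#' Sample entropy `-ln(A/B)` with embedding dimension `m`, tolerance
#' `r = r_factor * SD(x)` (Chebyshev distance, self-matches excluded),
#' computed on the signal decimated to `target_fs`. Long inputs are
#' truncated to `max_samples` after decimation to bound the quadratic
#' template search; a zero-variance signal is perfectly regular and defined
#' as 0.
#'
#' @param x Numeric vector: one derivation.
#' @param fs Sampling frequency (Hz).
#' @param m Embedding dimension.
#' @param r_factor Tolerance as a fraction of the signal SD.
#' @param target_fs Decimation target (Hz).
#' @param max_samples Cap on the number of samples entering the search.
#' @return Scalar sample entropy (`NA` when no template matches exist).
#' @export
sample_entropy <- function(x, fs, m = 2, r_factor = 0.2, target_fs = 64,
                           max_samples = 4096) {
  factor <- max(1L, round(fs / target_fs))
  if (factor > 1L) x <- signal::decimate(x, factor)
  if (length(x) < 300)
    stop_input("need >= 300 samples after decimation for sample entropy")
  if (length(x) > max_samples) x <- x[seq_len(max_samples)]
  s <- sd(x)
  if (s == 0) return(0)
  .sampen_cpp(x, as.integer(m), r_factor * s)
}

#' Suppression curve
#'
#' Fraction of epoch time the amplitude envelope spends below each threshold
#' of a grid: `s(theta) = P(envelope < theta)`, a non-decreasing curve whose
#' height profile separates discontinuous from continuous EEG. Summarised by
#' `sc_auc`, the trapezoidal area under `s` normalised by the grid span, and
#' `sc_theta50`, the smallest grid threshold with `s(theta) >= 0.5`.
#'
#' @param envelope Numeric vector of envelope samples (uV), non-empty.
#' @param thresholds Strictly increasing grid of at least 3 thresholds (uV).
#' @return A list of class `suppression_curve`: `curve` (tibble `threshold`,
#'   `fraction`), `sc_auc`, `sc_theta50`.
#' @export
suppression_curve <- function(envelope, thresholds = seq(0, 50, by = 1)) {
  if (length(envelope) == 0) stop_input("empty envelope")
  if (length(thresholds) < 3 || any(diff(thresholds) <= 0))
    stop_input("thresholds must be strictly increasing with >= 3 points")
  s <- vapply(thresholds, function(th) mean(envelope < th), 0)
  at50 <- which(s >= 0.5)
  structure(list(
    curve = tibble::tibble(threshold = thresholds, fraction = s),
    sc_auc = trapz(thresholds, s) / diff(range(thresholds)),
    sc_theta50 = if (length(at50)) thresholds[at50[1]] else NA_real_
  ), class = "suppression_curve")
}

#' Quantitative-EEG extraction configuration
#'
#' All tunables of the feature layer in one place, recorded alongside any
#' feature table so an extraction is reproducible.
#'
#' @param montage [montage_spec()] applied before per-derivation analysis.
#' @param epoch_s,min_clean_fraction,min_duration_s Epoching rules, see
#'   [segment_epochs()].
#' @param amp_threshold_uV,flat_threshold_uV,pad_s Artefact rules, see
#'   [detect_artefacts()].
#' @param burst_on_uV,burst_off_uV,min_burst_s,min_ibi_s Burst detector, see
#'   [detect_bursts()].
#' @param reeg_window_s rEEG window (s).
#' @param sampen_m,sampen_r_factor,sampen_target_fs Sample-entropy settings.
#' @param sc_thresholds Suppression-curve grid (uV).
#' @return A list of class `qeeg_config`.
#' @export
qeeg_config <- function(montage = montage_default_eeg(),
                        epoch_s = 3600, min_clean_fraction = 0.5,
                        min_duration_s = 600,
                        amp_threshold_uV = 500, flat_threshold_uV = 2,
                        pad_s = 1,
                        burst_on_uV = 10, burst_off_uV = 6,
                        min_burst_s = 0.5, min_ibi_s = 1,
                        reeg_window_s = 2,
                        sampen_m = 2, sampen_r_factor = 0.2,
                        sampen_target_fs = 64,
                        sc_thresholds = seq(0, 50, by = 1)) {
  structure(as.list(environment()), class = "qeeg_config")
}

#' Names of the qEEG feature vector, in canonical order
#' @return Character vector of the 17 feature names.
#' @export
qeeg_feature_names <- function() {
  c("reeg_p5", "reeg_p50", "reeg_p95",
    "ibi_median", "ibi_max", "suppression_fraction",
    "relpow_delta", "relpow_theta", "relpow_alpha", "relpow_beta",
    "sampen", "sc_auc", "sc_theta50",
    "burst_dur_logmean", "burst_dur_logsd",
    "burst_shape_skew", "burst_shape_kurt")
}

# Features for one derivation over a clean (artefact-removed, concatenated)
# sample vector.
derivation_features <- function(x, fs, config) {
  bursts <- detect_bursts(x, fs, config$burst_on_uV, config$burst_off_uV,
                          config$min_burst_s, config$min_ibi_s)
  sc <- suppression_curve(bursts$envelope, config$sc_thresholds)
  dplyr::bind_cols(
    reeg_features(x, fs, config$reeg_window_s),
    ibi_features(bursts),
    band_powers(x, fs),
    tibble::tibble(
      sampen = sample_entropy(x, fs, config$sampen_m, config$sampen_r_factor,
                              config$sampen_target_fs),
      sc_auc = sc$sc_auc, sc_theta50 = sc$sc_theta50),
    burst_shape_features(bursts)
  )
}

#' Assemble the qEEG feature vector for one epoch
#'
#' Applies the configured montage, removes masked (artefact) intervals from
#' the epoch, concatenates the clean segments per derivation, computes the
#' full feature set per derivation and aggregates across derivations by the
#' median (robust to a single bad derivation). Burst features undefined on a
#' derivation (too few bursts) are dropped from that derivation's
#' contribution; if no derivation defines them the epoch value is missing
#' and imputed at model-fit time.
#'
#' @param recording An [eeg_recording()] in referential layout.
#' @param mask Optional [detect_artefacts()] result.
#' @param epoch Numeric `c(start, end)` in seconds (one row of
#'   [segment_epochs()]).
#' @param config A [qeeg_config()].
#' @return A one-row tibble: `recording_id`, `infant_id`, `pma_weeks`,
#'   `epoch_start`, `epoch_end`, `clean_fraction`, then the features of
#'   [qeeg_feature_names()].
#' @export
assemble_features <- function(recording, mask = NULL, epoch = NULL,
                              config = qeeg_config()) {
  fs <- recording$fs
  dur <- eeg_duration(recording)
  epoch <- epoch %||% c(0, dur)
  if (length(epoch) != 2 || anyNA(epoch) || epoch[2] <= epoch[1])
    stop_input("epoch must be a finite c(start, end) interval")
  mon <- apply_montage(recording, config$montage)
  mask_ints <- if (is.null(mask)) tibble::tibble(start = numeric(),
                                                 end = numeric())
               else mask$intervals
  clean <- complement_intervals(mask_ints, epoch[1], epoch[2])
  clean_fraction <- interval_total(clean) / (epoch[2] - epoch[1])
  if (clean_fraction < config$min_clean_fraction)
    abort("epoch below minimum clean fraction", class = "neofba_epoch_error")
  idx <- unlist(lapply(seq_len(nrow(clean)), function(i) {
    (floor(clean$start[i] * fs) + 1L):min(ceiling(clean$end[i] * fs),
                                          ncol(mon$signal))
  }))
  idx <- unique(idx)

  per_deriv <- purrr::map_dfr(seq_len(nrow(mon$signal)), function(ch) {
    derivation_features(mon$signal[ch, idx], fs, config)
  })
  if (nrow(per_deriv) == 0)
    abort("no usable derivations in epoch", class = "neofba_epoch_error")
  agg <- dplyr::summarise(per_deriv, dplyr::across(dplyr::everything(),
                                                   ~ median(.x, na.rm = TRUE)))
  agg <- dplyr::mutate(agg, dplyr::across(dplyr::everything(),
                                          ~ ifelse(is.nan(.x), NA_real_, .x)))
  dplyr::bind_cols(
    tibble::tibble(recording_id = recording$recording_id,
                   infant_id = recording$infant_id,
                   pma_weeks = recording$pma_weeks,
                   epoch_start = epoch[1], epoch_end = epoch[2],
                   clean_fraction = clean_fraction),
    agg[, qeeg_feature_names()]
  )
}

#' Extract per-epoch features for a recording or cohort
#'
#' `extract_features()` runs artefact detection, epoch segmentation and
#' [assemble_features()] for one recording; `extract_cohort_features()` maps
#' it over a cohort list, one row per (recording, epoch).
#'
#' @param recording An [eeg_recording()].
#' @param config A [qeeg_config()].
#' @return A tibble of epoch feature rows.
#' @export
extract_features <- function(recording, config = qeeg_config()) {
  mask <- detect_artefacts(recording, config$amp_threshold_uV,
                           config$flat_threshold_uV, config$pad_s)
  eps <- segment_epochs(recording, mask, config$epoch_s,
                        config$min_clean_fraction, config$min_duration_s)
  purrr::map_dfr(seq_len(nrow(eps)), function(i) {
    assemble_features(recording, mask, c(eps$start[i], eps$end[i]), config)
  })
}

#' @rdname extract_features
#' @param cohort List of recordings, e.g. from [simulate_cohort()].
#' @export
extract_cohort_features <- function(cohort, config = qeeg_config()) {
  purrr::map_dfr(cohort, extract_features, config = config)
}
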