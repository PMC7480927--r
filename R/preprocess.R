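#' Amplitude-based artefact detection
#'
#' Flags samples where any channel exceeds `amp_threshold_uV` in absolute
#' value (movement/electrode artefact) and 2-s windows whose peak-to-peak
#' amplitude is below `flat_threshold_uV` on every channel (disconnection /
#' flat trace). Flagged regions are dilated by `pad_s` on both sides and
#' merged into a sorted set of half-open `[start, end)` intervals.
#'
#' @param recording An [eeg_recording()].
#' @param amp_threshold_uV Absolute amplitude ceiling (uV), > 0.
#' @param flat_threshold_uV Peak-to-peak floor (uV) over 2-s windows, > 0.
#' @param pad_s Dilation of each artefact interval in seconds, >= 0.
#' @param flat_window_s Window used for the flatness check (s).
#' @return An object of class `artefact_mask`: list with `intervals`
#'   (tibble `start`, `end`), `total_masked_s` and `duration_s`.
#' @examples
#' rec <- simulate_preterm_eeg(30, duration = 30, fs = 64, seed = 1)
#' detect_artefacts(rec)
#' @export
detect_artefacts <- function(recording, amp_threshold_uV = 500,
                             flat_threshold_uV = 2, pad_s = 1,
                             flat_window_s = 2) {
  if (amp_threshold_uV <= 0 || flat_threshold_uV <= 0)
    stop_input("thresholds must be > 0")
  if (pad_s < 0) stop_input("pad_s must be >= 0")
  sig <- recording$signal
  fs <- recording$fs
  n <- ncol(sig)
  dur <- n / fs

  bad <- matrixStats_colMaxs_abs(sig) > amp_threshold_uV

  wlen <- round(flat_window_s * fs)
  n_win <- floor(n / wlen)
  flat_win <- logical(n_win)
  if (n_win > 0) {
    for (w in seq_len(n_win)) {
      cols <- ((w - 1L) * wlen + 1L):(w * wlen)
      pp <- apply(sig[, cols, drop = FALSE], 1,
                  function(v) max(v) - min(v))
      flat_win[w] <- all(pp < flat_threshold_uV)
    }
  }
  flat <- logical(n)
  if (n_win > 0) flat[seq_len(n_win * wlen)] <- rep(flat_win, each = wlen)
  # trailing partial window inherits the last full window's flatness
  if (n_win > 0 && n > n_win * wlen) flat[(n_win * wlen + 1L):n] <- flat_win[n_win]

  mask_samples <- bad | flat
  ints <- runs_to_intervals(mask_samples, fs)
  if (nrow(ints) > 0) {
    ints <- merge_intervals(pmax(ints$start - pad_s, 0),
                            pmin(ints$end + pad_s, dur))
  }
  structure(list(intervals = ints,
                 total_masked_s = interval_total(ints),
                 duration_s = dur),
            class = "artefact_mask")
}

# column-wise max of |signal| across channels without building abs() copy rows
matrixStats_colMaxs_abs <- function(sig) {
  out <- abs(sig[1, ])
  if (nrow(sig) > 1) {
    for (ch in 2:nrow(sig)) out <- pmax(out, abs(sig[ch, ]))
  }
  out
}

runs_to_intervals <- function(flag, fs) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  merge_intervals(starts[keep] / fs, ends[keep] / fs)
}

#' @export
print.artefact_mask <- function(x, ...) {
  cat(sprintf("<artefact_mask> %.1f of %.1f s masked (%d intervals)\n",
              x$total_masked_s, x$duration_s, nrow(x$intervals)))
  invisible(x)
}

#' Segment a recording into analysis epochs
#'
#' Consecutive half-open epochs of `epoch_s` seconds from time zero. Epochs
#' whose artefact-free fraction falls below `min_clean_fraction` are
#' dropped. Recordings shorter than one epoch fall back to a single
#' whole-recording epoch, provided they reach `min_duration_s` (the fallback
#' that admits short clinical recordings of ~0.4 h under hour-long epochs).
#'
#' @param recording An [eeg_recording()].
#' @param mask Optional [detect_artefacts()] result.
#' @param epoch_s Epoch length in seconds, > 0.
#' @param min_clean_fraction Minimum artefact-free fraction per epoch.
#' @param min_duration_s Minimum usable recording length (s).
#' @return A tibble with `epoch`, `start`, `end`, `clean_fraction`.
#' @examples
#' rec <- simulate_preterm_eeg(30, duration = 120, fs = 64, seed = 1)
#' segment_epochs(rec, epoch_s = 60)
#' @export
segment_epochs <- function(recording, mask = NULL, epoch_s = 3600,
                           min_clean_fraction = 0.5, min_duration_s = 600) {
  if (epoch_s <= 0) stop_input("epoch_s must be > 0")
  dur <- eeg_duration(recording)
  if (dur < min(min_duration_s, epoch_s))
    abort(sprintf("recording too short: %.0f s < %.0f s minimum", dur,
                  min(min_duration_s, epoch_s)),
          class = "neofba_tooshort_error")
  if (dur < epoch_s) {
    eps <- tibble::tibble(epoch = 1L, start = 0, end = dur)
  } else {
    k <- floor(dur / epoch_s)
    eps <- tibble::tibble(epoch = seq_len(k), start = (seq_len(k) - 1) * epoch_s,
                          end = seq_len(k) * epoch_s)
  }
  mask_ints <- if (is.null(mask)) tibble::tibble(start = numeric(),
                                                 end = numeric())
               else mask$intervals
  eps$clean_fraction <- vapply(seq_len(nrow(eps)), function(i) {
    masked <- interval_total(clip_intervals(mask_ints, eps$start[i], eps$end[i]))
    1 - masked / (eps$end[i] - eps$start[i])
  }, 0)
  out <- eps[eps$clean_fraction >= min_clean_fraction, , drop = FALSE]
  tibble::as_tibble(out)
}

#' Recording-level exclusion rules for a reviewed cohort
#'
#' A recording is excluded when at least two panel reviewers flag excessive
#' artefact, at least two flag it as too brief, or any reviewer's estimate
#' is missing; the reported reason is the first rule that fires, in that
#' fixed order.
#'
#' @param flags Data frame with one row per (recording, reviewer):
#'   `recording_id`, `reviewer_id`, `artefact_flag`, `too_brief_flag`,
#'   `estimate_present` (logicals).
#' @param panel_size Expected number of reviewers per recording.
#' @return A tibble with one row per recording: `recording_id`, `include`,
#'   `reason` (`"artefact"`, `"too_brief"`, `"missing"` or `NA` when
#'   included).
#' @examples
#' flags <- tidyr::crossing(recording_id = "r1", reviewer_id = 1:7) |>
#'   dplyr::mutate(artefact_flag = reviewer_id <= 2, too_brief_flag = FALSE,
#'                 estimate_present = TRUE)
#' apply_exclusion_rules(flags, panel_size = 7)
#' @export
apply_exclusion_rules <- function(flags, panel_size) {
  flags <- tibble::as_tibble(flags)
  need <- c("recording_id", "artefact_flag", "too_brief_flag",
            "estimate_present")
  if (!all(need %in% names(flags)))
    stop_input("flags must have recording_id, artefact_flag, too_brief_flag, estimate_present")
  counts <- dplyr::count(flags, .data$recording_id)
  if (any(counts$n != panel_size))
    stop_input("flags are incomplete: every recording needs one row per panel reviewer")
  flags |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(
      n_artefact = sum(.data$artefact_flag),
      n_brief = sum(.data$too_brief_flag),
      n_missing = sum(!.data$estimate_present),
      .groups = "drop") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_artefact >= 2 ~ "artefact",
        .data$n_brief >= 2 ~ "too_brief",
        .data$n_missing >= 1 ~ "missing",
        TRUE ~ NA_character_),
      include = is.na(.data$reason)) |>
    dplyr::select("recording_id", "include", "reason")
}
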