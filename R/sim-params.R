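#' Simulation parameters for synthetic preterm EEG
#'
#' Defines the maturation curve the synthetic cohort follows. Each pair of
#' `*_at_25wk` / `*_at_38wk` anchors is interpolated linearly in
#' postmenstrual age (PMA), encoding the developmental trend of discontinuous
#' preterm EEG: inter-burst intervals (IBIs) shorten, burst amplitude falls
#' and inter-burst (trough) amplitude rises as the background becomes
#' continuous towards term.
#'
#' Amplitudes are approximate peak-to-peak values in microvolts; internally
#' the generator uses a per-sample standard deviation of `amp / 4`, so the
#' 0.5-s RMS envelope sits near `amp / 4`.
#'
#' @param ibi_mean_at_25wk,ibi_mean_at_38wk Mean inter-burst interval (s).
#' @param burst_dur_mean_at_25wk,burst_dur_mean_at_38wk Mean burst duration (s).
#' @param burst_amp_at_25wk,burst_amp_at_38wk Burst amplitude (uV, peak-to-peak).
#' @param interburst_amp_at_25wk,interburst_amp_at_38wk Inter-burst amplitude
#'   (uV, peak-to-peak).
#' @param spectral_slope Exponent gamma of the 1/f^gamma background spectrum.
#' @param n_channels Number of scalp channels (9 = neonatal 10-20 layout).
#' @param channel_correlation Share of variance common across channels, in
#'   `[0, 1]`; bursts themselves are synchronous across the scalp.
#' @param artefact_rate Expected high-amplitude artefact events per hour.
#' @param pma_range Supported PMA range (weeks).
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$ibi_mean_at_25wk
#' @export
sim_params <- function(ibi_mean_at_25wk = 8,
                       ibi_mean_at_38wk = 1.5,
                       burst_dur_mean_at_25wk = 3,
                       burst_dur_mean_at_38wk = 6,
                       burst_amp_at_25wk = 120,
                       burst_amp_at_38wk = 60,
                       interburst_amp_at_25wk = 8,
                       interburst_amp_at_38wk = 25,
                       spectral_slope = 2,
                       n_channels = 9,
                       channel_correlation = 0.7,
                       artefact_rate = 2,
                       pma_range = c(25, 38)) {
  p <- list(
    ibi_mean_at_25wk = ibi_mean_at_25wk,
    ibi_mean_at_38wk = ibi_mean_at_38wk,
    burst_dur_mean_at_25wk = burst_dur_mean_at_25wk,
    burst_dur_mean_at_38wk = burst_dur_mean_at_38wk,
    burst_amp_at_25wk = burst_amp_at_25wk,
    burst_amp_at_38wk = burst_amp_at_38wk,
    interburst_amp_at_25wk = interburst_amp_at_25wk,
    interburst_amp_at_38wk = interburst_amp_at_38wk,
    spectral_slope = spectral_slope,
    n_channels = as.integer(n_channels),
    channel_correlation = channel_correlation,
    artefact_rate = artefact_rate,
    pma_range = pma_range
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (!(p$ibi_mean_at_25wk > p$ibi_mean_at_38wk && p$ibi_mean_at_38wk > 0))
    stop_input("IBI means must satisfy ibi_mean_at_25wk > ibi_mean_at_38wk > 0")
  durs <- c(p$burst_dur_mean_at_25wk, p$burst_dur_mean_at_38wk)
  amps <- c(p$burst_amp_at_25wk, p$burst_amp_at_38wk,
            p$interburst_amp_at_25wk, p$interburst_amp_at_38wk)
  if (any(c(durs, amps) <= 0))
    stop_input("all durations and amplitudes must be > 0")
  for (pma in p$pma_range) {
    if (lerp_pma(p$burst_amp_at_25wk, p$burst_amp_at_38wk, pma) <=
        lerp_pma(p$interburst_amp_at_25wk, p$interburst_amp_at_38wk, pma))
      stop_input("burst amplitude must exceed inter-burst amplitude at every PMA")
  }
  if (p$channel_correlation < 0 || p$channel_correlation > 1)
    stop_input("channel_correlation must be in [0, 1]")
  if (p$n_channels < 1) stop_input("n_channels must be >= 1")
  if (length(p$pma_range) != 2 || p$pma_range[1] >= p$pma_range[2])
    stop_input("pma_range must be an increasing pair of weeks")
  invisible(p)
}

# Default neonatal 10-20 labels (9-electrode layout with Cz reference).
neonatal_channels <- function(n = 9) {
  std <- c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2", "Cz")
  if (n <= length(std)) std[seq_len(n)] else c(std, paste0("Ch", seq_len(n - length(std)) + 9))
}

#' Specification of a synthetic rater
#'
#' A rater estimates PMA as `truth + bias + e`, `e ~ N(0, sd^2)`, optionally
#' rounded to a grid and clipped to a known range. `bias` is the rater's
#' systematic error and `sd` the random error, both in weeks.
#'
#' @param rater_id Identifier.
#' @param bias Systematic error (weeks).
#' @param sd Random error (weeks), `>= 0`.
#' @param rounding Rounding grid in weeks (e.g. `1` for integer weeks) or
#'   `NULL` for none.
#' @param clip_range Length-2 clipping range in weeks, or `NULL` for none.
#' @return A list of class `rater_spec`.
#' @examples
#' rater_spec("R1", bias = 0.8, sd = 2.5)
#' @export
rater_spec <- function(rater_id, bias = 0, sd = 0, rounding = NULL,
                       clip_range = NULL) {
  if (sd < 0) stop_input("rater sd must be >= 0")
  if (!is.null(clip_range) &&
      (length(clip_range) != 2 || clip_range[1] >= clip_range[2]))
    stop_input("clip_range must be an increasing pair")
  structure(list(rater_id = as.character(rater_id), bias = bias, sd = sd,
                 rounding = rounding, clip_range = clip_range),
            class = "rater_spec")
}

#' Preset rater panels
#'
#' Two panels mirroring the published study scale: an "EEG-like" panel of
#' four raters whose biases average +0.8 wk but spread widely (SD approx.
#' 2.7 wk, reproducing the systematic between-rater differences seen in raw
#' EEG review) with random error 2.5 wk, and an "aEEG-like" panel of three
#' nearly interchangeable raters (mean bias -1.8 wk, bias SD approx. 0.3 wk)
#' with random error 2.3 wk. With targets spread over 25-38 wk these produce
#' panel ICCs near 0.52 and 0.72 respectively.
#'
#' @param rounding,clip_range Passed to every [rater_spec()]; raters knew the
#'   cohort's age range, so `clip_range = c(25, 38)` is a realistic variant,
#'   off by default.
#' @return A list of [rater_spec()] objects.
#' @examples
#' length(rater_panel_eeg())
#' @export
rater_panel_eeg <- function(rounding = NULL, clip_range = NULL) {
  offsets <- c(-3.1, -1.1, 1.1, 3.1)
  purrr::imap(offsets, function(off, i) {
    rater_spec(paste0("EEG_R", i), bias = 0.8 + off, sd = 2.5,
               rounding = rounding, clip_range = clip_range)
  })
}

#' @rdname rater_panel_eeg
#' @export
rater_panel_aeeg <- function(rounding = NULL, clip_range = NULL) {
  offsets <- c(-0.3, 0, 0.3)
  purrr::imap(offsets, function(off, i) {
    rater_spec(paste0("aEEG_R", i), bias = -1.8 + off, sd = 2.3,
               rounding = rounding, clip_range = clip_range)
  })
}
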