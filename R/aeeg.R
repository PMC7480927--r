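#' Amplitude-integrated EEG (aEEG) trace
#'
#' Computes the cerebral-function-monitor style trend from a single
#' derivation: band-pass 2-15 Hz (3rd-order Butterworth, zero-phase),
#' rectification, a 0.5-s moving-RMS envelope, then the minimum and maximum
#' of the envelope over consecutive half-open windows (15 s by default).
#' The classic semilogarithmic display (linear below 10 uV, logarithmic
#' above) is purely a plotting transform — see [autoplot.aeeg_trace()] —
#' and does not affect the stored values.
#'
#' @param x Numeric vector: one derivation in microvolts (e.g. C3-C4 from
#'   [apply_montage()]), at least one window long.
#' @param fs Sampling frequency (Hz).
#' @param window_s Compression window length in seconds.
#' @param band Band-pass edges in Hz.
#' @param env_window_s Moving-RMS envelope window (s).
#' @return A tibble of class `aeeg_trace` with columns `time` (window start,
#'   s), `lower` and `upper` (uV).
#' @examples
#' x <- 50 * sin(2 * pi * 5 * seq(0, 60, by = 1 / 128))
#' compute_aeeg(x, fs = 128)
#' @export
compute_aeeg <- function(x, fs, window_s = 15, band = c(2, 15),
                         env_window_s = 0.5) {
  n <- length(x)
  if (n < window_s * fs)
    stop_input("signal shorter than one aEEG window")
  if (band[2] >= fs / 2) stop_input("band-pass edge above Nyquist frequency")
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, x)
  env <- moving_rms(abs(filtered), fs, env_window_s)
  wlen <- round(window_s * fs)
  n_win <- floor(n / wlen)
  idx <- rep(seq_len(n_win), each = wlen)
  env <- env[seq_len(n_win * wlen)]
  out <- tibble::tibble(
    time = (seq_len(n_win) - 1) * window_s,
    lower = as.numeric(tapply(env, idx, min)),
    upper = as.numeric(tapply(env, idx, max))
  )
  structure(out, class = c("aeeg_trace", class(out)), window_s = window_s)
}
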