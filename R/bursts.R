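#' Burst detection by hysteresis thresholding of the RMS envelope
#'
#' A burst opens when the 0.5-s moving-RMS envelope rises above
#' `on_threshold_uV` and closes when it falls below `off_threshold_uV`; the
#' two-threshold hysteresis suppresses chatter around a single threshold.
#' Gaps shorter than `min_ibi_s` are bridged, then bursts shorter than
#' `min_burst_s` are dropped. Default thresholds (on 10 / off 6 uV) sit
#' between the inter-burst and burst envelope levels of bipolar-derived
#' preterm EEG across the whole 25-38 wk range.
#'
#' @param x Numeric vector: one derivation in microvolts.
#' @param fs Sampling frequency (Hz).
#' @param on_threshold_uV,off_threshold_uV Hysteresis thresholds (uV);
#'   `on > off > 0`.
#' @param min_burst_s Minimum burst duration (s).
#' @param min_ibi_s Minimum inter-burst gap (s); shorter gaps are bridged.
#' @param envelope_window_s Moving-RMS window (s).
#' @return An object of class `burst_set`: list with `intervals` (tibble
#'   `start`, `end` in seconds), `envelope` (uV), `fs` and `duration_s`.
#' @examples
#' x <- rep(c(100, 2), each = 5 * 64) * rnorm(640)
#' detect_bursts(x, fs = 64, on_threshold_uV = 50, off_threshold_uV = 40)
#' @export
detect_bursts <- function(x, fs, on_threshold_uV = 10, off_threshold_uV = 6,
                          min_burst_s = 0.5, min_ibi_s = 1,
                          envelope_window_s = 0.5) {
  if (!(on_threshold_uV > off_threshold_uV && off_threshold_uV > 0))
    stop_input("thresholds must satisfy on > off > 0")
  env <- moving_rms(x, fs, envelope_window_s)
  n <- length(env)
  dur <- n / fs

  # hysteresis over envelope level runs: 2 = above on, 1 = between, 0 = below off
  lvl <- ifelse(env > on_threshold_uV, 2L, ifelse(env >= off_threshold_uV, 1L, 0L))
  r <- rle(lvl)
  state <- 0L
  in_burst <- logical(length(r$values))
  for (i in seq_along(r$values)) {
    if (r$values[i] == 2L) state <- 1L
    else if (r$values[i] == 0L) state <- 0L
    in_burst[i] <- state == 1L
  }
  flag <- inverse.rle(list(lengths = r$lengths, values = in_burst))
  ints <- runs_to_intervals(flag, fs)

  # bridge short gaps, then drop short bursts
  if (nrow(ints) > 1) {
    gap <- ints$start[-1] - ints$end[-nrow(ints)]
    bridge <- gap < min_ibi_s
    ends <- ints$end
    for (i in which(bridge)) ends[i] <- ints$start[i + 1]
    ints <- merge_intervals(ints$start, ends)
  }
  ints <- ints[ints$end - ints$start >= min_burst_s, , drop = FALSE]

  structure(list(intervals = tibble::as_tibble(ints), envelope = env, fs = fs,
                 duration_s = dur),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts in %.1f s\n", nrow(x$intervals),
              x$duration_s))
  invisible(x)
}

#' Inter-burst interval features
#'
#' IBIs are the gaps between consecutive bursts; the leading gap before the
#' first burst and the trailing gap after the last are excluded as censored.
#' With no bursts the IBI statistics are missing-coded and the suppression
#' fraction is 1.
#'
#' @param bursts A [detect_bursts()] result, or a tibble of `start`/`end`
#'   intervals.
#' @param duration_s Epoch duration (s), > 0; defaults to the burst set's own.
#' @return A one-row tibble: `ibi_median`, `ibi_max` (s),
#'   `suppression_fraction`, `burst_rate` (bursts/min).
#' @export
ibi_features <- function(bursts, duration_s = NULL) {
  ints <- if (inherits(bursts, "burst_set")) bursts$intervals else
    tibble::as_tibble(bursts)
  duration_s <- duration_s %||%
    (if (inherits(bursts, "burst_set")) bursts$duration_s else NULL)
  if (is.null(duration_s) || duration_s <= 0)
    stop_input("duration_s must be > 0")
  nb <- nrow(ints)
  ibis <- if (nb >= 2) ints$start[-1] - ints$end[-nb] else numeric()
  tibble::tibble(
    ibi_median = if (length(ibis)) median(ibis) else NA_real_,
    ibi_max = if (length(ibis)) max(ibis) else NA_real_,
    suppression_fraction = 1 - interval_total(ints) / duration_s,
    burst_rate = nb / duration_s * 60
  )
}

#' Burst duration and average-shape features
#'
#' Burst durations are summarised on the log scale (mean, SD). Each burst's
#' envelope is resampled to 100 points and peak-normalised to 1; the
#' pointwise average of these time/amplitude-normalised shapes is summarised
#' by its temporal skewness and excess kurtosis, treating the normalised
#' shape as a weight function over relative time in `[0, 1]` (0 for a
#' symmetric burst, positive skew when energy arrives early and decays
#' slowly). Fewer than `min_bursts` bursts yields missing values, imputed
#' downstream at model fit time.
#'
#' @param bursts A [detect_bursts()] result (its stored envelope is used),
#'   or an interval tibble with `envelope`, `fs` supplied.
#' @param envelope,fs Envelope samples and rate, when `bursts` is a plain
#'   interval table.
#' @param min_bursts Minimum number of bursts for the features to be defined.
#' @param n_points Resampling grid for the normalised shape.
#' @return A one-row tibble: `burst_dur_logmean`, `burst_dur_logsd`,
#'   `burst_shape_skew`, `burst_shape_kurt`.
#' @export
burst_shape_features <- function(bursts, envelope = NULL, fs = NULL,
                                 min_bursts = 3, n_points = 100) {
  if (inherits(bursts, "burst_set")) {
    envelope <- envelope %||% bursts$envelope
    fs <- fs %||% bursts$fs
    ints <- bursts$intervals
  } else ints <- tibble::as_tibble(bursts)
  miss <- tibble::tibble(burst_dur_logmean = NA_real_,
                         burst_dur_logsd = NA_real_,
                         burst_shape_skew = NA_real_,
                         burst_shape_kurt = NA_real_)
  if (nrow(ints) < min_bursts) return(miss)

  durs <- ints$end - ints$start
  shapes <- matrix(NA_real_, nrow = nrow(ints), ncol = n_points)
  for (i in seq_len(nrow(ints))) {
    i0 <- max(floor(ints$start[i] * fs) + 1L, 1L)
    i1 <- min(ceiling(ints$end[i] * fs), length(envelope))
    seg <- envelope[i0:i1]
    if (length(seg) < 2 || max(seg) <= 0) next
    shapes[i, ] <- stats::approx(seq_along(seg), seg,
                                 xout = seq(1, length(seg),
                                            length.out = n_points))$y / max(seg)
  }
  ok <- stats::complete.cases(shapes)
  if (sum(ok) < min_bursts) return(miss)
  mean_shape <- colMeans(shapes[ok, , drop = FALSE])

  tt <- seq(0, 1, length.out = n_points)
  w <- mean_shape / sum(mean_shape)
  mu <- sum(w * tt)
  s2 <- sum(w * (tt - mu)^2)
  tibble::tibble(
    burst_dur_logmean = mean(log(durs)),
    burst_dur_logsd = sd(log(durs)),
    burst_shape_skew = sum(w * (tt - mu)^3) / s2^1.5,
    burst_shape_kurt = sum(w * (tt - mu)^4) / s2^2 - 3
  )
}
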