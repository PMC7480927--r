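# constructed burst-suppression trace: sinusoidal carrier, alternating
# amplitude blocks of burst_s at amp_hi then gap_s at amp_lo
alternating_signal <- function(burst_s = 5, gap_s = 5, amp_hi = 100,
                               amp_lo = 2, total_s = 100, fs = 64) {
  tt <- seq(0, total_s - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 10 * tt)
  period <- burst_s + gap_s
  in_burst <- (tt %% period) < burst_s
  list(x = carrier * ifelse(in_burst, amp_hi, amp_lo),
       truth = tibble::tibble(
         start = seq(0, total_s - period, by = period),
         end = seq(0, total_s - period, by = period) + burst_s))
}

interval_jaccard <- function(a, b) {
  grid <- seq(0, max(a$end, b$end), by = 0.01)
  ina <- rowSums(outer(grid, a$start, `>=`) & outer(grid, a$end, `<`)) > 0
  inb <- rowSums(outer(grid, b$start, `>=`) & outer(grid, b$end, `<`)) > 0
  sum(ina & inb) / sum(ina | inb)
}

test_that("burst detector recovers a noiseless construction", {
  sig <- alternating_signal()
  bs <- detect_bursts(sig$x, 64, on_threshold_uV = 50, off_threshold_uV = 40)
  expect_equal(nrow(bs$intervals), nrow(sig$truth))
  expect_gte(interval_jaccard(bs$intervals, sig$truth), 0.95)
})

test_that("burst detector edge cases: silence, DC, bad thresholds", {
  expect_equal(nrow(detect_bursts(numeric(640), 64)$intervals), 0)
  bs <- detect_bursts(rep(100, 64 * 20), 64)
  expect_equal(nrow(bs$intervals), 1)
  expect_equal(bs$intervals$start, 0)
  expect_equal(bs$intervals$end, 20)
  expect_error(detect_bursts(numeric(640), 64, on_threshold_uV = 5,
                             off_threshold_uV = 10),
               class = "neofba_input_error")
})

test_that("IBI features follow from the interval construction", {
  ints <- tibble::tibble(start = seq(0, 90, by = 10),
                         end = seq(0, 90, by = 10) + 5)
  f <- ibi_features(ints, duration_s = 100)
  expect_equal(f$ibi_median, 5)
  expect_equal(f$ibi_max, 5)
  expect_equal(f$suppression_fraction, 0.5)

  whole <- ibi_features(tibble::tibble(start = 0, end = 100), duration_s = 100)
  expect_equal(whole$suppression_fraction, 0)
  expect_true(is.na(whole$ibi_median))

  none <- ibi_features(tibble::tibble(start = numeric(), end = numeric()),
                       duration_s = 100)
  expect_equal(none$suppression_fraction, 1)
  expect_equal(none$burst_rate, 0)
})

test_that("detected IBIs track the generative truth on synthetic EEG", {
  rec <- simulate_preterm_eeg(25, duration = 600, fs = 64, seed = 2,
                              params = sim_params(artefact_rate = 0))
  deriv <- rec$signal["C3", ] - rec$signal["C4", ]
  bs <- detect_bursts(deriv, 64)
  det <- ibi_features(bs)
  tb <- rec$truth_bursts
  truth_med <- median(tb$start[-1] - tb$end[-nrow(tb)])
  expect_lt(abs(det$ibi_median - truth_med) / truth_med, 0.2)
})

test_that("rEEG percentiles match closed-form window amplitudes", {
  fs <- 64
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 30 * sin(2 * pi * 5 * tt)
  f <- reeg_features(x, fs)
  expect_equal(f$reeg_p5 / 60, 1, tolerance = 0.02)
  expect_equal(f$reeg_p50 / 60, 1, tolerance = 0.02)
  expect_equal(f$reeg_p95 / 60, 1, tolerance = 0.02)

  z <- reeg_features(numeric(10 * fs), fs)
  expect_equal(unlist(z), c(reeg_p5 = 0, reeg_p50 = 0, reeg_p95 = 0))

  # half the windows at amplitude A, half at B > A
  w <- rep(c(10, 40), each = 2 * fs)
  x2 <- rep(w, 15) * sin(2 * pi * 8 * seq(0, 60 - 1 / fs, by = 1 / fs))
  f2 <- reeg_features(x2, fs)
  expect_gt(f2$reeg_p50, 20)
  expect_lt(f2$reeg_p50, 80)
  expect_equal(f2$reeg_p95 / 80, 1, tolerance = 0.03)
})

test_that("relative band powers are normalised and spectrally correct", {
  fs <- 128
  set.seed(4)
  x <- rnorm(120 * fs)
  bp <- band_powers(x, fs)
  expect_equal(sum(unlist(bp)), 1, tolerance = 1e-9)
  # flat spectrum: proportions approach the bandwidth ratios
  expected <- c(3.5, 4, 5, 17) / 29.5
  expect_true(all(abs(unlist(bp) - expected) < 0.03))

  tone <- sin(2 * pi * 2 * seq(0, 30, by = 1 / fs))
  expect_gte(band_powers(tone, fs)$relpow_delta, 0.99)
  expect_error(band_powers(x, fs = 50), class = "neofba_band_error")
})

test_that("sample entropy matches the naive O(N^2) oracle exactly", {
  set.seed(7)
  x <- rnorm(500)
  got <- sample_entropy(x, fs = 64, target_fs = 64)
  want <- sampen_oracle(x, m = 2, r = 0.2 * sd(x))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("sample entropy orders regular below irregular signals", {
  expect_equal(sample_entropy(rep(5, 1000), fs = 64, target_fs = 64), 0)
  sq <- rep(c(1, -1), each = 8, times = 40)
  set.seed(8)
  wn <- rnorm(length(sq), sd = sd(sq))
  expect_lt(sample_entropy(sq, 64, target_fs = 64),
            sample_entropy(wn, 64, target_fs = 64))
})

test_that("suppression curve is a monotone CDF with correct summaries", {
  sc <- suppression_curve(rep(10, 100), thresholds = 0:50)
  expect_equal(sc$curve$fraction[sc$curve$threshold <= 10], rep(0, 11))
  expect_equal(sc$curve$fraction[sc$curve$threshold > 10], rep(1, 40))
  expect_equal(sc$sc_theta50, 11)

  set.seed(9)
  rand <- suppression_curve(abs(rnorm(500, sd = 15)))
  expect_true(all(diff(rand$curve$fraction) >= 0))
  expect_error(suppression_curve(numeric()), class = "neofba_input_error")
  expect_error(suppression_curve(1:10, thresholds = c(3, 2, 1)),
               class = "neofba_input_error")
})

test_that("suppression curve at the midway threshold matches truth", {
  rec <- simulate_preterm_eeg(27, duration = 300, fs = 64, seed = 3,
                              params = sim_params(artefact_rate = 0))
  deriv <- rec$signal["C3", ] - rec$signal["C4", ]
  bs <- detect_bursts(deriv, 64)
  p <- sim_params()
  # envelope RMS is ~amp/4 per channel; a bipolar derivation keeps only the
  # channel-independent part, scaling amplitudes by sqrt(2 (1 - rho))
  lerp <- function(a25, a38) a25 + (a38 - a25) * (27 - 25) / 13
  deriv_scale <- sqrt(2 * (1 - p$channel_correlation))
  inter <- lerp(p$interburst_amp_at_25wk, p$interburst_amp_at_38wk) / 4
  burst <- lerp(p$burst_amp_at_25wk, p$burst_amp_at_38wk) / 4
  theta_star <- (inter + burst) / 2 * deriv_scale
  sc <- suppression_curve(bs$envelope,
                          thresholds = sort(c(0:50, theta_star)))
  s_at <- sc$curve$fraction[sc$curve$threshold == theta_star]
  tb <- rec$truth_bursts
  truth_supp <- 1 - sum(tb$end - tb$start) / 300
  expect_lt(abs(s_at - truth_supp), 0.1)
})

test_that("burst shape features behave on constructed shapes", {
  fs <- 64
  tri <- c(seq(0, 1, length.out = fs), seq(1, 0, length.out = fs))
  env <- c(rep(0, fs), rep(tri, 3) * 50, rep(0, fs))
  ints <- tibble::tibble(start = 1 + (0:2) * 2, end = 3 + (0:2) * 2)
  f <- burst_shape_features(ints, envelope = env, fs = fs)
  expect_lt(abs(f$burst_shape_skew), 1e-6)
  expect_equal(f$burst_dur_logsd, 0)

  # fast rise, slow decay: sign agrees with the direct shape-moment oracle
  fr <- c(seq(0, 1, length.out = round(0.2 * fs)),
          seq(1, 0, length.out = round(1.8 * fs)))
  env2 <- c(rep(0, fs), rep(c(fr * 40, rep(0, fs)), 3))
  ints2 <- tibble::tibble(start = 1 + (0:2) * 3, end = 3 + (0:2) * 3)
  f2 <- burst_shape_features(ints2, envelope = env2, fs = fs)
  expect_equal(sign(f2$burst_shape_skew), sign(shape_skew_oracle(fr)))

  durs <- tibble::tibble(start = c(0, 10, 20), end = c(1, 12, 24))
  f3 <- burst_shape_features(durs, envelope = rep(30, 64 * 30), fs = 64)
  expect_equal(f3$burst_dur_logmean, mean(log(c(1, 2, 4))))

  two <- burst_shape_features(durs[1:2, ], envelope = rep(30, 64 * 30), fs = 64)
  expect_true(is.na(two$burst_dur_logmean))
})

test_that("feature assembly aggregates derivations and honours the mask", {
  fs <- 64
  set.seed(11)
  y <- rnorm(60 * fs, sd = 30)
  sig <- rbind(y, 0, y, 0)
  rec <- eeg_recording(sig, fs, c("C3", "C4", "T3", "T4"),
                       recording_id = "r1", infant_id = "i1", pma_weeks = 30)
  cfg2 <- qeeg_config(montage = montage_spec(c("C3-C4", "T3-T4")),
                      epoch_s = 60, min_duration_s = 60)
  cfg1 <- qeeg_config(montage = montage_spec("C3-C4"),
                      epoch_s = 60, min_duration_s = 60)
  f2 <- assemble_features(rec, NULL, c(0, 60), cfg2)
  f1 <- assemble_features(rec, NULL, c(0, 60), cfg1)
  expect_equal(f2[, qeeg_feature_names()], f1[, qeeg_feature_names()])

  expect_true(all(is.finite(unlist(f2[, setdiff(qeeg_feature_names(),
    c("ibi_median", "ibi_max", "burst_dur_logmean", "burst_dur_logsd",
      "burst_shape_skew", "burst_shape_kurt"))]))))
  expect_equal(f2$relpow_delta + f2$relpow_theta + f2$relpow_alpha +
                 f2$relpow_beta, 1, tolerance = 1e-9)
})

test_that("an artefact confined to masked time cannot change the features", {
  rec <- simulate_preterm_eeg(29, duration = 300, fs = 64, seed = 6,
                              params = sim_params(artefact_rate = 0))
  mask <- structure(list(intervals = tibble::tibble(start = 100, end = 110),
                         total_masked_s = 10, duration_s = 300),
                    class = "artefact_mask")
  cfg <- qeeg_config(epoch_s = 300, min_duration_s = 300)
  before <- assemble_features(rec, mask, c(0, 300), cfg)
  rec$signal[, (102 * 64):(104 * 64)] <- 5000
  after <- assemble_features(rec, mask, c(0, 300), cfg)
  expect_equal(before[, qeeg_feature_names()], after[, qeeg_feature_names()],
               tolerance = 1e-9)
})

test_that("amplitude scaling propagates as expected through the features", {
  set.seed(12)
  x <- rnorm(60 * 64, sd = 15)
  r1 <- reeg_features(x, 64); r2 <- reeg_features(2 * x, 64)
  expect_equal(unlist(r2), 2 * unlist(r1), tolerance = 1e-9)
  b1 <- band_powers(x, 64); b2 <- band_powers(2 * x, 64)
  expect_equal(unlist(b1), unlist(b2), tolerance = 1e-9)
  s1 <- sample_entropy(x, 64, target_fs = 64)
  s2 <- sample_entropy(2 * x, 64, target_fs = 64)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("the maturational trend survives the feature layer", {
  feats <- purrr::map_dfr(c(25, 31, 37), function(pma) {
    purrr::map_dfr(1:3, function(s) {
      rec <- simulate_preterm_eeg(pma, duration = 300, fs = 64, seed = s,
                                  recording_id = sprintf("p%d_s%d", pma, s),
                                  params = sim_params(artefact_rate = 0))
      cbind(pma = pma,
            assemble_features(rec, NULL, c(0, 300),
                              qeeg_config(epoch_s = 300, min_duration_s = 300)))
    })
  })
  med <- feats |>
    dplyr::group_by(pma) |>
    dplyr::summarise(ibi = median(ibi_median), amp = median(reeg_p50),
                     supp = median(suppression_fraction))
  expect_true(all(diff(med$ibi) < 0))
  expect_true(all(diff(med$supp) < 0))
  # the amplitude median rises while the EEG is discontinuous; towards term
  # the declining burst amplitude caps it, so the check stops at 31 wk
  expect_gt(med$amp[med$pma == 31], med$amp[med$pma == 25])
})
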