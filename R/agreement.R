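#' Bootstrap comparison of two panels' ICCs
#'
#' Recordings are resampled with replacement jointly from both panels (the
#' same resampled recording set enters both ICCs, preserving the pairing),
#' the ICC difference is computed per replicate, and the percentile 2.5/97.5
#' bounds form the 95% CI; the difference is called significant when that
#' interval excludes zero.
#'
#' @param table_a,table_b Long estimate tables. Paired resampling (the
#'   default) requires them to cover the same recordings; with
#'   `paired = FALSE` (e.g. comparing disjoint subgroups) each table's
#'   recordings are resampled independently.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @param paired Resample the same recordings jointly from both tables?
#' @return A one-row tibble: `delta_icc` (`ICC_A - ICC_B` on the full data),
#'   `ci_low`, `ci_high`, `significant`, `icc_a`, `icc_b`, `n`, `n_boot`.
#' @export
bootstrap_icc_difference <- function(table_a, table_b, n_boot = 1000,
                                     seed = 1, conf_level = 0.95,
                                     paired = TRUE) {
  ma <- panel_matrix(table_a)
  mb <- panel_matrix(table_b)
  if (paired) {
    shared <- intersect(rownames(ma), rownames(mb))
    if (length(shared) < 3)
      abort("panels share too few recordings for paired resampling",
            class = "neofba_pairing_error")
    ma <- ma[shared, , drop = FALSE]
    mb <- mb[shared, , drop = FALSE]
  }
  icc_a <- icc21_point(icc_mean_squares(ma))
  icc_b <- icc21_point(icc_mean_squares(mb))
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    ia <- sample(nrow(ma), replace = TRUE)
    ib <- if (paired) ia else sample(nrow(mb), replace = TRUE)
    icc21_point(icc_mean_squares(ma[ia, , drop = FALSE])) -
      icc21_point(icc_mean_squares(mb[ib, , drop = FALSE]))
  }, 0))
  ci <- unname(quantile(reps, c((1 - conf_level) / 2,
                                1 - (1 - conf_level) / 2), na.rm = TRUE))
  tibble::tibble(delta_icc = icc_a - icc_b, ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 | ci[2] < 0,
                 icc_a = icc_a, icc_b = icc_b,
                 n = nrow(ma), n_boot = n_boot)
}

#' Pearson correlation with percentile bootstrap CI
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @param n_boot Number of paired resamples.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
pearson_bootstrap_ci <- function(x, y, n_boot = 1000, seed = 1,
                                 conf_level = 0.95) {
  if (length(x) != length(y)) stop_input("x and y must be paired")
  if (length(x) < 3) stop_input("need >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant input",
          class = "neofba_degenerate_error")
  r <- cor(x, y)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample(length(x), replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx]))
  }, 0))
  ci <- unname(quantile(reps, c((1 - conf_level) / 2,
                                1 - (1 - conf_level) / 2), na.rm = TRUE))
  tibble::tibble(r = r, ci_low = ci[1], ci_high = ci[2],
                 n = length(x), n_boot = n_boot)
}

#' Kruskal-Wallis test for systematic rater differences
#'
#' Tests whether raters' estimate distributions share a location: groups are
#' the raters, observations their estimates across recordings; rank-based H
#' with tie correction, chi-square reference with `k - 1` df.
#'
#' @param table Long estimate table with `rater_id` and `estimate_weeks`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `k`, `n`.
#' @export
kruskal_wallis_rater_effect <- function(table) {
  table <- tibble::as_tibble(table)
  groups <- split(table$estimate_weeks, table$rater_id)
  if (length(groups) < 2) stop_input("need >= 2 raters")
  if (any(lengths(groups) == 0)) stop_input("empty rater group")
  kt <- kruskal.test(groups)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, k = length(groups),
                 n = length(groups[[1]]))
}
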