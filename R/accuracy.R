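#' Systematic/random error decomposition of age estimates
#'
#' Errors are `e = estimate - truth`; the systematic error is their mean
#' (bias), the random error their sample standard deviation (imprecision).
#' Accuracy bands count recordings within 1 and 2 weeks of the truth,
#' boundaries inclusive.
#'
#' @param estimates,truth Paired numeric vectors of weeks, `n >= 2`.
#' @return A one-row tibble of class `error_summary`: `n`,
#'   `systematic_error`, `random_error`, `pearson_r`, `pct_within_1wk`,
#'   `pct_within_2wk`.
#' @examples
#' error_summary(c(31, 31, 36), c(30, 32, 34))
#' @export
error_summary <- function(estimates, truth) {
  if (length(estimates) != length(truth))
    stop_input("estimates and truth must be paired")
  if (length(estimates) < 2) stop_input("need >= 2 recordings")
  e <- estimates - truth
  r <- if (sd(estimates) == 0 || sd(truth) == 0) NA_real_ else
    cor(estimates, truth)
  out <- tibble::tibble(
    n = length(e),
    systematic_error = mean(e),
    random_error = sd(e),
    pearson_r = r,
    pct_within_1wk = 100 * mean(abs(e) <= 1),
    pct_within_2wk = 100 * mean(abs(e) <= 2)
  )
  structure(out, class = c("error_summary", class(out)))
}

#' Ensemble (group-average) age estimate
#'
#' The arithmetic mean across raters per recording; with independent rater
#' noise its random error shrinks like `sigma / sqrt(k)`, which is why the
#' group average tracks the truth better than any individual rater.
#'
#' @param table Complete long estimate table.
#' @return A tibble, one row per recording: `recording_id`, `infant_id`,
#'   `pma_weeks`, `estimate_weeks` (the ensemble mean), `n_raters`.
#' @export
ensemble_estimate <- function(table) {
  table <- tibble::as_tibble(table)
  if (anyNA(table$estimate_weeks))
    stop_input("estimate table is incomplete")
  k <- length(unique(table$rater_id))
  counts <- dplyr::count(table, .data$recording_id)
  if (any(counts$n != k))
    stop_input("estimate table is incomplete: unequal raters per recording")
  table |>
    dplyr::group_by(.data$recording_id, .data$infant_id, .data$pma_weeks) |>
    dplyr::summarise(estimate_weeks = mean(.data$estimate_weeks),
                     n_raters = dplyr::n(), .groups = "drop")
}

#' Per-rater and ensemble error summaries for a panel
#'
#' @param table Long estimate table.
#' @return A tibble with one [error_summary()] row per rater plus one for
#'   the ensemble average (`rater_id = "ensemble"`).
#' @export
panel_error_summary <- function(table) {
  table <- tibble::as_tibble(table)
  per <- table |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::group_modify(~ error_summary(.x$estimate_weeks, .x$pma_weeks)) |>
    dplyr::ungroup()
  ens <- ensemble_estimate(table)
  dplyr::bind_rows(
    per,
    dplyr::bind_cols(tibble::tibble(rater_id = "ensemble"),
                     error_summary(ens$estimate_weeks, ens$pma_weeks)))
}

#' Compare systematic errors (means) of two estimators
#'
#' Paired t-test on the error differences, or Welch's t-test with
#' Satterthwaite df for unpaired samples. Cohen's d uses the SD of the
#' paired differences (matching the paired-t construction) or the pooled SD
#' when unpaired.
#'
#' @param errors_a,errors_b Numeric error vectors (estimate - truth), weeks.
#' @param paired Paired comparison (same recordings)?
#' @return A one-row tibble: `test`, `t`, `df`, `p_value`, `cohens_d`.
#' @export
compare_systematic_error <- function(errors_a, errors_b, paired = TRUE) {
  if (paired && length(errors_a) != length(errors_b))
    stop_input("paired comparison needs equal lengths")
  if (length(errors_a) < 3 || length(errors_b) < 3)
    stop_input("need >= 3 errors per sample")
  if (paired) {
    d <- errors_a - errors_b
    if (sd(d) == 0) {
      return(tibble::tibble(test = "paired_t", t = 0,
                            df = length(d) - 1, p_value = 1, cohens_d = 0))
    }
    tt <- t.test(errors_a, errors_b, paired = TRUE)
    cd <- mean(d) / sd(d)
    test <- "paired_t"
  } else {
    if (sd(errors_a) == 0 && sd(errors_b) == 0)
      abort("zero variance in both samples", class = "neofba_degenerate_error")
    tt <- t.test(errors_a, errors_b, var.equal = FALSE)
    na <- length(errors_a); nb <- length(errors_b)
    sp <- sqrt(((na - 1) * var(errors_a) + (nb - 1) * var(errors_b)) /
                 (na + nb - 2))
    cd <- (mean(errors_a) - mean(errors_b)) / sp
    test <- "welch_t"
  }
  tibble::tibble(test = test, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 cohens_d = cd)
}

#' Compare random errors (variances) of two estimators
#'
#' Paired samples use the Pitman-Morgan test: with `D = A - B` and
#' `S = A + B`, equality of the two variances is equivalent to zero
#' correlation between D and S, tested by
#' `t = r_DS * sqrt((n - 2) / (1 - r_DS^2))` on `n - 2` df (two-sided).
#' Identical inputs are a defined boundary case: statistic 0, p = 1.
#' Unpaired samples use Bartlett's chi-square test.
#'
#' @param errors_a,errors_b Numeric error vectors, weeks; paired comparisons
#'   need equal lengths and `n >= 4`.
#' @param paired Paired comparison?
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
compare_random_error <- function(errors_a, errors_b, paired = TRUE) {
  if (paired) {
    if (length(errors_a) != length(errors_b))
      stop_input("paired comparison needs equal lengths")
    n <- length(errors_a)
    if (n < 4) stop_input("Pitman-Morgan needs n >= 4")
    d <- errors_a - errors_b
    s <- errors_a + errors_b
    if (sd(d) == 0)
      return(tibble::tibble(test = "pitman_morgan", statistic = 0,
                            df = n - 2, p_value = 1))
    if (sd(s) == 0)
      abort("sum variance is zero: Pitman-Morgan undefined",
            class = "neofba_degenerate_error")
    r_ds <- cor(d, s)
    t_stat <- r_ds * sqrt((n - 2) / (1 - r_ds^2))
    tibble::tibble(test = "pitman_morgan", statistic = t_stat, df = n - 2,
                   p_value = 2 * pt(-abs(t_stat), n - 2))
  } else {
    bt <- bartlett.test(list(errors_a, errors_b))
    tibble::tibble(test = "bartlett", statistic = unname(bt$statistic),
                   df = unname(bt$parameter), p_value = bt$p.value)
  }
}
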