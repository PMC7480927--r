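#' Subgroup (normal vs abnormal) agreement and accuracy analysis
#'
#' Splits a panel's recordings by an abnormality label and reports, per
#' group, the panel ICC and the ensemble error summary; between groups, a
#' Welch t-test on the ensemble errors (systematic), Bartlett's test
#' (random) and a bootstrap ICC difference. Because an abnormality analysis
#' is typically repeated under several alternative groupings (e.g. visual
#' annotation, brain lesions, developmental outcome), all p-values are
#' Bonferroni-multiplied by `n_groupings` (capped at 1) and the CIs use the
#' correspondingly divided alpha.
#'
#' @param table Long estimate table (see [simulate_rater_panel()]).
#' @param labels Data frame `recording_id`, `abnormal` (logical), one row
#'   per recording; both groups must have `n >= 3`.
#' @param n_groupings Number of groupings the correction accounts for.
#' @param n_boot,seed Bootstrap settings for the ICC comparison.
#' @return An object of class `fba_subgroups`: list with `per_group`
#'   (tibble of group, n, icc and error-summary columns), `tests` (tibble
#'   `test`, `statistic`, `p_value`, `p_adj`), `icc_difference`,
#'   `n_groupings`.
#' @export
subgroup_analysis <- function(table, labels, n_groupings = 3, n_boot = 1000,
                              seed = 1) {
  table <- tibble::as_tibble(table)
  labels <- tibble::as_tibble(labels)
  if (!all(c("recording_id", "abnormal") %in% names(labels)))
    stop_input("labels must have recording_id and abnormal columns")
  tab <- dplyr::inner_join(table, labels, by = "recording_id")
  groups <- split(tab, tab$abnormal)
  if (length(groups) < 2 ||
      any(vapply(groups, function(g) length(unique(g$recording_id)), 0L) < 3))
    abort("both normal and abnormal groups need >= 3 recordings",
          class = "neofba_groupsize_error")
  conf_level <- 1 - 0.05 / n_groupings

  summarise_group <- function(g, name) {
    ic <- icc_agreement(g, conf_level = conf_level)
    ens <- ensemble_estimate(g)
    dplyr::bind_cols(
      tibble::tibble(group = name, icc = ic$icc, icc_ci_low = ic$ci_low,
                     icc_ci_high = ic$ci_high),
      error_summary(ens$estimate_weeks, ens$pma_weeks))
  }
  per_group <- dplyr::bind_rows(
    summarise_group(groups[["FALSE"]], "normal"),
    summarise_group(groups[["TRUE"]], "abnormal"))

  err <- function(g) {
    ens <- ensemble_estimate(g)
    ens$estimate_weeks - ens$pma_weeks
  }
  e_norm <- err(groups[["FALSE"]]); e_abn <- err(groups[["TRUE"]])
  mt <- compare_systematic_error(e_norm, e_abn, paired = FALSE)
  vt <- compare_random_error(e_norm, e_abn, paired = FALSE)
  dicc <- bootstrap_icc_difference(groups[["FALSE"]], groups[["TRUE"]],
                                   n_boot = n_boot, seed = seed,
                                   conf_level = conf_level, paired = FALSE)

  tests <- tibble::tibble(
    test = c(mt$test, vt$test),
    statistic = c(mt$t, vt$statistic),
    p_value = c(mt$p_value, vt$p_value),
    p_adj = pmin(c(mt$p_value, vt$p_value) * n_groupings, 1))

  structure(list(per_group = per_group, tests = tests,
                 icc_difference = dicc, n_groupings = n_groupings),
            class = "fba_subgroups")
}

#' @export
print.fba_subgroups <- function(x, ...) {
  cat(sprintf("<fba_subgroups> Bonferroni x%d\n", x$n_groupings))
  print(x$per_group)
  print(x$tests)
  invisible(x)
}

#' Tidy a subgroup analysis
#' @param x A [subgroup_analysis()] result.
#' @param ... Unused.
#' @return The between-group test tibble with adjusted p-values.
#' @export
tidy.fba_subgroups <- function(x, ...) x$tests

#' Bonferroni adjustment helper
#'
#' Multiplies p-values by the number of groupings examined, capped at 1 —
#' the correction applied when an abnormality analysis is repeated under
#' several alternative grouping definitions.
#'
#' @param p Numeric vector of p-values.
#' @param n_groupings Number of groupings corrected for.
#' @return Adjusted p-values.
#' @export
bonferroni_groupings <- function(p, n_groupings = 3) pmin(p * n_groupings, 1)
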