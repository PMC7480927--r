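#' Trajectory analysis: per-infant stability of age estimates
#'
#' For tracking maturation across serial recordings, the quantity that
#' matters is the within-infant spread of the estimation error: the SD of
#' `estimate - truth` over each infant's recordings, per method. Infants
#' with fewer than two recordings carry no within-infant information and
#' are dropped. The per-infant SDs are log-transformed (zeros floored at
#' `log_floor` first, since log 0 is undefined), compared across methods by
#' one-way ANOVA with Levene's test (absolute deviations from group means)
#' checking variance homogeneity, and Tukey's HSD giving pairwise adjusted
#' p-values.
#'
#' @param data Long tibble, one row per (recording, method): columns
#'   `infant_id`, `method`, `estimate_weeks`, `pma_weeks`.
#' @param log_floor Floor applied to zero SDs before the log transform
#'   (weeks).
#' @return An object of class `fba_trajectory`: list with `per_infant_sd`
#'   (tibble `infant_id`, `method`, `sd_weeks`, `n_recordings`), `anova`
#'   (tibble `F`, `df1`, `df2`, `p_value`), `levene_p`, `tukey` (tibble
#'   `comparison`, `diff`, `p_adj`), `n_infants`.
#' @export
trajectory_analysis <- function(data, log_floor = 0.01) {
  data <- tibble::as_tibble(data)
  need <- c("infant_id", "method", "estimate_weeks", "pma_weeks")
  if (!all(need %in% names(data)))
    stop_input("data must have infant_id, method, estimate_weeks, pma_weeks")
  methods <- unique(data$method)
  if (length(methods) < 2) stop_input("need >= 2 methods to compare")

  per <- data |>
    dplyr::group_by(.data$infant_id, .data$method) |>
    dplyr::summarise(
      sd_weeks = sd(.data$estimate_weeks - .data$pma_weeks),
      n_recordings = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_recordings >= 2)
  counts <- dplyr::count(per, .data$method)
  if (any(counts$n < 3) || nrow(counts) < 2)
    stop_input("each method needs >= 3 infants with >= 2 recordings")
  if (any(tapply(per$sd_weeks, per$method, function(v) all(v == 0))))
    abort("all per-infant SDs are zero within a method group",
          class = "neofba_degenerate_error")

  per$log_sd <- log(pmax(per$sd_weeks, log_floor))
  per$method <- factor(per$method)
  fit <- aov(log_sd ~ method, data = per)
  at <- anova(fit)
  lev <- car::leveneTest(log_sd ~ method, data = per, center = mean)
  tk <- TukeyHSD(fit)$method

  structure(list(
    per_infant_sd = dplyr::select(per, "infant_id", "method", "sd_weeks",
                                  "n_recordings"),
    anova = tibble::tibble(F = at$`F value`[1], df1 = at$Df[1],
                           df2 = at$Df[2], p_value = at$`Pr(>F)`[1]),
    levene_p = lev$`Pr(>F)`[1],
    tukey = tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                           p_adj = tk[, "p adj"]),
    n_infants = length(unique(per$infant_id))
  ), class = "fba_trajectory")
}

#' @export
print.fba_trajectory <- function(x, ...) {
  cat(sprintf("<fba_trajectory> %d infants; ANOVA F(%d, %d) = %.2f, p = %.3g\n",
              x$n_infants, x$anova$df1, x$anova$df2, x$anova$F,
              x$anova$p_value))
  invisible(x)
}

#' Tidy a trajectory analysis
#' @param x A [trajectory_analysis()] result.
#' @param ... Unused.
#' @return Tibble of Tukey pairwise comparisons with the ANOVA F and p
#'   attached.
#' @export
tidy.fba_trajectory <- function(x, ...) {
  dplyr::mutate(x$tukey, anova_F = x$anova$F, anova_p = x$anova$p_value,
                levene_p = x$levene_p)
}
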