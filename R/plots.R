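# Semilogarithmic aEEG display transform: linear below 10 uV, logarithmic
# above — the classic cerebral-function-monitor paper speed axis.
aeeg_trans <- function() {
  fwd <- function(y) ifelse(y <= 10, y, 10 + 10 * log10(pmax(y, 10) / 10))
  inv <- function(y) ifelse(y <= 10, y, 10 * 10^((y - 10) / 10))
  scales::trans_new("aeeg_semilog", fwd, inv,
                    breaks = function(x) c(0, 5, 10, 25, 50, 100))
}

#' Plot an aEEG trace
#'
#' Ribbon between the per-window envelope minimum and maximum, on the
#' conventional semilogarithmic amplitude axis (linear to 10 uV,
#' logarithmic above).
#'
#' @param object An `aeeg_trace` from [compute_aeeg()].
#' @param semilog Use the semilogarithmic display axis?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aeeg_trace <- function(object, semilog = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time / 3600)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "Time (h)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
  if (semilog) p <- p + ggplot2::scale_y_continuous(trans = aeeg_trans())
  p
}

#' Plot cross-validated FBA against true age
#'
#' Scatter of the leave-one-infant-out FBA versus PMA with the identity
#' line; serial recordings of one infant are connected.
#'
#' @param object An `fba_loocv` result from [loo_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fba_loocv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pma_weeks,
                                       y = .data$fba_weeks)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(group = .data$infant_id),
                       alpha = 0.4, colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick", size = 1.6) +
    ggplot2::labs(x = "PMA (weeks)", y = "FBA (weeks)") +
    ggplot2::theme_minimal()
}

#' Error-distribution plot for rater panels
#'
#' Kernel density of `estimate - PMA` per modality, the at-a-glance
#' comparison of systematic (location) and random (width) error.
#'
#' @param table Long estimate table with `modality`, `estimate_weeks`,
#'   `pma_weeks`.
#' @return A ggplot.
#' @export
plot_error_density <- function(table) {
  table <- tibble::as_tibble(table)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$estimate_weeks -
                                        .data$pma_weeks,
                                      fill = .data$modality)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Estimate − PMA (weeks)", y = "Density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
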