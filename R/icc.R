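# Two-way mean squares of an n x k ratings matrix (rows = targets,
# columns = raters): the building blocks of ICC(2,1).
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

icc21_point <- function(ms) {
  with(ms, (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
}

# Closed-form 95% CI for ICC(2,1) (two-way random effects, absolute
# agreement, single rater): F-based interval with Satterthwaite df.
icc21_ci_f <- function(ms, icc, conf_level = 0.95) {
  alpha <- 1 - conf_level
  n <- ms$n; k <- ms$k
  if (!is.finite(icc) || icc >= 1) return(c(icc, icc))
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  c(lower, upper)
}

#' Intraclass correlation for a panel of raters
#'
#' ICC(2,1): two-way random-effects, absolute-agreement, single-rater
#' intraclass correlation — the model in which the panel is a random sample
#' of judges from a larger population and every judge rates every
#' recording. Computed from the two-way mean squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The 95% CI is the
#' closed-form F-based interval by default; `ci_method = "bootstrap"`
#' resamples recordings with percentile bounds.
#'
#' @param table Long estimate table (see [simulate_rater_panel()]): columns
#'   `recording_id`, `rater_id`, `estimate_weeks`; must be complete, with
#'   `n >= 3` recordings, `k >= 2` raters and non-zero between-recording
#'   variance.
#' @param ci_method `"fisher"` (closed-form F) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap settings when `ci_method = "bootstrap"`.
#' @param conf_level Confidence level.
#' @return An object of class `fba_icc` (list: `icc`, `ci_low`, `ci_high`,
#'   `k`, `n`, `method`, `conf_level`); see [tidy.fba_icc()].
#' @examples
#' truth <- tibble::tibble(recording_id = sprintf("r%02d", 1:20),
#'                         infant_id = sprintf("i%02d", 1:20),
#'                         pma_weeks = runif(20, 25, 38))
#' panel <- simulate_rater_panel(truth, rater_panel_aeeg(), seed = 2)
#' icc_agreement(panel)
#' @export
icc_agreement <- function(table, ci_method = c("fisher", "bootstrap"),
                          n_boot = 1000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  m <- panel_matrix(table)
  if (nrow(m) < 3) stop_input("ICC needs >= 3 recordings")
  if (ncol(m) < 2) stop_input("ICC needs >= 2 raters")
  if (var(rowMeans(m)) == 0)
    abort("zero between-recording variance: ICC undefined",
          class = "neofba_degenerate_error")
  ms <- icc_mean_squares(m)
  icc <- icc21_point(ms)
  ci <- if (ci_method == "fisher") {
    icc21_ci_f(ms, icc, conf_level)
  } else {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      mb <- m[sample(nrow(m), replace = TRUE), , drop = FALSE]
      icc21_point(icc_mean_squares(mb))
    }, 0))
    unname(quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    na.rm = TRUE))
  }
  structure(list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
                 k = ms$k, n = ms$n, method = ci_method,
                 conf_level = conf_level),
            class = "fba_icc")
}

#' @export
print.fba_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%.0f%% CI %.3f-%.3f), n = %d, k = %d [%s]\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$k,
              x$method))
  invisible(x)
}

#' Tidy an ICC result
#' @param x An [icc_agreement()] result.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `k`, `n`, `method`.
#' @export
tidy.fba_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 k = x$k, n = x$n, method = x$method)
}
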