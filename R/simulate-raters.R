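#' Simulate a panel of raters estimating PMA
#'
#' For every recording and rater, the estimate is
#' `truth + bias_r + e`, `e ~ N(0, sd_r^2)`, then optionally rounded and
#' clipped — the generative inverse of the systematic/random error
#' decomposition used to score raters. The returned long table is the input
#' for all agreement and accuracy analyses.
#'
#' @param truth Data frame with columns `recording_id`, `infant_id`,
#'   `pma_weeks` (e.g. [cohort_manifest()] output); `recording_id` must be
#'   unique.
#' @param raters List of [rater_spec()] objects (e.g. [rater_panel_eeg()]).
#' @param seed Integer seed.
#' @param modality Label attached to every row (`"EEG"`, `"aEEG"`, `"FBA"`).
#' @return A tibble in long format: `recording_id`, `infant_id`,
#'   `pma_weeks`, `modality`, `rater_id`, `estimate_weeks`; complete (every
#'   rater scores every recording).
#' @examples
#' truth <- tibble::tibble(recording_id = c("a", "b"),
#'                         infant_id = c("i1", "i2"),
#'                         pma_weeks = c(27, 31))
#' simulate_rater_panel(truth, rater_panel_aeeg(), seed = 1, modality = "aEEG")
#' @export
simulate_rater_panel <- function(truth, raters, seed = 1, modality = "EEG") {
  truth <- tibble::as_tibble(truth)
  need <- c("recording_id", "infant_id", "pma_weeks")
  if (!all(need %in% names(truth)))
    stop_input("truth must have columns recording_id, infant_id, pma_weeks")
  if (nrow(truth) < 1) stop_input("at least one recording is required")
  if (anyDuplicated(truth$recording_id))
    stop_input("duplicate recording_id in truth table")
  if (length(raters) < 1) stop_input("at least one rater is required")
  if (inherits(raters, "rater_spec")) raters <- list(raters)

  purrr::map_dfr(raters, function(r) {
    stopifnot(inherits(r, "rater_spec"))
    est <- with_seed(derive_seed(seed, paste0("rater-", r$rater_id)),
                     truth$pma_weeks + r$bias + rnorm(nrow(truth), 0, r$sd))
    if (!is.null(r$rounding)) est <- round(est / r$rounding) * r$rounding
    if (!is.null(r$clip_range))
      est <- pmin(pmax(est, r$clip_range[1]), r$clip_range[2])
    tibble::tibble(recording_id = truth$recording_id,
                   infant_id = truth$infant_id,
                   pma_weeks = truth$pma_weeks,
                   modality = modality,
                   rater_id = r$rater_id,
                   estimate_weeks = est)
  })
}

# Wide n x k matrix of estimates (rows = recordings, columns = raters) from
# the long panel format; errors on missing cells.
panel_matrix <- function(table, require_complete = TRUE) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(table), "recording_id", "rater_id",
                  "estimate_weeks"),
    names_from = "rater_id", values_from = "estimate_weeks")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$recording_id
  if (require_complete && anyNA(m))
    stop_input("estimate table is incomplete: every rater must score every recording")
  m
}
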