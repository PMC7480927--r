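#' Read and write rater-estimate tables as TSV
#'
#' The long format exchanged by the agreement and accuracy layers: one row
#' per (recording, rater) with columns `recording_id`, `infant_id`,
#' `pma_weeks`, `modality`, `rater_id`, `estimate_weeks`.
#'
#' @param table Long estimate table (see [simulate_rater_panel()]).
#' @param path File path.
#' @return `read_estimates_tsv()` returns a tibble; `write_estimates_tsv()`
#'   returns `path` invisibly.
#' @export
write_estimates_tsv <- function(table, path) {
  need <- c("recording_id", "infant_id", "pma_weeks", "modality",
            "rater_id", "estimate_weeks")
  table <- tibble::as_tibble(table)
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop_input(sprintf("estimate table lacks columns: %s",
                       paste(missing, collapse = ", ")))
  utils::write.table(table[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_tsv
#' @export
read_estimates_tsv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
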