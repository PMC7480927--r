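#' Bipolar montage specification
#'
#' An ordered list of electrode-pair derivations; derivation `k` of a
#' montaged recording is `signal(A_k) - signal(B_k)`, labelled `"A-B"`.
#'
#' @param derivations Character vector of `"A-B"` pairs, or a 2-column
#'   matrix/data frame of electrode labels.
#' @return An object of class `montage_spec`.
#' @examples
#' montage_spec(c("C3-C4", "Fp1-T3"))
#' @export
montage_spec <- function(derivations) {
  if (is.character(derivations)) {
    parts <- strsplit(derivations, "-", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop_input("derivations must be 'A-B' electrode pairs")
    m <- do.call(rbind, parts)
  } else {
    m <- as.matrix(derivations)
    if (ncol(m) != 2) stop_input("derivations must have two electrode columns")
  }
  if (any(m[, 1] == m[, 2]))
    stop_input("a derivation cannot pair an electrode with itself")
  structure(list(a = m[, 1], b = m[, 2]), class = "montage_spec")
}

#' Default neonatal review montages
#'
#' `montage_default_eeg()` is the 10-derivation bipolar montage used for
#' conventional neonatal EEG review on the 9-electrode layout;
#' `montage_default_aeeg()` is the single central derivation C3-C4 used for
#' the compressed aEEG trend.
#'
#' @return A [montage_spec()].
#' @export
montage_default_eeg <- function() {
  montage_spec(c("Fp1-T3", "T3-O1", "Fp2-T4", "T4-O2", "Fp1-C3", "C3-O1",
                 "Fp2-C4", "C4-O2", "T3-C3", "C4-T4"))
}

#' @rdname montage_default_eeg
#' @export
montage_default_aeeg <- function() montage_spec("C3-C4")

#' Apply a bipolar montage
#'
#' @param recording An [eeg_recording()] in a referential layout.
#' @param montage A [montage_spec()]; every electrode must exist among the
#'   recording's channel labels.
#' @return A derived [eeg_recording()] whose channels are the requested
#'   derivations, in order, labelled `"A-B"`.
#' @examples
#' rec <- simulate_preterm_eeg(30, duration = 20, fs = 64, seed = 1)
#' mon <- apply_montage(rec, montage_default_aeeg())
#' mon$channel_labels
#' @export
apply_montage <- function(recording, montage) {
  stopifnot(inherits(montage, "montage_spec"))
  missing <- setdiff(unique(c(montage$a, montage$b)), recording$channel_labels)
  if (length(missing) > 0)
    abort(sprintf("montage electrodes not in recording: %s",
                  paste(missing, collapse = ", ")),
          class = "neofba_montage_error")
  out <- recording$signal[montage$a, , drop = FALSE] -
    recording$signal[montage$b, , drop = FALSE]
  labels <- paste0(montage$a, "-", montage$b)
  eeg_recording(out, recording$fs, labels,
                infant_id = recording$infant_id,
                recording_id = recording$recording_id,
                pma_weeks = recording$pma_weeks,
                truth_bursts = recording$truth_bursts,
                truth_artefacts = recording$truth_artefacts,
                annotations = recording$annotations)
}
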