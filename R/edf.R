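# 16-bit EDF (European Data Format) reader/writer. EDF stores a 256-byte
# fixed header, 256 bytes of per-signal headers, then data records of
# little-endian int16 samples, one block per signal per record. Records are
# 1 s long here, so the sampling rate must be a whole number and trailing
# part-seconds are dropped on write.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

# format a physical bound into <=8 ASCII chars and reparse it, so writer and
# reader agree exactly on the quantization grid
edf_number <- function(x) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4, width = 1)
  as.numeric(s)
}

#' Write a recording as EDF
#'
#' Physical min/max are chosen symmetric around zero to cover the signal, and
#' the digital range is the symmetric `[-32767, 32767]` so zero microvolts is
#' representable exactly. Identifiers and the true PMA are embedded in the
#' EDF recording-id field and recovered by [read_edf()].
#'
#' @param recording An [eeg_recording()]; `fs` must be a whole number and the
#'   signal at least one second long. Trailing samples beyond the last whole
#'   second are dropped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  if (nrow(sig) == 0 || length(recording$channel_labels) == 0)
    stop_input("recording has no channels")
  if (!all(is.finite(sig))) stop_input("signal contains non-finite samples")
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop_input("EDF export requires integer fs")
  fs <- as.integer(round(fs))
  n_rec <- ncol(sig) %/% fs
  if (n_rec < 1) stop_input("signal must be at least one second long")
  ns <- nrow(sig)
  nsamp <- n_rec * fs

  dmin <- -32767L; dmax <- 32767L
  pm <- apply(abs(sig[, seq_len(nsamp), drop = FALSE]), 1, max)
  pm <- vapply(pmax(pm, 1), function(v) max(edf_number(v * 1.0001), v), 0)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  rec_field <- sprintf("Startdate 01.01.11 rec=%s inf=%s pma=%.3f",
                       recording$recording_id, recording$infant_id,
                       recording$pma_weeks)
  wr("0", 8)
  wr(recording$infant_id, 80)
  wr(rec_field, 80)
  wr("01.01.11", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pm) wr(formatC(-v, format = "g", digits = 6, width = 1), 8)
  for (v in pm) wr(formatC(v, format = "g", digits = 6, width = 1), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (2 * pm)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      d <- round((sig[ch, cols] + pm[ch]) * scale[ch]) + dmin
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @param infant_id,recording_id,pma_weeks Optional overrides; by default
#'   these are parsed back from the header fields written by [write_edf()].
#' @return An [eeg_recording()] with the signal rescaled to microvolts.
#' @export
read_edf <- function(path, infant_id = NULL, recording_id = NULL,
                     pma_weeks = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  sz <- file.size(path)
  if (sz < 256) stop_format("not an EDF file: header truncated")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop_format("not an EDF file: bad version field")
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)                      # start date/time, unused
  rd(8)                             # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_format("not an EDF file: bad signal count")
  rds <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rds(16)
  rds(80)
  rds(8)                            # physical dimension
  pmin_ <- as.numeric(rds(8)); pmax_ <- as.numeric(rds(8))
  dmin_ <- as.numeric(rds(8)); dmax_ <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8))
  rds(32)
  if (length(unique(spr)) != 1)
    stop_format("unsupported layout: channels with unequal sampling rates")
  expected <- 256 * (ns + 1) + as.double(n_rec) * sum(spr) * 2
  if (sz < expected) stop_format("truncated EDF file: data records incomplete")
  fs <- spr[1] / rec_dur

  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      sig[ch, cols] <- pmin_[ch] +
        (d - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
    }
  }

  grab <- function(pat) {
    m <- regmatches(rec_field, regexec(pat, rec_field))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  eeg_recording(
    sig, fs, labels,
    infant_id = infant_id %||% (grab("inf=(\\S+)") %||% patient),
    recording_id = recording_id %||% grab("rec=(\\S+)"),
    pma_weeks = pma_weeks %||% as.numeric(grab("pma=(\\S+)")))
}

#' Export a cohort as EDF files plus a manifest
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`recording_id`, `infant_id`, `pma_weeks`,
#'   `path`), also written to `dir/manifest.tsv`.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::map_dfr(cohort, function(r) {
    p <- file.path(dir, paste0(r$recording_id, ".edf"))
    write_edf(r, p)
    tibble::tibble(recording_id = r$recording_id, infant_id = r$infant_id,
                   pma_weeks = r$pma_weeks, path = p)
  })
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
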