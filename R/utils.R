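# Internal helpers shared across modules.

# Deterministic 32-bit stream seed derived from a master seed and a string id,
# so every recording gets its own reproducible RNG stream.
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cc in utf8ToInt(as.character(id))) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Linear interpolation of a maturation parameter between the 25 and 38 wk
# anchor values.
lerp_pma <- function(at25, at38, pma) {
  at25 + (at38 - at25) * (pma - 25) / (38 - 25)
}

# Centered moving RMS with edge shrinkage (window clipped at the ends).
moving_rms <- function(x, fs, window_s = 0.5) {
  n <- length(x)
  w <- max(1L, round(window_s * fs))
  half <- w %/% 2L
  cs <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# Merge sorted/unsorted half-open [start, end) intervals, dropping empties.
merge_intervals <- function(start, end) {
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      j <- length(out_s)
      if (start[i] <= out_e[j]) {
        out_e[j] <- max(out_e[j], end[i])
      } else {
        out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
      }
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Intersect a set of merged intervals with a single window [lo, hi).
clip_intervals <- function(ints, lo, hi) {
  s <- pmax(ints$start, lo)
  e <- pmin(ints$end, hi)
  merge_intervals(s, e)
}

# Total length covered by merged intervals.
interval_total <- function(ints) sum(pmax(ints$end - ints$start, 0))

# Complement of merged intervals within [lo, hi).
complement_intervals <- function(ints, lo, hi) {
  ints <- clip_intervals(ints, lo, hi)
  if (nrow(ints) == 0L) return(tibble::tibble(start = lo, end = hi))
  s <- c(lo, ints$end)
  e <- c(ints$start, hi)
  merge_intervals(s, e)
}

# 1/f^gamma Gaussian noise with unit variance, built by spectral shaping.
# AC-coupled like an EEG amplifier: power below f_hp is removed, otherwise
# the infra-slow wander of steep 1/f spectra dominates the variance.
colored_noise <- function(n, fs, gamma, f_hp = 0.5) {
  white <- rnorm(n)
  if (gamma == 0) return(white)
  xf <- fft(white)
  freq <- c(0, seq_len(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)       # two-sided spectrum, symmetric in f
  scale <- 1 / pmax(freq, f_hp)^(gamma / 2)
  scale[freq < f_hp] <- 0
  x <- Re(fft(xf * scale, inverse = TRUE)) / n
  x / sd(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(msg) abort(msg, class = "neofba_input_error")
stop_domain <- function(msg) abort(msg, class = "neofba_domain_error")
stop_format <- function(msg) abort(msg, class = "neofba_format_error")
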