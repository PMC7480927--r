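# Independent oracles used to cross-check package computations. These are
# deliberately naive re-derivations from first principles and must stay
# independent of the package's own code paths.

# Sample entropy by direct O(N^2) template matching.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# ICC(2,1) via stats::aov mean squares (QR-based two-way ANOVA), an
# independent route to the variance components.
icc21_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  a <- anova(aov(y ~ target + rater, data = df))
  msr <- a["target", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Pitman-Morgan t via the variance-ratio formulation (algebraic identity
# with the sum/difference correlation form).
pitman_morgan_oracle <- function(a, b) {
  n <- length(a)
  (var(a) - var(b)) * sqrt(n - 2) /
    (2 * sd(a) * sd(b) * sqrt(1 - cor(a, b)^2))
}

# Kruskal-Wallis H with tie correction, straight from the rank definition.
kruskal_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  rk <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Temporal skewness of a normalised burst shape treated as a weight
# function over relative time in [0, 1].
shape_skew_oracle <- function(shape) {
  tt <- seq(0, 1, length.out = length(shape))
  w <- shape / sum(shape)
  mu <- sum(w * tt)
  s2 <- sum(w * (tt - mu)^2)
  sum(w * (tt - mu)^3) / s2^1.5
}

# Zero-phase gain of an IIR filter applied forward and backward, from the
# transfer-function polynomials evaluated on the unit circle.
filtfilt_gain_oracle <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  den <- sum(a * z)
  Mod(num / den)^2
}

# Correlated standard-normal pairs with correlation rho.
rnorm_pair <- function(n, rho) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}
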