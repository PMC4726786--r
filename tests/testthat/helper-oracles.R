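# Independent oracles, deliberately brute-force and separate from the
# implementation paths they check.

# Direct DFT band power: explicit double loop over bins and samples.
dft_band_power_oracle <- function(window, sampling_rate, low = 60, high = 100) {
  window <- as.matrix(window)
  n <- nrow(window)
  out <- numeric(ncol(window))
  for (ch in seq_len(ncol(window))) {
    x <- window[, ch]
    total <- 0
    for (k in 0:(n - 1)) {
      f <- k * sampling_rate / n
      if (f >= low && f <= high && f <= sampling_rate / 2) {
        re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
        im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
        total <- total + re^2 + im^2
      }
    }
    out[ch] <- total
  }
  out
}

# Two-tailed correlation p-value by numerical quadrature of the Student-t
# density (written from the closed-form density, not stats::dt/pt).
t_pvalue_quadrature <- function(r, n) {
  if (abs(r) >= 1) return(0)
  df <- n - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-12)$value
}

# Brute-force significant-pair mask: per-pair correlation from first
# principles plus the t transform, no vectorised shortcuts.
brute_force_mask <- function(x, alpha = 0.05, include_self = TRUE) {
  w <- nrow(x)
  n <- ncol(x)
  m <- matrix(FALSE, w, w)
  for (i in seq_len(w)) {
    for (j in seq_len(w)) {
      xi <- x[i, ]
      xj <- x[j, ]
      si <- sqrt(sum((xi - mean(xi))^2))
      sj <- sqrt(sum((xj - mean(xj))^2))
      if (si == 0 || sj == 0) next
      r <- sum((xi - mean(xi)) * (xj - mean(xj))) / (si * sj)
      r <- max(-1, min(1, r))
      p <- if (abs(r) == 1) 0 else {
        tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(tt, n - 2, lower.tail = FALSE)
      }
      m[i, j] <- r > 0 && p <= alpha
    }
  }
  if (!include_self) diag(m) <- FALSE
  m
}

# Hand Pearson correlation via the definition.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
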