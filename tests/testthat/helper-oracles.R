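# Independent oracles, written against the definitions rather than the
# package internals, for benchmarking the nonparametric estimator.

# Geweke spectral GC of a VAR, from the closed-form transfer function:
# H(f) = (I - sum_k A_k e^(-2 pi i f k / fs))^(-1), S ~ H Sigma H^*.
# Returns the GC spectrum source -> target at `freqs`.
oracle_var_gc_spectrum <- function(A, Sigma, source, target, freqs, fs) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1))
  R <- dim(A)[1]; p <- dim(A)[3]
  s2 <- Sigma[source, source] - Sigma[source, target]^2 / Sigma[target, target]
  vapply(freqs, function(f) {
    Af <- diag(R) + 0i
    for (l in seq_len(p)) Af <- Af - A[, , l] * exp(-2i * pi * f * l / fs)
    H <- solve(Af)
    Syy <- Re((H %*% Sigma %*% Conj(t(H)))[target, target])
    log(Syy / (Syy - s2 * Mod(H[target, source])^2))
  }, numeric(1))
}

oracle_var_band_gc <- function(A, Sigma, source, target, band, fs,
                               res = 0.0025) {
  freqs <- seq(band[1], band[2], by = res)
  mean(oracle_var_gc_spectrum(A, Sigma, source, target, freqs, fs))
}

# Time-domain Granger causality by explicit restricted/full VAR fits:
# ln(var(restricted residual) / var(full residual)).
oracle_time_domain_gc <- function(x, y, p) {
  n <- length(y)
  idx <- (p + 1):n
  lagmat <- function(v) sapply(seq_len(p), function(k) v[idx - k])
  full <- lm.fit(cbind(1, lagmat(y), lagmat(x)), y[idx])
  restr <- lm.fit(cbind(1, lagmat(y)), y[idx])
  log(mean(restr$residuals^2) / mean(full$residuals^2))
}

# Brute-force Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m))
  pmin(adj, 1)[order(o)]
}
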