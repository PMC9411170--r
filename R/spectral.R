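# Nonparametric spectral estimation: windowing, cross-spectral density
# (multitaper / Welch), and Wilson minimum-phase spectral matrix
# factorization. These are the ingredients of the Granger-causality module.

#' Spectral analysis options
#'
#' Bundles every tunable of the window-level Granger-causality estimator.
#' Defaults follow the analysis this pipeline implements: nonoverlapping
#' 54-s windows, GC read out in the 0.01-0.07 Hz neurovascular band.
#'
#' @param window_s Analysis window length in seconds (>= `min_window_s`).
#' @param min_window_s Smallest admissible window (stationarity floor), 50 s.
#' @param band Frequency band (Hz) for band-averaged GC.
#' @param method Cross-spectrum estimator: `"auto"` picks Welch averaging
#'   when the series holds at least `welch_min_segments` sub-segments and
#'   sine-multitaper otherwise (the single-window case).
#' @param n_tapers Number of sine tapers for the multitaper path.
#' @param seg_s Welch sub-segment length (seconds).
#' @param overlap Welch sub-segment overlap fraction.
#' @param welch_min_segments Minimum sub-segment count for `"auto"` to pick
#'   Welch.
#' @param pad_to_resolution_hz Zero-padded frequency-grid resolution (Hz).
#' @param analysis_rate_hz Internal decimation target (Hz). Signals entering
#'   GC are band-limited well below 1 Hz, so spectra are estimated on a
#'   decimated grid; the full acquisition-rate Nyquist range would be almost
#'   everywhere signal-free and would destabilize the factorization.
#' @param ridge Diagonal ridge added to the spectral matrix as
#'   `ridge * mean(trace)` before factorization.
#' @param tol Wilson iteration relative-change tolerance.
#' @param max_iter Maximum Wilson iterations.
#' @return Object of class `gc_options`.
#' @export
gc_options <- function(window_s = 54, min_window_s = 50,
                       band = c(0.01, 0.07),
                       method = c("auto", "multitaper", "welch"),
                       n_tapers = 6, seg_s = 32, overlap = 0.5,
                       welch_min_segments = 8,
                       pad_to_resolution_hz = 0.005,
                       analysis_rate_hz = 2.5,
                       ridge = 1e-6, tol = 1e-9, max_iter = 100) {
  method <- match.arg(method)
  if (window_s < min_window_s)
    stop(sprintf("window_s = %g below the minimum window of %g s", window_s, min_window_s))
  if (band[1] >= band[2]) stop("band reversed")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (window_s * analysis_rate_hz < 64)
    stop("window_s x analysis_rate_hz must be at least 64 samples")
  structure(list(window_s = window_s, min_window_s = min_window_s,
                 band = band, method = method, n_tapers = n_tapers,
                 seg_s = seg_s, overlap = overlap,
                 welch_min_segments = welch_min_segments,
                 pad_to_resolution_hz = pad_to_resolution_hz,
                 analysis_rate_hz = analysis_rate_hz,
                 ridge = ridge, tol = tol, max_iter = max_iter),
            class = "gc_options")
}

#' Cut a series into nonoverlapping analysis windows
#'
#' Contiguous, gapless windows of `window_s` seconds starting at the first
#' sample; a trailing remainder shorter than one window is discarded.
#'
#' @param roi_series A [roi_timeseries()] (or numeric matrix with attribute-free
#'   interpretation via `sampling_rate_hz`).
#' @param window_s Window length (seconds).
#' @param sampling_rate_hz Required only when `roi_series` is a bare matrix.
#' @return List of `roi_ts` windows, each with attribute `window_index`
#'   (0-based) and `start_s`.
#' @export
segment_windows <- function(roi_series, window_s = 54, sampling_rate_hz = NULL) {
  if (inherits(roi_series, "roi_ts")) {
    x <- roi_series$values; fs <- roi_series$sampling_rate_hz
    labs <- roi_series$roi_labels
  } else {
    if (is.null(sampling_rate_hz)) stop("sampling_rate_hz required for bare matrices")
    x <- as.matrix(roi_series); fs <- sampling_rate_hz; labs <- colnames(x)
  }
  wlen <- round(window_s * fs)
  nwin <- floor(nrow(x) / wlen)
  if (nwin < 1)
    stop(sprintf("series (%.1f s) shorter than one %g-s window",
                 nrow(x) / fs, window_s))
  lapply(seq_len(nwin) - 1L, function(w) {
    win <- roi_timeseries(x[(w * wlen + 1):((w + 1) * wlen), , drop = FALSE],
                          fs, labs)
    attr(win, "window_index") <- w
    attr(win, "start_s") <- w * wlen / fs
    win
  })
}

# internal: decimate a matrix to ~target rate by subsampling; input is
# assumed band-limited (by construction or by the preprocessing bandpass),
# so no additional anti-alias filter is applied. Returns list(x, fs).
decimate_matrix <- function(x, fs, target_hz) {
  if (is.null(target_hz) || fs <= target_hz) return(list(x = x, fs = fs))
  k <- max(1L, round(fs / target_hz))
  list(x = x[seq(1, nrow(x), by = k), , drop = FALSE], fs = fs / k)
}

# internal: sine taper matrix (n x K), orthonormal columns
sine_tapers <- function(n, K) {
  tt <- seq_len(n)
  vapply(seq_len(K), function(k) sqrt(2 / (n + 1)) * sin(pi * k * tt / (n + 1)),
         numeric(n))
}

#' Estimate the cross-spectral density matrix of one window
#'
#' Short-time Fourier estimation of the `R x R` cross-spectrum. Two paths:
#' sine-multitaper on the whole window (default for a single short window,
#' where sub-segmenting would destroy the slow neurovascular band), or Welch
#' averaging of Hann-tapered, overlapping sub-segments (long series). The
#' window is linearly detrended as a whole, decimated to the analysis rate,
#' tapered, zero-padded to the requested frequency resolution, and averaged
#' over tapers/segments. One-sided scaling: the integral of the diagonal
#' over the frequency grid approximates each channel's variance (Parseval).
#'
#' @param window A `roi_ts` window or numeric matrix (samples x channels).
#' @param sampling_rate_hz Required for bare matrices.
#' @param opts A [gc_options()].
#' @return Object of class `cross_spectrum`: `freqs` (Hz), `S` (complex
#'   `R x R x Nf`, Hermitian per frequency), `n_segments` (tapers or
#'   sub-segments averaged), `fs` (analysis rate), `method`.
#' @export
estimate_cross_spectrum <- function(window, sampling_rate_hz = NULL,
                                    opts = gc_options()) {
  if (inherits(window, "roi_ts")) {
    x <- window$values; fs <- window$sampling_rate_hz; labs <- window$roi_labels
  } else {
    if (is.null(sampling_rate_hz)) stop("sampling_rate_hz required for bare matrices")
    x <- as.matrix(window); fs <- sampling_rate_hz; labs <- colnames(x)
  }
  dec <- decimate_matrix(x, fs, opts$analysis_rate_hz)
  x <- dec$x; fd <- dec$fs
  n <- nrow(x); R <- ncol(x)
  if (n < 64) stop("window holds fewer than 64 samples at the analysis rate")
  if (opts$pad_to_resolution_hz > (opts$band[2] - opts$band[1]) / 2)
    stop(sprintf("pad resolution %g Hz too coarse for the %g-%g Hz band (need >= 3 bins)",
                 opts$pad_to_resolution_hz, opts$band[1], opts$band[2]))
  # full-window linear detrend
  tt <- seq_len(n)
  x <- qr.resid(qr(cbind(1, tt)), x)

  seg_len <- min(n, round(opts$seg_s * fd))
  step <- max(1L, round(seg_len * (1 - opts$overlap)))
  n_sub <- length(seq(1L, n - seg_len + 1L, by = step))
  method <- opts$method
  if (method == "auto")
    method <- if (n_sub >= opts$welch_min_segments) "welch" else "multitaper"

  nfft <- ceiling(fd / opts$pad_to_resolution_hz)
  base_len <- if (method == "welch") seg_len else n
  nfft <- max(nfft, base_len)
  if (nfft %% 2 == 1) nfft <- nfft + 1
  Nf <- nfft / 2 + 1
  S <- array(0 + 0i, dim = c(R, R, Nf))

  accumulate <- function(seg_tapered) {
    X <- mvfft(rbind(seg_tapered, matrix(0, nfft - nrow(seg_tapered), R)))
    X <- X[seq_len(Nf), , drop = FALSE]
    for (i in seq_len(R)) for (j in seq_len(R))
      S[i, j, ] <<- S[i, j, ] + X[, i] * Conj(X[, j])
  }

  if (method == "multitaper") {
    W <- sine_tapers(n, opts$n_tapers)
    for (k in seq_len(opts$n_tapers)) accumulate(x * W[, k])
    S <- S / (opts$n_tapers * fd)     # sum(w^2) = 1 per sine taper
    n_avg <- opts$n_tapers
  } else {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))  # Hann
    U <- sum(w^2)
    starts <- seq(1L, n - seg_len + 1L, by = step)
    for (s in starts) accumulate(x[s:(s + seg_len - 1L), , drop = FALSE] * w)
    S <- S / (length(starts) * U * fd)
    n_avg <- length(starts)
  }
  S[, , 2:(Nf - 1)] <- 2 * S[, , 2:(Nf - 1)]   # one-sided doubling
  structure(list(freqs = (seq_len(Nf) - 1) * fd / nfft, S = S,
                 n_segments = n_avg, fs = fd, method = method,
                 labels = labs),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d x %d, %d frequencies (0-%.3g Hz), %s over %d segments\n",
              dim(x$S)[1], dim(x$S)[2], length(x$freqs), max(x$freqs),
              if (is.null(x$method)) "analytic" else x$method, x$n_segments))
  invisible(x)
}

#' Wilson minimum-phase spectral matrix factorization
#'
#' Factorizes a cross-spectral density `S(f) = H(f) Sigma H(f)^*` with
#' minimum-phase transfer matrices `H` normalized to the identity at lag
#' zero and a real positive-definite innovation covariance `Sigma`, using
#' Wilson's Newton-type iteration. This yields the transfer/noise split that
#' frequency-domain Granger causality needs, without fitting an explicit
#' autoregressive model.
#'
#' @param cs A `cross_spectrum` (one-sided, uniform grid from 0 to Nyquist).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum iterations; on non-convergence the result is
#'   returned with `converged = FALSE` and the caller decides policy.
#' @param ridge Diagonal regularization, `ridge * mean(trace(S))`, applied
#'   before iterating.
#' @return Object of class `wilson_fact`: `H` (`R x R x Nf`), `Sigma` (the
#'   innovation covariance in signal units; `H (Sigma/fs) H^*` reproduces
#'   the PSD-scaled input), `converged`, `iterations`, `residual` (last
#'   relative change), `reconstruction` (max elementwise
#'   `|S - H (Sigma/fs) H^*|` against the two-sided input).
#' @export
wilson_factorize <- function(cs, tol = 1e-9, max_iter = 100, ridge = 1e-6) {
  stopifnot(inherits(cs, "cross_spectrum"))
  S <- cs$S
  R <- dim(S)[1]; Nf <- dim(S)[3]
  nfft <- 2L * (Nf - 1L)
  # per-channel ridge (proportional to each channel's own mean power), so
  # regularization commutes with channel-wise rescaling and band GC stays
  # scale-free
  for (i in seq_len(R)) S[i, i, ] <- S[i, i, ] + ridge * mean(Re(S[i, i, ]))
  # two-sided values on the full frequency circle
  half <- S
  half[, , 2:(Nf - 1)] <- half[, , 2:(Nf - 1)] / 2
  if (R == 2L) {
    res <- wilson_iterate_2x2(half, Nf, nfft, tol, max_iter)
  } else {
    res <- wilson_iterate_gen(half, R, Nf, nfft, tol, max_iter)
  }
  # the factor of a PSD-scaled spectrum carries 1/fs; rescale so Sigma is
  # the innovation covariance in signal units (uM^2)
  fs <- cs$fs %||% 1
  res$Sigma <- res$Sigma * fs
  # reconstruction residual against the (ridge-regularized) two-sided input
  rec <- max(abs(reconstruct_spectrum(res$H, res$Sigma / fs) - half))
  structure(list(H = res$H, Sigma = res$Sigma, converged = res$converged,
                 iterations = res$iterations, residual = res$residual,
                 reconstruction = rec, freqs = cs$freqs, fs = cs$fs),
            class = "wilson_fact")
}

#' @export
print.wilson_fact <- function(x, ...) {
  cat(sprintf("<wilson_fact> %d x %d, %s in %d iterations (residual %.2e, reconstruction %.2e)\n",
              dim(x$H)[1], dim(x$H)[2],
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual, x$reconstruction))
  invisible(x)
}

# H Sigma H^* per frequency, vectorized over the grid.
reconstruct_spectrum <- function(H, Sigma) {
  R <- dim(H)[1]; Nf <- dim(H)[3]
  out <- array(0i, dim = c(R, R, Nf))
  for (i in seq_len(R)) for (j in seq_len(R)) {
    acc <- complex(Nf)
    for (a in seq_len(R)) for (b in seq_len(R))
      acc <- acc + H[i, a, ] * Sigma[a, b] * Conj(H[j, b, ])
    out[i, j, ] <- acc
  }
  out
}

# The "plus operator": retain the causal part of a lag expansion.
# On an even-length circle both the zero lag and the shared +/-Nyquist lag
# must be halved, otherwise the iteration stalls above tolerance.
plus_op_vec <- function(v, Nf, nfft) {
  gam <- fft(v, inverse = TRUE) / nfft
  gam[1] <- 0.5 * gam[1]
  gam[Nf] <- 0.5 * gam[Nf]
  gam[(Nf + 1):nfft] <- 0i
  fft(gam)
}

# Fully vectorized bivariate Wilson iteration (the pairwise-GC workhorse).
# `half`: two-sided-scale one-sided array (2 x 2 x Nf).
wilson_iterate_2x2 <- function(half, Nf, nfft, tol, max_iter) {
  mirror <- function(v) c(v, Conj(v[(Nf - 1):2]))
  s11 <- Re(mirror(half[1, 1, ])); s22 <- Re(mirror(half[2, 2, ]))
  s12 <- mirror(half[1, 2, ]); s21 <- Conj(s12)
  g0 <- matrix(c(mean(s11), Re(mean(s21)), Re(mean(s12)), mean(s22)), 2)
  L <- t(chol((g0 + t(g0)) / 2))
  p11 <- rep(L[1, 1] + 0i, nfft); p12 <- rep(0i, nfft)
  p21 <- rep(L[2, 1] + 0i, nfft); p22 <- rep(L[2, 2] + 0i, nfft)
  converged <- FALSE; resid <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    det <- p11 * p22 - p12 * p21
    i11 <- p22 / det; i12 <- -p12 / det; i21 <- -p21 / det; i22 <- p11 / det
    t11 <- i11 * s11 + i12 * s21; t12 <- i11 * s12 + i12 * s22
    t21 <- i21 * s11 + i22 * s21; t22 <- i21 * s12 + i22 * s22
    g11 <- t11 * Conj(i11) + t12 * Conj(i12) + 1
    g12 <- t11 * Conj(i21) + t12 * Conj(i22)
    g21 <- t21 * Conj(i11) + t22 * Conj(i12)
    g22 <- t21 * Conj(i21) + t22 * Conj(i22) + 1
    q11 <- plus_op_vec(g11, Nf, nfft); q12 <- plus_op_vec(g12, Nf, nfft)
    q21 <- plus_op_vec(g21, Nf, nfft); q22 <- plus_op_vec(g22, Nf, nfft)
    n11 <- p11 * q11 + p12 * q21; n12 <- p11 * q12 + p12 * q22
    n21 <- p21 * q11 + p22 * q21; n22 <- p21 * q12 + p22 * q22
    resid <- max(abs(c(n11 - p11, n12 - p12, n21 - p21, n22 - p22))) /
      max(abs(c(p11, p12, p21, p22)))
    p11 <- n11; p12 <- n12; p21 <- n21; p22 <- n22
    if (resid < tol) { converged <- TRUE; break }
  }
  A0 <- matrix(c(Re(mean(p11)), Re(mean(p21)), Re(mean(p12)), Re(mean(p22))), 2)
  Sigma <- A0 %*% t(A0)
  A0i <- solve(A0)
  H <- array(0i, dim = c(2, 2, Nf))
  H[1, 1, ] <- p11[1:Nf] * A0i[1, 1] + p12[1:Nf] * A0i[2, 1]
  H[1, 2, ] <- p11[1:Nf] * A0i[1, 2] + p12[1:Nf] * A0i[2, 2]
  H[2, 1, ] <- p21[1:Nf] * A0i[1, 1] + p22[1:Nf] * A0i[2, 1]
  H[2, 2, ] <- p21[1:Nf] * A0i[1, 2] + p22[1:Nf] * A0i[2, 2]
  list(H = H, Sigma = Sigma, converged = converged, iterations = it,
       residual = resid)
}

# General R-channel Wilson iteration (loop over frequencies).
wilson_iterate_gen <- function(half, R, Nf, nfft, tol, max_iter) {
  Sfull <- array(0i, dim = c(R, R, nfft))
  Sfull[, , 1:Nf] <- half
  for (k in 2:(Nf - 1)) Sfull[, , nfft - k + 2] <- Conj(half[, , k])
  ffts <- function(A, inverse = FALSE) {
    M <- matrix(A, nrow = R * R, ncol = nfft)
    out <- t(mvfft(t(M), inverse = inverse))
    if (inverse) out <- out / nfft
    array(out, dim = c(R, R, nfft))
  }
  gam0 <- Re(ffts(Sfull, inverse = TRUE)[, , 1])
  L <- t(chol((gam0 + t(gam0)) / 2))
  psi <- array(0i, dim = c(R, R, nfft))
  for (k in seq_len(nfft)) psi[, , k] <- L
  I_R <- diag(R)
  plus_op <- function(g) {
    gam <- ffts(g, inverse = TRUE)
    gam[, , 1] <- 0.5 * gam[, , 1]
    gam[, , Nf] <- 0.5 * gam[, , Nf]
    gam[, , (Nf + 1):nfft] <- 0i
    ffts(gam)
  }
  converged <- FALSE; resid <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    g <- array(0i, dim = c(R, R, nfft))
    for (k in seq_len(nfft)) {
      ip <- solve(psi[, , k])
      g[, , k] <- ip %*% Sfull[, , k] %*% Conj(t(ip)) + I_R
    }
    gp <- plus_op(g)
    psi_new <- array(0i, dim = c(R, R, nfft))
    for (k in seq_len(nfft)) psi_new[, , k] <- psi[, , k] %*% gp[, , k]
    resid <- max(abs(psi_new - psi)) / max(abs(psi))
    psi <- psi_new
    if (resid < tol) { converged <- TRUE; break }
  }
  A0 <- Re(ffts(psi, inverse = TRUE)[, , 1])
  Sigma <- A0 %*% t(A0)
  A0i <- solve(A0)
  H <- array(0i, dim = c(R, R, Nf))
  for (k in seq_len(Nf)) H[, , k] <- psi[, , k] %*% A0i
  list(H = H, Sigma = Sigma, converged = converged, iterations = it,
       residual = resid)
}
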