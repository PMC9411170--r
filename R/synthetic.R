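# Synthetic-data generator: ground-truth-known inputs at every level of the
# pipeline (ROI series, raw intensities, behavior scores, full factorial
# study), so downstream stages can be tested by parameter recovery.

#' Ground-truth coupled network
#'
#' Defines the generative model for one experimental cell: a stationary
#' vector autoregression (VAR) acting on a slow "coupling grid", whose
#' directed lag couplings are the ground truth the spectral Granger-causality
#' estimator is supposed to recover. The coupling grid rate (default 2 Hz)
#' together with strong AR self-coefficients concentrates the spectral power
#' of the simulated hemodynamics in the low-frequency neurovascular band.
#'
#' @param coupling `R x R x p` array of VAR lag coefficients;
#'   `coupling[i, j, k]` is the weight of region `j` at lag `k` on region `i`
#'   (dimensionless AR weights).
#' @param noise_cov `R x R` innovation covariance (uM^2); must be symmetric
#'   positive definite.
#' @param rois Ordered region labels.
#' @param coupling_rate_hz Rate (Hz) of the grid the VAR coefficients act on.
#' @param band Frequency interval (Hz) in which the couplings are meant to be
#'   read out; metadata used by truth computations.
#' @return Object of class `gt_network`.
#' @export
ground_truth_network <- function(coupling, noise_cov,
                                 rois = ROI_LABELS,
                                 coupling_rate_hz = 2,
                                 band = c(0.01, 0.07)) {
  if (is.matrix(coupling)) coupling <- array(coupling, dim = c(dim(coupling), 1L))
  R <- dim(coupling)[1]
  stopifnot(dim(coupling)[2] == R, length(rois) == R,
            nrow(noise_cov) == R, ncol(noise_cov) == R)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-12)
    stop("noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise_cov must be positive definite")
  rho <- var_spectral_radius(coupling)
  if (rho >= 1)
    stop(sprintf("non-stationary VAR: companion spectral radius %.4f >= 1", rho))
  structure(list(coupling = coupling, noise_cov = noise_cov, rois = rois,
                 coupling_rate_hz = coupling_rate_hz, band = band,
                 spectral_radius = rho),
            class = "gt_network")
}

#' @export
print.gt_network <- function(x, ...) {
  p <- dim(x$coupling)[3]
  cat(sprintf("<gt_network> %d regions, VAR(%d) on %g Hz grid, spectral radius %.3f\n",
              length(x$rois), p, x$coupling_rate_hz, x$spectral_radius))
  invisible(x)
}

#' Spectral radius of a VAR companion matrix
#'
#' @param coupling `R x R x p` lag-coefficient array.
#' @return Largest eigenvalue modulus of the companion matrix; the VAR is
#'   stationary iff this is `< 1`.
#' @export
var_spectral_radius <- function(coupling) {
  if (is.matrix(coupling)) coupling <- array(coupling, dim = c(dim(coupling), 1L))
  R <- dim(coupling)[1]; p <- dim(coupling)[3]
  comp <- matrix(0, R * p, R * p)
  for (k in seq_len(p)) comp[1:R, ((k - 1) * R + 1):(k * R)] <- coupling[, , k]
  if (p > 1) comp[(R + 1):(R * p), 1:(R * (p - 1))] <- diag(R * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate ROI hemodynamics from a ground-truth network
#'
#' Draws the VAR on its coupling grid (after discarding a burn-in), then
#' linearly interpolates to the output sampling rate and adds white
#' measurement noise. Because the VAR acts on a slow grid with strong
#' self-coefficients, the simulated series emulates bandpassed oxyhemoglobin:
#' power is concentrated below ~0.1 Hz.
#'
#' @param net A [ground_truth_network()].
#' @param n_samples Number of output samples (> 100 * VAR order).
#' @param sampling_rate_hz Output rate; must be >= the coupling grid rate.
#' @param seed Integer seed; identical seeds give identical series.
#' @param measurement_noise_sd White noise sd (uM) added at the output rate.
#'   Default 0.01.
#' @param burn_in Slow-grid samples discarded before output (>= 500).
#' @return A [roi_timeseries()] of dimension `n_samples x R`.
#' @export
simulate_var_network <- function(net, n_samples, sampling_rate_hz = 25,
                                 seed, measurement_noise_sd = 0.01,
                                 burn_in = 500) {
  stopifnot(inherits(net, "gt_network"))
  p <- dim(net$coupling)[3]
  if (n_samples <= 100 * p)
    stop("n_samples must exceed 100 * VAR order")
  if (burn_in < 500) stop("burn_in must be >= 500 slow samples")
  if (sampling_rate_hz < net$coupling_rate_hz)
    stop("sampling_rate_hz below the coupling grid rate")
  R <- length(net$rois)
  duration_s <- n_samples / sampling_rate_hz
  n_slow <- ceiling(duration_s * net$coupling_rate_hz) + p + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  L <- chol(net$noise_cov)
  e <- matrix(rnorm((n_slow + burn_in) * R), ncol = R) %*% L
  xs <- matrix(0, n_slow + burn_in, R)
  for (t in (p + 1):nrow(xs)) {
    acc <- e[t, ]
    for (k in seq_len(p)) acc <- acc + net$coupling[, , k] %*% xs[t - k, ]
    xs[t, ] <- acc
  }
  xs <- xs[-seq_len(burn_in), , drop = FALSE]
  if (sampling_rate_hz == net$coupling_rate_hz) {
    xf <- xs[seq_len(n_samples), , drop = FALSE]
  } else {
    t_slow <- (seq_len(nrow(xs)) - 1) / net$coupling_rate_hz
    t_fast <- (seq_len(n_samples) - 1) / sampling_rate_hz
    xf <- vapply(seq_len(R),
                 function(j) approx(t_slow, xs[, j], xout = t_fast)$y,
                 numeric(n_samples))
  }
  if (measurement_noise_sd > 0)
    xf <- xf + matrix(rnorm(length(xf), sd = measurement_noise_sd), nrow = n_samples)
  roi_timeseries(xf, sampling_rate_hz, net$rois)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Analytic spectral density of a ground-truth VAR
#'
#' Evaluates the population cross-spectral matrix
#' `S(f) = H(f) Sigma H(f)^* / fs` of the VAR on its coupling grid, with
#' `H(f) = (I - sum_k A_k e^(-2 pi i f k / fs))^(-1)`.
#'
#' @param net A [ground_truth_network()].
#' @param freqs Frequencies (Hz), each below the coupling-grid Nyquist.
#' @return List with `freqs`, `S` (`R x R x length(freqs)` complex array) and
#'   `H` (transfer matrices).
#' @export
var_spectral_density <- function(net, freqs) {
  fs <- net$coupling_rate_hz
  if (any(freqs > fs / 2 + 1e-12))
    stop("frequencies above the coupling-grid Nyquist")
  A <- net$coupling; Sigma <- net$noise_cov
  R <- dim(A)[1]; p <- dim(A)[3]; Nf <- length(freqs)
  S <- array(0 + 0i, dim = c(R, R, Nf)); H <- S
  for (k in seq_len(Nf)) {
    Af <- diag(R) + 0i
    for (l in seq_len(p)) Af <- Af - A[, , l] * exp(-2i * pi * freqs[k] * l / fs)
    Hk <- solve(Af)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sigma %*% Conj(t(Hk)) / fs
  }
  list(freqs = freqs, S = S, H = H)
}

#' Population band-averaged Granger causality of a ground-truth network
#'
#' The "oracle" the estimator is benchmarked against. For a bivariate network
#' the Geweke spectrum follows in closed form from the VAR transfer function
#' and innovation covariance. For more regions, pairwise GC refers to the
#' bivariate marginal of the process, whose spectral factors are obtained by
#' Wilson factorization of the analytic 2 x 2 sub-spectrum (the population
#' quantity, evaluated without any data).
#'
#' @param net A [ground_truth_network()].
#' @param band Frequency band (Hz); defaults to the network's band.
#' @param resolution_hz Frequency grid step used for the band average.
#' @return `R x R` matrix of band-averaged GC (nats), `[i, j]` = flow from
#'   region `j` to region `i`; diagonal `NA`.
#' @export
population_band_gc <- function(net, band = net$band, resolution_hz = 0.0025) {
  fs <- net$coupling_rate_hz
  nfft <- 2 * ceiling(fs / (2 * resolution_hz))
  freqs <- (0:(nfft / 2)) * fs / nfft
  sp <- var_spectral_density(net, freqs)
  R <- length(net$rois)
  inb <- which(freqs >= band[1] & freqs <= band[2])
  if (length(inb) < 3) stop("fewer than 3 grid frequencies inside band")
  out <- matrix(NA_real_, R, R,
                dimnames = list(target = net$rois, source = net$rois))
  if (R == 2) {
    gcs <- geweke_from_parts(sp$S, sp$H, net$noise_cov)
    out[2, 1] <- mean(gcs$fwd[inb]); out[1, 2] <- mean(gcs$rev[inb])
    return(out)
  }
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    S2 <- sp$S[c(i, j), c(i, j), , drop = FALSE]
    # one-sided scaling for the factorization routine
    S1 <- S2; S1[, , 2:(length(freqs) - 1)] <- 2 * S1[, , 2:(length(freqs) - 1)]
    cs <- structure(list(freqs = freqs, S = S1, n_segments = NA_integer_,
                         fs = fs), class = "cross_spectrum")
    fact <- wilson_factorize(cs, tol = 1e-10, max_iter = 200)
    g_ij <- geweke_gc_spectrum(cs, fact, source = 2, target = 1)  # j -> i
    g_ji <- geweke_gc_spectrum(cs, fact, source = 1, target = 2)  # i -> j
    out[i, j] <- mean(g_ij$value[inb])
    out[j, i] <- mean(g_ji$value[inb])
  }
  out
}

# Closed-form bivariate Geweke spectra from analytic H and Sigma. The PSD
# scaling (1/fs) cancels in the Geweke ratio, so it is computed scale-free
# from fs * S_yy = (H Sigma H^*)_yy.
geweke_from_parts <- function(S, H, Sigma) {
  Nf <- dim(S)[3]
  gc_dir <- function(src, tgt) {
    s2 <- Sigma[src, src] - Sigma[src, tgt]^2 / Sigma[tgt, tgt]
    vapply(seq_len(Nf), function(k) {
      Hk <- H[, , k]
      Syy <- Re((Hk %*% Sigma %*% Conj(t(Hk)))[tgt, tgt])
      log(Syy / (Syy - s2 * Mod(Hk[tgt, src])^2))
    }, numeric(1))
  }
  list(fwd = gc_dir(1, 2), rev = gc_dir(2, 1))
}

#' Canonical bivariate demonstration network
#'
#' The two-region network used throughout the documentation and validation
#' runs: AR self-couplings on both regions and a single directed lag-1
#' coupling of strength `coupling` from the first region to the second
#' (zero for a null network), on the default 2 Hz coupling grid.
#'
#' @param coupling Directed coupling strength (default 0.5).
#' @param self AR self-coupling (default 0.9).
#' @param innovation_sd Innovation sd in uM (default 0.05).
#' @param labels Region labels.
#' @return A [ground_truth_network()].
#' @export
default_pair_truth <- function(coupling = 0.5, self = 0.9,
                               innovation_sd = 0.05,
                               labels = c("X", "Y")) {
  A <- array(0, dim = c(2, 2, 1))
  A[1, 1, 1] <- self; A[2, 2, 1] <- self
  A[2, 1, 1] <- coupling
  ground_truth_network(A, diag(innovation_sd^2, 2), labels,
                       coupling_rate_hz = 2)
}

#' Simulate behavior scores from edge-level ground truth
#'
#' Scores are a linear read-out of selected ground-truth edge strengths plus
#' Gaussian noise: `score = intercept + sum_e weight_e * edge_e + N(0, sd)`.
#'
#' @param edge_truth Numeric matrix (trials x edges) of ground-truth
#'   band-averaged GC per edge, columns named with canonical edge names (see
#'   [roi_pairs()]).
#' @param weights Named numeric vector of weights on a subset of the columns.
#' @param intercept Scalar intercept (score units).
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of scores, one per row of `edge_truth`, with the
#'   noiseless linear predictor attached as attribute `"truth"`.
#' @export
simulate_behavior_scores <- function(edge_truth, weights, intercept = 0,
                                     noise_sd = 0, seed = 1) {
  edge_truth <- as.matrix(edge_truth)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  unknown <- setdiff(names(weights), colnames(edge_truth))
  if (length(unknown))
    stop("weights refer to unknown edges: ", paste(unknown, collapse = ", "))
  lin <- intercept + as.vector(edge_truth[, names(weights), drop = FALSE] %*% weights)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  scores <- lin + rnorm(length(lin), sd = noise_sd)
  attr(scores, "truth") <- lin
  scores
}
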