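# Shared fixtures, built in code.

# canonical unidirectional pair used across GC tests (X drives Y)
pair_net <- function(coupling = 0.5) default_pair_truth(coupling)

# a tiny study design that keeps test runtimes low
tiny_design <- function(...) {
  study_design(n_subjects = c(expert = 2, novice = 2), n_trials = 2,
               trial_duration_s = 54, ...)
}

# analytic cross_spectrum object of a VAR ground-truth network, on a
# uniform one-sided grid (what wilson_factorize() consumes)
analytic_cs <- function(net, nfft = 256) {
  fs <- net$coupling_rate_hz
  freqs <- (0:(nfft / 2)) * fs / nfft
  sp <- var_spectral_density(net, freqs)
  S <- sp$S
  Nf <- length(freqs)
  S[, , 2:(Nf - 1)] <- 2 * S[, , 2:(Nf - 1)]
  structure(list(freqs = freqs, S = S, n_segments = NA_integer_, fs = fs,
                 labels = net$rois),
            class = "cross_spectrum")
}
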