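test_that("window segmentation is contiguous, gapless, remainder-dropping", {
  rs <- roi_timeseries(matrix(seq_len(300 * 10 * 2), ncol = 2), 10)
  wins <- segment_windows(rs, 54)
  expect_length(wins, 5)           # 300 s / 54 s -> 5, remainder 30 s
  starts <- vapply(wins, attr, numeric(1), "start_s")
  expect_equal(starts, (0:4) * 54)
  idx <- unlist(lapply(wins, function(w) w$values[, 1]))
  expect_equal(idx, seq_len(5 * 540))   # no gaps, no overlap
  one <- segment_windows(roi_timeseries(matrix(0, 540, 1), 10), 54)
  expect_length(one, 1)
  expect_error(segment_windows(roi_timeseries(matrix(0, 400, 1), 10), 54),
               "shorter")
})

test_that("gc_options enforces its invariants", {
  expect_error(gc_options(window_s = 40), "minimum")
  expect_error(gc_options(band = c(0.07, 0.01)), "reversed")
  expect_error(gc_options(window_s = 54, analysis_rate_hz = 1), "64")
  coarse <- gc_options(pad_to_resolution_hz = 0.05)
  expect_error(estimate_cross_spectrum(matrix(rnorm(200), ncol = 2), 2, coarse),
               "too coarse")
})

test_that("cross-spectrum satisfies Parseval and Hermitian symmetry", {
  set.seed(3)
  x <- matrix(rnorm(4096), ncol = 1)
  opts <- gc_options(window_s = 4096, analysis_rate_hz = 1, seg_s = 256,
                     method = "welch")
  cs <- estimate_cross_spectrum(x, 1, opts)
  df <- diff(cs$freqs[1:2])
  expect_equal(sum(Re(cs$S[1, 1, ])) * df, as.numeric(var(x)), tolerance = 0.1)
  # Hermitian with two channels
  y <- matrix(rnorm(4096 * 2), ncol = 2)
  cs2 <- estimate_cross_spectrum(y, 1, opts)
  expect_equal(cs2$S[1, 2, ], Conj(cs2$S[2, 1, ]))
  expect_true(all(Re(cs2$S[1, 1, ]) >= 0))
})

test_that("a pure sinusoid concentrates at the nearest grid frequency", {
  fs <- 2
  tt <- seq_len(fs * 256) / fs
  x <- matrix(sin(2 * pi * 0.05 * tt), ncol = 1)
  opts <- gc_options(window_s = 256, analysis_rate_hz = fs,
                     method = "multitaper", n_tapers = 4)
  cs <- estimate_cross_spectrum(x, fs, opts)
  peak <- cs$freqs[which.max(Re(cs$S[1, 1, ]))]
  expect_lt(abs(peak - 0.05), 0.01)
})

test_that("identical channels are perfectly coherent", {
  set.seed(4)
  v <- rnorm(512)
  x <- cbind(v, v)
  opts <- gc_options(window_s = 512, analysis_rate_hz = 1, seg_s = 128,
                     method = "welch", ridge = 0)
  cs <- estimate_cross_spectrum(x, 1, opts)
  coh <- Mod(cs$S[1, 2, ])^2 / (Re(cs$S[1, 1, ]) * Re(cs$S[2, 2, ]))
  expect_equal(coh, rep(1, length(coh)), tolerance = 1e-6)
})

test_that("Wilson factorization: flat identity spectrum gives H = I, Sigma ~ I", {
  Nf <- 65
  S <- array(0i, dim = c(2, 2, Nf))
  S[1, 1, ] <- 2; S[2, 2, ] <- 2     # one-sided white spectrum, fs = 1
  S[, , c(1, Nf)] <- S[, , c(1, Nf)] / 2   # endpoints are not doubled
  cs <- structure(list(freqs = seq(0, 0.5, length.out = Nf), S = S,
                       n_segments = 1, fs = 1, labels = c("a", "b")),
                  class = "cross_spectrum")
  f <- wilson_factorize(cs, ridge = 0)
  expect_true(f$converged)
  expect_lt(max(abs(f$H - array(rep(c(1, 0, 0, 1), Nf) + 0i,
                                dim = c(2, 2, Nf))[c(1, 2), c(1, 2), ])), 1e-8)
  expect_equal(f$Sigma, diag(2), tolerance = 1e-8)
})

test_that("Wilson reconstructs an analytic VAR spectrum to 1e-6", {
  net <- pair_net(0.5)
  cs <- analytic_cs(net, nfft = 256)
  f <- wilson_factorize(cs, tol = 1e-10, max_iter = 200, ridge = 0)
  expect_true(f$converged)
  expect_lt(f$reconstruction, 1e-6)
  expect_equal(f$Sigma, net$noise_cov, tolerance = 1e-6)
})

test_that("diagonal spectra factor into diagonal transfer functions", {
  A <- array(0, dim = c(2, 2, 1)); diag(A[, , 1]) <- c(0.7, 0.4)
  net <- ground_truth_network(A, diag(2), c("a", "b"), coupling_rate_hz = 1)
  cs <- analytic_cs(net, nfft = 128)
  f <- wilson_factorize(cs, tol = 1e-12, max_iter = 300, ridge = 0)
  expect_lt(max(Mod(f$H[1, 2, ])), 1e-8)
  expect_lt(max(Mod(f$H[2, 1, ])), 1e-8)
})

test_that("non-convergence is reported honestly", {
  net <- pair_net(0.5)
  cs <- analytic_cs(net, nfft = 256)
  f <- wilson_factorize(cs, tol = 1e-14, max_iter = 2)
  expect_false(f$converged)
  expect_gt(f$residual, 1e-14)
})
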