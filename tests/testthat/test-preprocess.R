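mk_raw_const <- function(value = 100, n = 300, fs = 10) {
  ci <- channel_info(c("L1", "S1"), c(32, 8), c("LPFC", NA))
  I <- matrix(value, n, 4,
              dimnames = list(NULL, c("L1_690", "L1_830", "S1_690", "S1_830")))
  raw_recording(I, ci, fs)
}

test_that("optical density has closed-form behavior", {
  raw <- mk_raw_const()
  od <- intensity_to_od(raw, c(0, 10))
  expect_true(all(abs(od) < 1e-12))           # constant intensity -> 0
  # one-sample dip to I/e gives dOD = 1 there
  raw2 <- mk_raw_const()
  raw2$intensity[200, "L1_690"] <- 100 * exp(-1)
  od2 <- intensity_to_od(raw2, c(0, 10))
  expect_equal(unname(od2[200, "L1_690"]), 1, tolerance = 1e-9)
  raw3 <- mk_raw_const()
  raw3$intensity[5, "S1_830"] <- -1
  expect_error(intensity_to_od(raw3), "S1_830")
  expect_error(intensity_to_od(raw, c(200, 100)), "baseline")
})

test_that("Savitzky-Golay correction reproduces polynomials and kills spikes", {
  fs <- 10
  tt <- seq_len(300) / fs
  cubic <- 2 + 0.5 * tt - 0.1 * tt^2 + 0.01 * tt^3
  out <- correct_motion_sg(cubic, fs, window_s = 3, polyorder = 3)
  expect_lt(max(abs(out - cubic)), 1e-9)
  flat <- rep(1, 300)
  expect_equal(correct_motion_sg(flat, fs, 3, 3), flat, tolerance = 1e-12)
  spike <- flat; spike[150] <- 2
  sm <- correct_motion_sg(spike, fs, 3, 3)
  expect_lt(abs(sm[150] - 1), 0.2)   # >= 80% amplitude reduction
  expect_error(correct_motion_sg(rep(1, 10), fs, window_s = 10), "longer")
})

test_that("zero-phase bandpass has the designed gains", {
  fs <- 10
  tt <- seq_len(fs * 600) / fs
  passband <- sin(2 * pi * 0.05 * tt)
  out <- bandpass_filter(passband, fs)
  mid <- seq(1000, length(tt) - 1000)
  expect_gt(max(abs(out[mid])), 0.95)
  stopnoise <- sin(2 * pi * 0.5 * tt)
  out2 <- bandpass_filter(stopnoise, fs)
  expect_lt(max(abs(out2[mid])), 0.05)   # >= 95% attenuation
  const <- rep(3, length(tt))
  out3 <- bandpass_filter(const, fs)
  expect_lt(max(abs(out3[mid])), 0.05)   # DC rejected
  expect_error(bandpass_filter(passband, fs, low_hz = 0.1, high_hz = 0.01), "reversed")
  expect_error(bandpass_filter(passband, fs, high_hz = 6), "Nyquist")
})

test_that("MBLL solves the two-wavelength system and round-trips", {
  z <- mbll(rep(0, 5), rep(0, 5), 30)
  expect_equal(z$HbO2, rep(0, 5))
  expect_equal(z$HbR, rep(0, 5))
  expect_equal(unname(default_dpf()), c(6.4, 5.8))
  # forward-then-inverse identity on random concentrations
  set.seed(1)
  hbo <- rnorm(50, sd = 0.3); hbr <- rnorm(50, sd = 0.1)
  eps <- extinction_coefficients(); d <- 35; dpf <- default_dpf()
  path <- (d / 10) * as.numeric(dpf) * 1e-3
  od690 <- (eps[1, 1] * hbo + eps[1, 2] * hbr) * path[1]
  od830 <- (eps[2, 1] * hbo + eps[2, 2] * hbr) * path[2]
  rec <- mbll(od690, od830, d)
  expect_equal(rec$HbO2, hbo, tolerance = 1e-9)
  expect_equal(rec$HbR, hbr, tolerance = 1e-9)
  expect_error(mbll(od690, od830, d, extinction = matrix(c(1, 1, 1, 1), 2)),
               "singular")
})

test_that("short-channel regression removes the projected component", {
  set.seed(2)
  short <- matrix(rnorm(4000), ncol = 2)
  neural <- matrix(rnorm(4000, sd = 0.5), ncol = 2)
  long <- neural + 0.7 * short[, c(1, 2)]
  out <- regress_short_channels(long, short, enabled = TRUE)
  expect_lt(max(abs(cor(out, short))), 0.05)
  # long == short exactly -> residual ~ 0
  same <- regress_short_channels(short[, 1, drop = FALSE], short[, 1, drop = FALSE],
                                 enabled = TRUE)
  expect_lt(max(abs(same)), 1e-10)
  expect_identical(regress_short_channels(long, short, enabled = FALSE), long)
  expect_error(regress_short_channels(long, NULL, enabled = TRUE), "short")
})

test_that("ROI averaging is the sample-wise mean of long channels", {
  ci <- channel_info(c("L1", "L2", "S1"), c(30, 35, 8), c("LPFC", "LPFC", NA))
  hb <- cbind(L1 = c(1, 2, 3), L2 = c(3, 2, 1), S1 = c(9, 9, 9))
  roi <- average_rois(hb, ci, 10)
  expect_equal(unname(roi$values[, "LPFC"]), c(2, 2, 2))
  ci2 <- channel_info(c("L1", "L2"), c(30, 35), c("LPFC", "RPFC"))
  expect_error(average_rois(hb[, 1:2], ci2, 10, roi_labels = c("LPFC", "SMA")),
               "SMA")
})

test_that("the preprocessing chain is linear (superposition)", {
  set.seed(20)
  roi_a <- roi_timeseries(matrix(rnorm(25 * 90 * 5, sd = 0.1), ncol = 5), 25)
  roi_b <- roi_timeseries(matrix(rnorm(25 * 90 * 5, sd = 0.1), ncol = 5), 25)
  mk <- function(vals) synthesize_raw_intensity(
    roi_timeseries(rbind(matrix(0, 25 * 60, 5), vals), 25, ROI_LABELS),
    artifacts = artifacts_off(), seed = 1)
  pp <- function(raw, band) preprocess_recording(raw, bandpass = band)$roi$values
  # without the IIR bandpass the chain is linear to near machine precision
  out_a <- pp(mk(roi_a$values), FALSE)
  out_b <- pp(mk(roi_b$values), FALSE)
  out_ab <- pp(mk(roi_a$values + roi_b$values), FALSE)
  expect_lt(max(abs(out_ab - (out_a + out_b))), 1e-9)
  # the narrowband forward-backward Butterworth at 25 Hz amplifies roundoff
  # (poles ~1e-4 from the unit circle); superposition holds to 1e-5 relative
  bp_a <- pp(mk(roi_a$values), TRUE)
  bp_b <- pp(mk(roi_b$values), TRUE)
  bp_ab <- pp(mk(roi_a$values + roi_b$values), TRUE)
  expect_lt(max(abs(bp_ab - (bp_a + bp_b))), 1e-5)   # absolute, in uM
})

test_that("a pre-MBLL spike is attenuated by the declared processing order", {
  vals <- matrix(0, 25 * 90, 5)
  roi <- roi_timeseries(rbind(matrix(0, 25 * 60, 5), vals), 25, ROI_LABELS)
  raw <- synthesize_raw_intensity(roi, artifacts = artifacts_off(), seed = 1)
  # inject an OD spike directly into the raw intensities
  at <- 25 * 75
  raw$intensity[at, "L01_690"] <- raw$intensity[at, "L01_690"] * exp(-0.5)
  pp <- preprocess_recording(raw)   # SG + bandpass on
  pp_off <- preprocess_recording(raw, motion_correct = FALSE, bandpass = FALSE)
  expect_lt(max(abs(pp$roi$values[at, ])), 0.2 * max(abs(pp_off$roi$values[at, ])))
})
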