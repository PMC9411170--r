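mk_roi <- function(n = 25 * 120, fs = 25, amp = 0.1, freq = 0.05) {
  tt <- (seq_len(n) - 1) / fs
  rest <- tt < 60
  vals <- sapply(seq_along(ROI_LABELS), function(j)
    ifelse(rest, 0, amp * sin(2 * pi * freq * (tt - 60))))
  roi_timeseries(vals, fs, ROI_LABELS)
}

test_that("forward model at zero concentration change gives constant intensities", {
  roi <- roi_timeseries(matrix(0, 500, 5), 25, ROI_LABELS)
  raw <- synthesize_raw_intensity(roi, artifacts = artifacts_off(), seed = 1)
  expect_true(all(abs(raw$intensity - raw$intensity[1, 1]) < 1e-12))
  expect_true(all(raw$intensity > 0))
})

test_that("optical-density bookkeeping matches intensity_to_od to 1e-10", {
  roi <- mk_roi()
  raw <- synthesize_raw_intensity(roi, artifacts = artifact_settings(), seed = 3)
  od <- intensity_to_od(raw, baseline_s = c(0, 60))
  truth <- attr(raw, "truth")$od
  fs <- raw$sampling_rate_hz
  # intensity_to_od recovers the generator's OD up to a per-column constant:
  # +log(mean(exp(-od_baseline)))
  offset <- log(colMeans(exp(-truth[1:(60 * fs), , drop = FALSE])))
  expected <- sweep(truth, 2, -offset, "-")
  expect_lt(max(abs(od - expected)), 1e-10)
})

test_that("sinusoidal hemodynamics round-trip through the MBLL within 1e-6", {
  roi <- mk_roi(amp = 0.2)
  raw <- synthesize_raw_intensity(roi, artifacts = artifacts_off(), seed = 1)
  pp <- preprocess_recording(raw, motion_correct = FALSE, bandpass = FALSE)
  rel <- max(abs(pp$roi$values - roi$values)) / max(abs(roi$values))
  expect_lt(rel, 1e-6)
  # deoxyhemoglobin is recovered at the generator's ratio
  hbr_ratio <- attr(raw, "truth")$hbr_scale
  long1 <- raw$channels$channel_id[raw$channels$kind == "long"][1]
  expect_equal(pp$channel_hbr[, long1], hbr_ratio * pp$channel_hbo[, long1],
               tolerance = 1e-8)
})

test_that("short channels carry systemic signal but no neural signal", {
  set.seed(5)
  vals <- matrix(rnorm(25 * 120 * 5, sd = 0.2), ncol = 5)
  vals[1:(25 * 60), ] <- 0
  roi <- roi_timeseries(vals, 25, ROI_LABELS)
  raw <- synthesize_raw_intensity(
    roi, artifacts = artifact_settings(systemic_uM = 0.05,
                                       short_noise_uM = 0.001,
                                       drift_od = 0, spike_rate_per_min = 0,
                                       spike_od = 0),
    seed = 2)
  pp <- preprocess_recording(raw, motion_correct = FALSE, bandpass = FALSE)
  task <- (60 * 25 + 1):nrow(roi$values)
  neural <- roi$values[task, 1]
  short1 <- pp$short_hbo[task, 1]
  expect_lt(abs(cor(short1, neural)), 0.1)
  sys <- attr(raw, "truth")$systemic[task]
  expect_gt(cor(short1, sys), 0.99)
})

test_that("seeded motion spikes appear as large excursions at recorded samples", {
  roi <- mk_roi(amp = 0.05)
  raw <- synthesize_raw_intensity(
    roi, artifacts = artifact_settings(spike_rate_per_min = 6, spike_od = 0.5,
                                       drift_od = 0, systemic_uM = 0,
                                       short_noise_uM = 0),
    seed = 7)
  truth <- attr(raw, "truth")
  spikes <- truth$spike_samples
  cols <- names(spikes)[vapply(spikes, length, integer(1)) > 0]
  expect_gt(length(cols), 0)
  od <- intensity_to_od(raw, c(0, 60))
  col <- cols[1]
  clean_sd <- sd(diff(truth$od[, col][-unlist(spikes[[col]])]))
  for (at in spikes[[col]])
    expect_gt(abs(od[at, col] - od[at - 2, col]), 5 * clean_sd)
})

test_that("montage problems are rejected", {
  roi <- mk_roi()
  m <- default_montage()
  expect_error(synthesize_raw_intensity(roi, m[m$roi_label != "SMA" | is.na(m$roi_label), ]),
               "SMA")
  expect_error(synthesize_raw_intensity(roi, m[m$kind == "long", ]), "short")
})
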