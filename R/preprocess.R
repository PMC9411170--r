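# Preprocessing: raw two-wavelength intensities -> ROI oxyhemoglobin series.
# Chain: optical density -> Savitzky-Golay motion correction -> zero-phase
# bandpass -> modified Beer-Lambert conversion -> (optional short-channel
# regression) -> per-ROI channel averaging. Every step is linear.

#' Convert intensities to optical-density changes
#'
#' `dOD(t) = -ln(I(t) / mean(I[baseline]))` per channel and wavelength, so
#' the mean optical density over the baseline interval is ~0.
#'
#' @param raw A [raw_recording()].
#' @param baseline_s Two-element interval (seconds) inside the recording
#'   used as baseline; default the first 60 s (the pre-task rest).
#' @return Numeric matrix of dOD, same columns as `raw$intensity`, with
#'   attributes `sampling_rate_hz`, `channels`, `wavelengths_nm`.
#' @export
intensity_to_od <- function(raw, baseline_s = c(0, 60)) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sampling_rate_hz
  n <- nrow(raw$intensity)
  i0 <- max(1L, floor(baseline_s[1] * fs) + 1L)
  i1 <- min(n, ceiling(baseline_s[2] * fs))
  if (i1 <= i0) stop("baseline interval outside the recording")
  bad <- which(raw$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive intensity in channel column '%s' at sample %d",
                 colnames(raw$intensity)[bad[1, 2]], bad[1, 1]))
  ibar <- colMeans(raw$intensity[i0:i1, , drop = FALSE])
  od <- -log(sweep(raw$intensity, 2, ibar, "/"))
  attr(od, "sampling_rate_hz") <- fs
  attr(od, "channels") <- raw$channels
  attr(od, "wavelengths_nm") <- raw$wavelengths_nm
  od
}

#' Savitzky-Golay motion correction
#'
#' Replaces each channel with its Savitzky-Golay fit: a moving local
#' polynomial of order `polyorder` over a `window_s`-second window. Sharp
#' motion spikes are strongly attenuated while polynomial (smooth) content
#' up to the fit order passes unchanged.
#'
#' @param series Numeric matrix (samples x channels) or vector.
#' @param sampling_rate_hz Sampling rate (taken from an attribute if
#'   present).
#' @param window_s Filter window in seconds (default 3 s).
#' @param polyorder Polynomial order (default 3).
#' @return Smoothed series, same shape, attributes preserved.
#' @export
correct_motion_sg <- function(series, sampling_rate_hz = NULL, window_s = 3,
                              polyorder = 3) {
  fs <- sampling_rate_hz %||% attr(series, "sampling_rate_hz")
  if (is.null(fs)) stop("sampling rate unknown")
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  wl <- round(window_s * fs)
  if (wl %% 2 == 0) wl <- wl + 1L
  if (wl < polyorder + 2) wl <- polyorder + 3 - ((polyorder + 3) %% 2 == 0)
  if (wl > nrow(x)) stop("Savitzky-Golay window longer than the series")
  out <- apply(x, 2, function(col) signal::sgolayfilt(col, p = polyorder, n = wl))
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec) out <- drop(out)
  attributes_copy(series, out)
}

# carry the bookkeeping attributes of the preprocessing chain
attributes_copy <- function(from, to) {
  for (a in c("sampling_rate_hz", "channels", "wavelengths_nm"))
    attr(to, a) <- attr(from, a)
  to
}

#' Zero-phase Butterworth bandpass
#'
#' 3rd-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the passband is traversed twice (zero phase,
#' squared magnitude response). Default band 0.01-0.1 Hz.
#'
#' @param series Numeric matrix (samples x channels) or vector.
#' @param sampling_rate_hz Sampling rate (attribute fallback).
#' @param low_hz,high_hz Band edges (Hz), `low < high < Nyquist`.
#' @param order Butterworth order (default 3).
#' @return Filtered series, same shape.
#' @export
bandpass_filter <- function(series, sampling_rate_hz = NULL, low_hz = 0.01,
                            high_hz = 0.1, order = 3) {
  fs <- sampling_rate_hz %||% attr(series, "sampling_rate_hz")
  if (is.null(fs)) stop("sampling rate unknown")
  if (low_hz >= high_hz) stop("band reversed")
  if (high_hz >= fs / 2) stop("high edge at or above Nyquist")
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  if (nrow(x) < 3 * (2 * order + 1))
    stop("series too short for stable zero-phase filtering")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec) out <- drop(out)
  attributes_copy(series, out)
}

#' Modified Beer-Lambert conversion
#'
#' Solves, sample-wise, the two-wavelength system
#' `dOD_lambda = (eps_HbO2,lambda dHbO2 + eps_HbR,lambda dHbR) * (d/10) * DPF_lambda * 1e-3`
#' for concentration changes in micromolar, with extinction coefficients in
#' 1/(mM cm), source-detector distance `d` in mm, and the differential
#' pathlength factors applied per wavelength. Optical density is in
#' natural-log units throughout the package.
#'
#' @param od690,od830 Optical-density vectors of one channel at the two
#'   wavelengths.
#' @param distance_mm Source-detector distance (> 0).
#' @param dpf Differential pathlength factors, default `c(6.4, 5.8)` for
#'   (690, 830) nm.
#' @param extinction 2 x 2 extinction matrix (rows wavelengths, columns
#'   HbO2, HbR); default [extinction_coefficients()].
#' @return List with numeric vectors `HbO2` and `HbR` (uM).
#' @export
mbll <- function(od690, od830, distance_mm, dpf = default_dpf(),
                 extinction = extinction_coefficients()) {
  if (distance_mm <= 0) stop("distance must be positive")
  if (kappa(extinction) > 1e8) stop("extinction matrix is near-singular")
  # pathlength per wavelength in cm, including the micromolar conversion
  path <- (distance_mm / 10) * as.numeric(dpf) * 1e-3
  A <- extinction * path        # rows scaled by each wavelength's pathlength
  conc <- t(solve(A, rbind(od690, od830)))
  list(HbO2 = conc[, 1], HbR = conc[, 2])
}

# internal: apply mbll() across all channels of an OD matrix.
# Returns list(HbO2 = samples x channels, HbR = ...), columns channel ids.
mbll_channels <- function(od, dpf = default_dpf(),
                          extinction = extinction_coefficients()) {
  channels <- attr(od, "channels")
  wl <- attr(od, "wavelengths_nm")
  hbo <- hbr <- matrix(NA_real_, nrow(od), nrow(channels),
                       dimnames = list(NULL, channels$channel_id))
  for (k in seq_len(nrow(channels))) {
    ch <- channels$channel_id[k]
    cc <- mbll(od[, paste0(ch, "_", wl[1])], od[, paste0(ch, "_", wl[2])],
               channels$distance_mm[k], dpf, extinction)
    hbo[, k] <- cc$HbO2; hbr[, k] <- cc$HbR
  }
  list(HbO2 = hbo, HbR = hbr, channels = channels,
       sampling_rate_hz = attr(od, "sampling_rate_hz"))
}

#' Regress systemic physiology out of long channels
#'
#' When enabled, each long channel is replaced by its residual after
#' least-squares projection onto the nearest short-separation channel (plus
#' intercept). Disabled by default: the source recordings this pipeline
#' models recorded short channels without stating that they were regressed
#' out.
#'
#' @param long_hbo Matrix (samples x long channels).
#' @param short_hbo Matrix (samples x short channels).
#' @param enabled Logical flag (default `FALSE` = identity).
#' @param pairing Optional integer vector: for each long channel, the index
#'   of its short channel; defaults to the most correlated short channel.
#' @return Corrected matrix, same shape as `long_hbo`.
#' @export
regress_short_channels <- function(long_hbo, short_hbo, enabled = FALSE,
                                   pairing = NULL) {
  if (!enabled) return(long_hbo)
  if (is.null(short_hbo) || ncol(as.matrix(short_hbo)) == 0)
    stop("short-channel regression enabled but no short channels available")
  long_hbo <- as.matrix(long_hbo); short_hbo <- as.matrix(short_hbo)
  if (is.null(pairing)) {
    cm <- abs(cor(long_hbo, short_hbo))
    pairing <- apply(cm, 1, which.max)
  }
  out <- long_hbo
  for (j in seq_len(ncol(long_hbo))) {
    s <- short_hbo[, pairing[j]]
    fit <- lm.fit(cbind(1, s), long_hbo[, j])
    out[, j] <- fit$residuals
  }
  out
}

#' Average long channels into ROI series
#'
#' Sample-wise unweighted mean of every ROI's long channels; short channels
#' are excluded.
#'
#' @param channel_hbo Matrix (samples x channels), columns named by channel
#'   id.
#' @param channels Channel metadata ([channel_info()]).
#' @param sampling_rate_hz Sampling rate of the series.
#' @param roi_labels ROI ordering of the output (default [ROI_LABELS]
#'   filtered to those present).
#' @return A [roi_timeseries()].
#' @export
average_rois <- function(channel_hbo, channels, sampling_rate_hz,
                         roi_labels = NULL) {
  long <- channels[channels$kind == "long", , drop = FALSE]
  present <- unique(long$roi_label)
  if (is.null(roi_labels))
    roi_labels <- if (all(present %in% ROI_LABELS))
      ROI_LABELS[ROI_LABELS %in% present] else present
  empty <- setdiff(roi_labels, present)
  if (length(empty)) stop("ROI without any long channel: ",
                          paste(empty, collapse = ", "))
  vals <- vapply(roi_labels, function(r) {
    ids <- long$channel_id[long$roi_label == r]
    rowMeans(channel_hbo[, ids, drop = FALSE])
  }, numeric(nrow(channel_hbo)))
  roi_timeseries(vals, sampling_rate_hz, roi_labels)
}

#' Full preprocessing chain
#'
#' Raw intensities to ROI oxyhemoglobin: optical density (baselined on the
#' pre-task rest), Savitzky-Golay motion correction and zero-phase bandpass
#' on optical density, modified Beer-Lambert conversion, optional
#' short-channel regression, per-ROI averaging. Motion correction and
#' bandpass run before the Beer-Lambert step, matching the processing order
#' the pipeline models; each step can be disabled for identity-based
#' testing.
#'
#' @param raw A [raw_recording()].
#' @param baseline_s Baseline interval (seconds) for optical density.
#' @param motion_correct,bandpass,short_regression Stage toggles.
#' @param sg_window_s,sg_polyorder Savitzky-Golay parameters.
#' @param band Bandpass edges (Hz).
#' @param dpf,extinction Beer-Lambert constants.
#' @return List: `roi` (a [roi_timeseries()] of HbO2), `channel_hbo`,
#'   `channel_hbr` (per-channel matrices), `short_hbo`.
#' @export
preprocess_recording <- function(raw, baseline_s = c(0, 60),
                                 motion_correct = TRUE, bandpass = TRUE,
                                 short_regression = FALSE,
                                 sg_window_s = 3, sg_polyorder = 3,
                                 band = c(0.01, 0.1),
                                 dpf = default_dpf(),
                                 extinction = extinction_coefficients()) {
  od <- intensity_to_od(raw, baseline_s)
  if (motion_correct)
    od <- correct_motion_sg(od, window_s = sg_window_s, polyorder = sg_polyorder)
  if (bandpass)
    od <- bandpass_filter(od, low_hz = band[1], high_hz = band[2])
  hb <- mbll_channels(od, dpf, extinction)
  ch <- hb$channels
  long_ids <- ch$channel_id[ch$kind == "long"]
  short_ids <- ch$channel_id[ch$kind == "short"]
  long_hbo <- hb$HbO2[, long_ids, drop = FALSE]
  short_hbo <- hb$HbO2[, short_ids, drop = FALSE]
  long_hbo <- regress_short_channels(long_hbo, short_hbo,
                                     enabled = short_regression)
  roi <- average_rois(long_hbo, ch, hb$sampling_rate_hz)
  list(roi = roi, channel_hbo = hb$HbO2, channel_hbr = hb$HbR,
       short_hbo = short_hbo)
}
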