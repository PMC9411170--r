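# Optics-level forward model: ROI hemodynamics -> raw two-wavelength
# intensities, the generative inverse of the preprocessing chain.

#' Default optode montage
#'
#' A deterministic montage in the style of the acquisition this pipeline
#' models: 25 long-separation channels (5 per ROI, 30-40 mm) and 8
#' short-separation channels (8 mm) with no ROI assignment.
#'
#' @param roi_labels Regions to cover.
#' @param n_long_per_roi Long channels per ROI (default 5).
#' @param n_short Short channels (default 8).
#' @return A [channel_info()] data frame.
#' @export
default_montage <- function(roi_labels = ROI_LABELS, n_long_per_roi = 5,
                            n_short = 8) {
  n_long <- n_long_per_roi * length(roi_labels)
  long <- channel_info(
    channel_id = sprintf("L%02d", seq_len(n_long)),
    source_detector_distance_mm = rep(seq(30, 40, length.out = n_long_per_roi),
                                      length(roi_labels)),
    roi_label = rep(roi_labels, each = n_long_per_roi))
  short <- channel_info(
    channel_id = sprintf("S%02d", seq_len(n_short)),
    source_detector_distance_mm = rep(8, n_short),
    roi_label = NA_character_)
  rbind(long, short)
}

#' Default artifact settings for the forward model
#'
#' @param drift_od Peak-to-peak slow drift amplitude in optical-density
#'   units over the recording (per channel-wavelength).
#' @param spike_rate_per_min Expected motion spikes per minute.
#' @param spike_od Spike amplitude in optical-density units.
#' @param systemic_uM Amplitude (uM) of the shared systemic component
#'   (low-frequency + Mayer-wave sinusoids) added to all channels.
#' @param short_noise_uM White noise sd (uM) on short-channel hemodynamics.
#' @return Named list of artifact parameters.
#' @export
artifact_settings <- function(drift_od = 0.02, spike_rate_per_min = 2,
                              spike_od = 0.5, systemic_uM = 0.05,
                              short_noise_uM = 0.01) {
  list(drift_od = drift_od, spike_rate_per_min = spike_rate_per_min,
       spike_od = spike_od, systemic_uM = systemic_uM,
       short_noise_uM = short_noise_uM)
}

#' Artifact-free forward-model settings
#' @return [artifact_settings()] with every amplitude zero.
#' @export
artifacts_off <- function()
  artifact_settings(drift_od = 0, spike_rate_per_min = 0, spike_od = 0,
                    systemic_uM = 0, short_noise_uM = 0)

#' Synthesize raw two-wavelength intensities from ROI hemodynamics
#'
#' Forward model inverted by the preprocessing chain: every long channel
#' carries its ROI's oxyhemoglobin change (plus a deoxyhemoglobin change
#' `hbr_scale` times it), short channels carry only systemic physiology and
#' noise; concentrations map to optical density through the modified
#' Beer-Lambert law and to intensity as `I = I0 * exp(-dOD)`. Optional
#' artifacts: per-channel slow drift, seeded motion spikes, and a shared
#' systemic component (whose optical-density footprint scales with each
#' channel's pathlength).
#'
#' @param roi_series A [roi_timeseries()] of oxyhemoglobin changes (uM);
#'   include the pre-task rest (zeros) so the baseline is well defined.
#' @param montage A [channel_info()] table; every ROI needs at least one
#'   long channel and the montage at least one short channel.
#' @param artifacts An [artifact_settings()] list.
#' @param seed Integer seed for artifact placement and noise.
#' @param baseline_intensity Detector counts at zero concentration change.
#' @param hbr_scale Deoxyhemoglobin change as a fraction of the
#'   oxyhemoglobin change (default -0.3).
#' @param dpf,extinction Beer-Lambert constants.
#' @return A [raw_recording()] with attribute `"truth"`: the exact
#'   optical-density record (re-centered on the baseline interval), the
#'   clean per-channel hemodynamics, and seeded spike sample indices.
#' @export
synthesize_raw_intensity <- function(roi_series, montage = default_montage(),
                                     artifacts = artifact_settings(),
                                     seed = 1, baseline_intensity = 100,
                                     hbr_scale = -0.3,
                                     dpf = default_dpf(),
                                     extinction = extinction_coefficients()) {
  stopifnot(inherits(roi_series, "roi_ts"))
  if (kappa(extinction) > 1e8) stop("extinction matrix is near-singular")
  long <- montage[montage$kind == "long", , drop = FALSE]
  missing_roi <- setdiff(roi_series$roi_labels, long$roi_label)
  if (length(missing_roi))
    stop("no long channel assigned to ROI: ", paste(missing_roi, collapse = ", "))
  if (!any(montage$kind == "short")) stop("montage needs at least one short channel")
  fs <- roi_series$sampling_rate_hz
  n <- nrow(roi_series$values)
  tt <- (seq_len(n) - 1) / fs
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  # shared systemic physiology (uM): slow oscillation + Mayer wave
  sys_sig <- if (artifacts$systemic_uM > 0) {
    ph <- runif(2, 0, 2 * pi)
    artifacts$systemic_uM * (sin(2 * pi * 0.008 * tt + ph[1]) +
                               0.5 * sin(2 * pi * 0.1 * tt + ph[2]))
  } else numeric(n)

  wl <- c(690, 830)
  nch <- nrow(montage)
  od <- matrix(0, n, nch * 2)
  colnames(od) <- as.vector(outer(montage$channel_id, wl, paste, sep = "_"))
  hbo_clean <- matrix(0, n, nch, dimnames = list(NULL, montage$channel_id))
  spike_samples <- vector("list", nch * 2)
  names(spike_samples) <- colnames(od)

  for (k in seq_len(nch)) {
    ch <- montage$channel_id[k]
    if (montage$kind[k] == "long") {
      hbo <- roi_series$values[, montage$roi_label[k]] + sys_sig
    } else {
      hbo <- sys_sig + rnorm(n, sd = artifacts$short_noise_uM)
    }
    hbr <- hbr_scale * hbo
    hbo_clean[, k] <- hbo
    path <- (montage$distance_mm[k] / 10) * as.numeric(dpf) * 1e-3
    for (w in 1:2) {
      col <- paste0(ch, "_", wl[w])
      od_w <- (extinction[w, "HbO2"] * hbo + extinction[w, "HbR"] * hbr) * path[w]
      if (artifacts$drift_od > 0) {
        slope <- runif(1, -1, 1) * artifacts$drift_od
        od_w <- od_w + slope * tt / max(tt)
      }
      if (artifacts$spike_rate_per_min > 0) {
        n_spk <- rpois(1, artifacts$spike_rate_per_min * n / fs / 60)
        if (n_spk > 0) {
          at <- sort(sample(seq(5, n - 5), n_spk))
          spike_samples[[col]] <- at
          width <- max(1L, round(0.12 * fs))
          for (a in at) {
            idx <- a:min(n, a + 3 * width)
            od_w[idx] <- od_w[idx] +
              artifacts$spike_od * sample(c(-1, 1), 1) * exp(-(idx - a) / width)
          }
        }
      }
      od[, col] <- od_w
    }
  }
  intensity <- baseline_intensity * exp(-od)
  raw <- raw_recording(intensity, montage, fs, wl)
  # what intensity_to_od() will reproduce: od re-centered on the baseline
  attr(raw, "truth") <- list(
    od = od, hbo = hbo_clean, systemic = sys_sig,
    spike_samples = spike_samples, hbr_scale = hbr_scale)
  raw
}
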