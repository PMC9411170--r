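# Core data containers. Lightweight S3: a container is a list with a class
# attribute, validated at construction.

#' ROI oxyhemoglobin time series
#'
#' A `T x R` matrix of hemoglobin concentration changes (micromolar) for `R`
#' named regions of interest at a uniform sampling rate.
#'
#' @param values Numeric matrix, samples in rows, one column per ROI.
#' @param sampling_rate_hz Sampling rate in Hz (positive scalar).
#' @param roi_labels Character vector naming the columns; defaults to
#'   [ROI_LABELS] when the column count matches, otherwise `V1..VR`.
#' @return An object of class `roi_ts` with fields `values`,
#'   `sampling_rate_hz`, `roi_labels`.
#' @export
roi_timeseries <- function(values, sampling_rate_hz, roi_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values)) stop("ROI series must not contain missing samples")
  stopifnot(is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
            sampling_rate_hz > 0)
  R <- ncol(values)
  if (is.null(roi_labels)) {
    roi_labels <- if (R == length(ROI_LABELS)) ROI_LABELS else paste0("V", seq_len(R))
  }
  if (length(roi_labels) != R) stop("roi_labels length must equal ncol(values)")
  colnames(values) <- roi_labels
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz,
                 roi_labels = roi_labels),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d samples x %d ROIs @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate_hz,
              nrow(x$values) / x$sampling_rate_hz))
  cat("  ROIs:", paste(x$roi_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' Channel metadata table
#'
#' Builds the per-channel metadata consumed by the preprocessing module.
#' Channels are classified as long (cortical) or short (scalp/systemic) by
#' source-detector distance.
#'
#' @param channel_id Character or integer vector of unique channel ids.
#' @param source_detector_distance_mm Numeric vector of optode separations.
#' @param roi_label ROI assignment for long channels (`NA` for short
#'   channels).
#' @param short_cut_mm Distance (mm) below which a channel counts as short
#'   separation. Default 15.
#' @return A `data.frame` with columns `channel_id`, `distance_mm`, `kind`
#'   (`"long"`/`"short"`), `roi_label`.
#' @export
channel_info <- function(channel_id, source_detector_distance_mm,
                         roi_label = NA_character_, short_cut_mm = 15) {
  n <- length(channel_id)
  if (anyDuplicated(channel_id)) stop("channel ids must be unique")
  d <- as.numeric(source_detector_distance_mm)
  if (length(d) != n) stop("distance vector length mismatch")
  roi_label <- rep_len(as.character(roi_label), n)
  kind <- ifelse(d < short_cut_mm, "short", "long")
  if (any(kind == "long" & is.na(roi_label)))
    stop("every long channel needs an ROI label")
  data.frame(channel_id = as.character(channel_id), distance_mm = d,
             kind = kind, roi_label = roi_label, stringsAsFactors = FALSE)
}

#' Raw two-wavelength intensity recording
#'
#' Container for detector intensities at 690 and 830 nm plus channel
#' metadata; the optics-level input of the pipeline.
#'
#' @param intensity Numeric matrix, one row per sample; columns named
#'   `<channel_id>_<wavelength>` for both wavelengths of every channel.
#' @param channels Channel metadata as produced by [channel_info()].
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param wavelengths_nm Two wavelengths, default `c(690, 830)`.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(intensity, channels, sampling_rate_hz,
                          wavelengths_nm = c(690, 830)) {
  intensity <- as.matrix(intensity)
  if (any(intensity <= 0))
    stop("intensities must be strictly positive (their log is taken)")
  stopifnot(length(wavelengths_nm) == 2L, sampling_rate_hz > 0)
  expected <- as.vector(outer(channels$channel_id, wavelengths_nm,
                              function(ch, wl) paste0(ch, "_", wl)))
  missing_cols <- setdiff(expected, colnames(intensity))
  if (length(missing_cols))
    stop("intensity is missing columns: ", paste(head(missing_cols, 5), collapse = ", "))
  structure(list(intensity = intensity[, expected, drop = FALSE],
                 channels = channels,
                 sampling_rate_hz = sampling_rate_hz,
                 wavelengths_nm = wavelengths_nm),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples, %d channels x 2 wavelengths @ %g Hz\n",
              nrow(x$intensity), nrow(x$channels), x$sampling_rate_hz))
  cat(sprintf("  long: %d, short: %d; wavelengths %g/%g nm\n",
              sum(x$channels$kind == "long"), sum(x$channels$kind == "short"),
              x$wavelengths_nm[1], x$wavelengths_nm[2]))
  invisible(x)
}

#' Directed network of band-averaged Granger causality
#'
#' One analysis window's directed functional network: a band-averaged GC
#' value (nats) for every ordered pair of ROIs.
#'
#' @param gc Numeric `R x R` matrix of band-averaged GC, `gc[i, j]` = flow
#'   from ROI `j` to ROI `i` (column = source, row = target); diagonal `NA`.
#' @param roi_labels Region names.
#' @param band Two-element frequency band (Hz) the values were averaged over.
#' @param valid Logical `R x R` matrix flagging converged, usable edges.
#' @param window_index Optional index of the window within its trial.
#' @return Object of class `directed_network`.
#' @export
directed_network <- function(gc, roi_labels, band, valid = NULL,
                             window_index = NA_integer_) {
  gc <- as.matrix(gc)
  R <- nrow(gc)
  stopifnot(ncol(gc) == R, length(roi_labels) == R)
  diag(gc) <- NA_real_
  offd <- gc[row(gc) != col(gc)]
  if (any(offd < 0, na.rm = TRUE)) stop("band GC values must be >= 0")
  if (is.null(valid)) valid <- !is.na(gc) | diag(R) == 1
  dimnames(gc) <- list(target = roi_labels, source = roi_labels)
  structure(list(gc = gc, roi_labels = roi_labels, band = band,
                 valid = valid, window_index = window_index),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, digits = 3, ...) {
  R <- length(x$roi_labels)
  cat(sprintf("<directed_network> %d ROIs, %d directed edges, band %g-%g Hz\n",
              R, R * (R - 1), x$band[1], x$band[2]))
  print(round(x$gc, digits))
  invisible(x)
}

#' Long-format edge table of one or more directed networks
#'
#' @param networks A `directed_network` or list of them.
#' @param meta Optional `data.frame` (one row per network) of design columns
#'   to prepend (subject, group, condition, trial, ...).
#' @return `data.frame` with columns from `meta` plus `source_roi`,
#'   `target_roi`, `gc_value`, `valid`.
#' @export
network_edge_table <- function(networks, meta = NULL) {
  if (inherits(networks, "directed_network")) networks <- list(networks)
  if (!is.null(meta) && nrow(meta) != length(networks))
    stop("meta must have one row per network")
  out <- lapply(seq_along(networks), function(k) {
    nw <- networks[[k]]
    R <- length(nw$roi_labels)
    idx <- which(row(nw$gc) != col(nw$gc))
    df <- data.frame(
      source_roi = nw$roi_labels[col(nw$gc)[idx]],
      target_roi = nw$roi_labels[row(nw$gc)[idx]],
      gc_value = nw$gc[idx],
      valid = nw$valid[idx],
      stringsAsFactors = FALSE)
    if (!is.null(meta)) df <- cbind(meta[rep(k, nrow(df)), , drop = FALSE], df,
                                    row.names = NULL)
    df
  })
  do.call(rbind, out)
}

# internal: canonical edge name "SRC.to.TGT"
edge_name <- function(source, target) paste0(source, ".to.", target)

#' All ordered ROI pairs
#'
#' @param roi_labels Region names.
#' @return `data.frame` with columns `source`, `target` (one row per ordered
#'   pair, `R*(R-1)` rows) and canonical `edge` names.
#' @export
roi_pairs <- function(roi_labels = ROI_LABELS) {
  g <- expand.grid(target = roi_labels, source = roi_labels,
                   stringsAsFactors = FALSE)
  g <- g[g$source != g$target, c("source", "target")]
  g$edge <- edge_name(g$source, g$target)
  rownames(g) <- NULL
  g
}
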