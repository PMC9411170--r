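# Plain-text readers and writers for the pipeline's data containers.
# Delimited tables with small JSON/YAML sidecars; everything round-trips.

#' Write an ROI time series to a delimited table
#'
#' CSV with commented header lines carrying the sampling rate and ROI
#' order, then one column per ROI.
#'
#' @param roi A [roi_timeseries()].
#' @param path Output file path.
#' @export
write_roi_timeseries <- function(roi, path) {
  stopifnot(inherits(roi, "roi_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %.10g", roi$sampling_rate_hz),
               sprintf("# rois: %s", paste(roi$roi_labels, collapse = ","))),
             con)
  write.csv(as.data.frame(roi$values), con, row.names = FALSE)
}

#' Read an ROI time series written by [write_roi_timeseries()]
#' @param path File path.
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# sampling_rate_hz: *", "", hdr[1]))
  rois <- strsplit(sub("# rois: *", "", hdr[2]), ",")[[1]]
  vals <- read.csv(path, comment.char = "#")
  roi_timeseries(as.matrix(vals), fs, rois)
}

#' Write a raw recording (intensity table + JSON sidecar)
#'
#' The intensity matrix goes to `<path>` as CSV (columns
#' `channel_wavelength`); channel metadata, wavelengths and sampling rate
#' go to `<path>.json`.
#'
#' @param raw A [raw_recording()].
#' @param path CSV output path.
#' @export
write_raw_recording <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  write.csv(as.data.frame(raw$intensity), path, row.names = FALSE)
  meta <- list(sampling_rate_hz = raw$sampling_rate_hz,
               wavelengths_nm = raw$wavelengths_nm,
               channels = raw$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' Read a raw recording written by [write_raw_recording()]
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return A [raw_recording()].
#' @export
read_raw_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  intensity <- as.matrix(read.csv(path, check.names = FALSE))
  raw_recording(intensity, as.data.frame(meta$channels),
                meta$sampling_rate_hz, meta$wavelengths_nm)
}

#' Write a long-format edge table
#' @param edge_table Output of [network_edge_table()].
#' @param path CSV path.
#' @export
write_edge_table <- function(edge_table, path) {
  write.csv(edge_table, path, row.names = FALSE)
}

#' Write a CoV table
#' @param cov_table Output of [build_cov_table()].
#' @param path CSV path.
#' @export
write_cov_table <- function(cov_table, path) {
  write.csv(as.data.frame(cov_table), path, row.names = FALSE)
}

#' Write a path-analysis table in the conventional column layout
#'
#' Columns: `Dependent var.`, `Independent variable`, `Weight Estimate`,
#' `S.E.`, `C.R.`, `P`.
#'
#' @param fit A [fit_path_model()] result.
#' @param path CSV path.
#' @export
write_path_table <- function(fit, path) {
  tab <- fit$table
  names(tab) <- c("Dependent var.", "Independent variable",
                  "Weight Estimate", "S.E.", "C.R.", "P")
  write.csv(tab, path, row.names = FALSE)
}

#' Write a study design to YAML
#' @param design A [study_design()].
#' @param path YAML path.
#' @export
write_design_yaml <- function(design, path) {
  d <- design
  d$base_network <- list(
    coupling = as.vector(d$base_network$coupling),
    dim = dim(d$base_network$coupling),
    noise_cov = as.vector(d$base_network$noise_cov),
    rois = d$base_network$rois,
    coupling_rate_hz = d$base_network$coupling_rate_hz,
    band = d$base_network$band)
  yaml::write_yaml(unclass(d), path)
}

#' Write a study manifest (JSON)
#'
#' Record-level metadata of a generated study (no series data): subjects,
#' groups, conditions, trials, scores, seeds, and per-cell ground-truth
#' band-GC matrices.
#'
#' @param study A `study_dataset`.
#' @param path JSON path.
#' @export
write_study_manifest <- function(study, path) {
  recs <- lapply(study$records, function(r)
    list(subject_id = r$subject_id, group = r$group, condition = r$condition,
         trial_index = r$trial_index, score = r$score, seed = r$seed,
         n_samples = nrow(r$roi_series$values)))
  cells <- lapply(study$cells, function(cl) list(band_gc = cl$band_gc))
  jsonlite::write_json(list(seed = study$design$seed, records = recs,
                            cells = cells),
                       path, auto_unbox = TRUE, digits = NA)
}
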