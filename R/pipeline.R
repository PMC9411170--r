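# Config-driven orchestration: one call runs the full chain
# (synthetic study or ROI-level user data) -> networks -> CoV -> statistics,
# writing every table with provenance (config hash + seed).

#' Default pipeline configuration
#'
#' Every default matches the analysis conventions the pipeline implements:
#' 54-s nonoverlapping windows, 0.01-0.1 Hz bandpass, 0.01-0.07 Hz GC band,
#' pathlength factors 6.4/5.8, FDR level q = 0.05, removal p = 0.1,
#' 5 trials per subject and condition.
#'
#' @return Nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    synthetic = list(),            # overrides passed to study_design()
    input = NULL,                  # or list(records = "<manifest.csv>")
    preprocessing = list(motion_correct = TRUE, bandpass = TRUE,
                         short_regression = FALSE,
                         band = c(0.01, 0.1), sg_window_s = 3,
                         sg_polyorder = 3),
    gc = list(window_s = 54, band = c(0.01, 0.07), n_tapers = 6,
              pad_to_resolution_hz = 0.005, analysis_rate_hz = 2.5,
              method = "auto", select_window = FALSE,
              candidates = NULL),
    trial_policy = "trial_mean",
    stats = list(
      q = 0.05, removal_p = 0.1,
      mediators = c("RPFC.to.LPMC", "RPFC.to.SMA", "LPMC.to.RPFC",
                    "LPMC.to.SMA", "SMA.to.LPFC"),
      cov_mediators = c("RPMC.to.LPMC", "LPMC.to.LPFC", "LPMC.to.RPMC")))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or `NULL` (full defaults).
#' Unknown keys are rejected; values are type- and range-checked; known
#' keys are merged over [default_config()].
#'
#' @param config Path, list, or `NULL`.
#' @param allow_short_window Permit windows below the 50-s stationarity
#'   floor (off by default).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL, allow_short_window = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list, a YAML path, or NULL")
  defaults <- default_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  for (section in c("preprocessing", "gc", "stats")) {
    bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(bad))
      errs <- c(errs, sprintf("unknown %s keys: %s", section,
                              paste(bad, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config[names(config) %in% names(defaults)])
  band_ok <- function(b) length(b) == 2 && b[1] < b[2]
  if (!band_ok(cfg$gc$band)) errs <- c(errs, "gc band reversed or malformed")
  if (!band_ok(cfg$preprocessing$band)) errs <- c(errs, "bandpass band reversed or malformed")
  if (!is.numeric(cfg$stats$q) || cfg$stats$q <= 0 || cfg$stats$q >= 1)
    errs <- c(errs, sprintf("q = %s outside (0, 1)", cfg$stats$q))
  if (cfg$stats$removal_p <= 0 || cfg$stats$removal_p > 1)
    errs <- c(errs, "removal_p outside (0, 1]")
  if (cfg$gc$window_s < 50 && !allow_short_window)
    errs <- c(errs, sprintf("window_s = %g below the 50-s minimum (set allow_short_window to override)",
                            cfg$gc$window_s))
  if (!cfg$trial_policy %in% c("trial_mean", "trial_as_replicate"))
    errs <- c(errs, "trial_policy must be trial_mean or trial_as_replicate")
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# 32-bit polynomial hash over the serialized config; provenance stamp for
# output tables
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# write a csv with a provenance comment line
write_stamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s seed: %d", hash, seed), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Synthetic mode (default): generates the study from the design implied by
#' the config, computes first-window directed networks per trial, the CoV
#' table, factorial effects with Benjamini-Hochberg flags, estimated
#' marginal means of FDR-significant edges, backward-elimination
#' regressions of the score (and its CoV) on candidate edges, and the two
#' recursive path models; writes every table plus a JSON run manifest to
#' `output_dir`. Deterministic: identical config and seed give identical
#' outputs. ROI-level user data can be supplied instead via
#' `config$input$records`, a CSV manifest with columns `subject_id`,
#' `group`, `condition`, `trial`, `roi_file`, `score`.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param output_dir Directory for outputs (created if missing).
#' @return Invisibly, a list with every in-memory result (`study`,
#'   `networks`, `edge_table`, `cov_table`, `anova_edges`, `anova_score`,
#'   `emm`, `regression`, `regression_cov`, `path_fit`, `path_fit_cov`,
#'   `files`).
#' @export
run_pipeline <- function(config = NULL, output_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  created <- !dir.exists(output_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  hash <- config_hash(cfg)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(file.path(output_dir, files))
    if (created) unlink(output_dir, recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    t_start <- Sys.time()
    log <- list(config = unclass(cfg), config_hash = hash,
                started = format(t_start), stages = list())
    tick <- function(name, extra = NULL) {
      log$stages[[name]] <<- c(list(elapsed_s =
        round(as.numeric(Sys.time() - t_start), 2)), extra)
    }
    emit <- function(df, name) {
      p <- file.path(output_dir, name)
      write_stamped(df, p, hash, cfg$seed)
      files <<- c(files, name)
      p
    }

    stage <- "data"
    if (is.null(cfg$input)) {
      design <- do.call(study_design,
                        c(cfg$synthetic, list(seed = cfg$seed)))
      study <- generate_study(design)
    } else {
      study <- load_roi_study(cfg$input$records)
    }
    for (rec in head(study$records, 1))
      write_roi_timeseries(rec$roi_series,
                           file.path(output_dir, "roi_example.csv"))
    files <- c(files, "roi_example.csv")
    tick("data", list(n_records = length(study$records)))

    stage <- "gc"
    opts <- gc_options(window_s = cfg$gc$window_s, band = cfg$gc$band,
                       n_tapers = cfg$gc$n_tapers,
                       pad_to_resolution_hz = cfg$gc$pad_to_resolution_hz,
                       analysis_rate_hz = cfg$gc$analysis_rate_hz,
                       method = cfg$gc$method)
    if (isTRUE(cfg$gc$select_window)) {
      w <- select_window_length(study$records[[1]]$roi_series,
                                candidates = cfg$gc$candidates)
      opts$window_s <- w
    }
    fw <- first_window_networks(study, opts)
    edge_table <- network_edge_table(fw$networks, fw$meta)
    emit(edge_table, "edge_table.csv")
    clip_total <- sum(vapply(fw$networks,
                             function(nw) attr(nw, "n_clipped") %||% 0L,
                             integer(1)))
    tick("gc", list(n_networks = length(fw$networks),
                    window_s = opts$window_s, clipped_bins = clip_total))

    stage <- "cov"
    cov_tab <- build_cov_table(edge_table)
    emit(as.data.frame(cov_tab), "cov_table.csv")
    tick("cov")

    stage <- "stats_edges"
    pairs <- roi_pairs(study$roi_labels)
    wide <- edge_table
    wide$edge <- edge_name(wide$source_roi, wide$target_roi)
    edge_wide <- reshape_edges_wide(wide)
    anova_edges <- factorial_effects(edge_wide, dvs = pairs$edge,
                                     policy = cfg$trial_policy)
    anova_edges <- add_bh_flags(anova_edges, cfg$stats$q)
    emit(anova_edges, "anova_edges.csv")

    score_df <- unique(edge_wide[, c("subject_id", "group", "condition",
                                     "trial", "score")])
    anova_score <- factorial_effects(score_df, dvs = "score",
                                     policy = cfg$trial_policy)
    cov_df <- as.data.frame(cov_tab)
    cov_dvs <- setdiff(names(cov_df), c("subject_id", "group", "condition"))
    anova_cov <- factorial_effects(cov_df, dvs = cov_dvs)
    anova_cov <- add_bh_flags(anova_cov, cfg$stats$q)
    emit(anova_score, "anova_score.csv")
    emit(anova_cov, "anova_cov.csv")
    tick("stats_edges")

    stage <- "emm"
    emm <- emm_for_significant(anova_edges, cfg$stats$q)
    if (!is.null(emm)) emit(emm, "estimated_marginal_means.csv")
    tick("emm")

    stage <- "regression"
    med <- intersect(cfg$stats$mediators, pairs$edge)
    reg <- backward_regression(edge_wide$score,
                               edge_wide[, med, drop = FALSE],
                               removal_p = cfg$stats$removal_p)
    emit(reg$coefficients, "regression_score.csv")
    cov_med <- paste0("cov_", cfg$stats$cov_mediators)
    cov_med <- intersect(cov_med, names(cov_df))
    ok <- complete.cases(cov_df[, c(cov_med, "cov_score")])
    reg_cov <- backward_regression(cov_df$cov_score[ok],
                                   cov_df[ok, cov_med, drop = FALSE],
                                   removal_p = cfg$stats$removal_p)
    emit(reg_cov$coefficients, "regression_cov.csv")
    tick("regression")

    stage <- "path"
    path_fit <- fit_score_path(edge_wide, med, "score", cfg$stats$q)
    emit(stamp_path(path_fit), "path_score.csv")
    cov_df2 <- cov_df
    names(cov_df2) <- sub("^cov_", "", names(cov_df2))
    path_fit_cov <- fit_score_path(cov_df2, cfg$stats$cov_mediators, "score",
                                   cfg$stats$q)
    emit(stamp_path(path_fit_cov), "path_cov.csv")
    tick("path")

    log$files <- files
    log$finished <- format(Sys.time())
    jsonlite::write_json(log, file.path(output_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(study = study, networks = fw$networks,
                   edge_table = edge_table, cov_table = cov_tab,
                   anova_edges = anova_edges, anova_score = anova_score,
                   anova_cov = anova_cov, emm = emm, regression = reg,
                   regression_cov = reg_cov, path_fit = path_fit,
                   path_fit_cov = path_fit_cov,
                   files = file.path(output_dir, files),
                   config = cfg))
  }, error = on_fail)
}

# long edge table -> one row per (subject, condition, trial) with an edge
# column per directed pair plus the score
reshape_edges_wide <- function(edge_table) {
  keys <- unique(edge_table[, c("subject_id", "group", "condition", "trial",
                                "score")])
  rownames(keys) <- NULL
  for (e in unique(edge_table$edge)) keys[[e]] <- NA_real_
  for (r in seq_len(nrow(keys))) {
    sel <- edge_table$subject_id == keys$subject_id[r] &
      edge_table$condition == keys$condition[r] &
      edge_table$trial == keys$trial[r]
    sub <- edge_table[sel, ]
    keys[r, sub$edge] <- ifelse(sub$valid, sub$gc_value, NA_real_)
  }
  keys
}

# BH adjustment within each effect family across dependent variables
add_bh_flags <- function(anova_tab, q) {
  anova_tab$p_bh <- NA_real_
  anova_tab$significant_bh <- NA
  for (eff in setdiff(unique(anova_tab$effect), "Residuals")) {
    sel <- anova_tab$effect == eff
    adj <- bh_adjust(anova_tab$p[sel], q)
    anova_tab$p_bh[sel] <- adj$adjusted
    anova_tab$significant_bh[sel] <- adj$reject
  }
  anova_tab
}

emm_for_significant <- function(anova_tab, q) {
  models <- attr(anova_tab, "models")
  sig <- anova_tab[!is.na(anova_tab$significant_bh) & anova_tab$significant_bh, ]
  if (!nrow(sig)) return(NULL)
  out <- list()
  for (r in seq_len(nrow(sig))) {
    specs <- strsplit(sig$effect[r], ":", fixed = TRUE)[[1]]
    em <- estimated_marginal_means(models[[sig$dv[r]]], specs)
    em <- cbind(data.frame(dv = sig$dv[r], effect = sig$effect[r]), em)
    out[[r]] <- em
  }
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) { d[setdiff(nm, names(d))] <- NA; d[nm] })
  do.call(rbind, out)
}

# the two-layer recursive path model: factors -> mediating edges -> outcome
fit_score_path <- function(data, mediators, outcome, q) {
  d <- data
  # effects coding: first level alphabetically = +1
  d$skill <- ifelse(d$group == sort(unique(d$group))[1], 1, -1)
  d$simulator <- ifelse(d$condition == sort(unique(d$condition))[1], 1, -1)
  arrows <- rbind(
    expand.grid(independent = c("skill", "simulator"), dependent = mediators,
                stringsAsFactors = FALSE),
    data.frame(independent = mediators, dependent = outcome))
  fit <- fit_path_model(path_spec(arrows), d)
  adj <- bh_adjust(fit$table$p, q)
  fit$table$p_bh <- adj$adjusted
  fit$table$significant_bh <- adj$reject
  fit
}

stamp_path <- function(fit) {
  tab <- fit$table
  names(tab)[1:6] <- c("Dependent var.", "Independent variable",
                       "Weight Estimate", "S.E.", "C.R.", "P")
  tab
}

#' Load an ROI-level study from a manifest
#'
#' Reads a CSV manifest (`subject_id`, `group`, `condition`, `trial`,
#' `roi_file`, `score`) pointing at [write_roi_timeseries()] files, and
#' assembles a `study_dataset`-shaped object that the network and
#' statistics stages consume.
#'
#' @param manifest_csv Path to the manifest.
#' @return A list of class `study_dataset` (without generator ground
#'   truth).
#' @export
load_roi_study <- function(manifest_csv) {
  man <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "trial", "roi_file", "score")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  base <- dirname(manifest_csv)
  records <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$roi_file[i]
    if (!file.exists(p)) p <- file.path(base, man$roi_file[i])
    list(subject_id = man$subject_id[i], group = man$group[i],
         condition = man$condition[i], trial_index = man$trial[i],
         roi_series = read_roi_timeseries(p), score = man$score[i])
  })
  structure(list(design = NULL, cells = NULL, records = records,
                 roi_labels = records[[1]]$roi_series$roi_labels),
            class = "study_dataset")
}
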