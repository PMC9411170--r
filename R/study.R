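# Factorial study generator: a 2 (skill) x 2 (simulator) repeated-trials
# design with per-cell ground-truth networks and behavior scores driven by
# selected couplings.

#' Default ground-truth base network for study generation
#'
#' VAR(1) on a 2 Hz coupling grid over the five ROIs: strong self-couplings
#' (0.8) concentrate spectral power in the neurovascular band, and a sparse
#' set of directed couplings along the fronto-motor edges the analysis
#' focuses on. Stationarity is checked at construction.
#'
#' @param self AR self-coupling applied to every region (default 0.8).
#' @param innovation_sd Innovation standard deviation in uM (default 0.05).
#' @return A [ground_truth_network()].
#' @export
default_study_truth <- function(self = 0.8, innovation_sd = 0.05) {
  R <- length(ROI_LABELS)
  A <- array(0, dim = c(R, R, 1),
             dimnames = list(ROI_LABELS, ROI_LABELS, NULL))
  diag(A[, , 1]) <- self
  set_edge <- function(src, tgt, w) A[tgt, src, 1] <<- w
  set_edge("RPFC", "SMA", 0.15)
  set_edge("LPMC", "SMA", 0.12)
  set_edge("SMA", "LPFC", 0.12)
  set_edge("RPFC", "LPMC", 0.10)
  set_edge("LPMC", "RPFC", 0.10)
  set_edge("RPMC", "LPMC", 0.10)
  set_edge("LPMC", "LPFC", 0.08)
  set_edge("LPMC", "RPMC", 0.08)
  ground_truth_network(A, diag(innovation_sd^2, R), ROI_LABELS,
                       coupling_rate_hz = 2)
}

#' Default group/condition effect map
#'
#' Additive coupling offsets defining which edges carry skill, simulator,
#' and interaction effects in generated studies: skill raises the
#' frontal-to-SMA and SMA-to-prefrontal couplings in experts, the simulator
#' raises right-prefrontal-to-left-motor coupling in VR, and two edges
#' carry interactions.
#'
#' @param delta Offset magnitude on the coupling scale (default 0.1).
#' @return Named list: per edge, a vector of `skill`, `simulator`,
#'   `interaction` offsets.
#' @export
default_effect_map <- function(delta = 0.1) {
  list(
    "RPFC.to.SMA"  = c(skill = delta),
    "LPMC.to.SMA"  = c(skill = delta),
    "SMA.to.LPFC"  = c(skill = delta, interaction = -delta),
    "RPFC.to.LPMC" = c(simulator = delta),
    "LPMC.to.RPFC" = c(interaction = -delta))
}

#' Study design specification
#'
#' Validated container for the factorial design the generator realizes:
#' 2 skill groups x 2 simulator conditions, repeated trials per subject.
#'
#' @param n_subjects Named counts per skill group,
#'   default `c(expert = 7, novice = 6)`.
#' @param conditions Simulator conditions, default `c("physical", "VR")`.
#' @param n_trials Trials per subject and condition (>= 2; default 5).
#' @param trial_duration_s Task duration per trial (>= 54 s; default 120).
#' @param rest_duration_s Pre-task rest (baseline) duration (default 60).
#' @param sampling_rate_hz Acquisition rate (default 25).
#' @param base_network A [ground_truth_network()] shared by all cells.
#' @param effect_map Per-edge coupling offsets, as [default_effect_map()];
#'   `NULL` for a null study with no group/condition differences.
#' @param behavior_weights Named weights of ground-truth edges on the trial
#'   score.
#' @param behavior_intercept Score intercept.
#' @param behavior_noise_sd Score noise sd; scalar or named per group
#'   (experts less variable by default).
#' @param trial_jitter_sd Log-normal sd of per-trial multiplicative jitter
#'   on the directed couplings; creates trial-to-trial variability in true
#'   connectivity (and hence in scores).
#' @param measurement_noise_sd White measurement noise on ROI series (uM).
#' @param include_raw Also synthesize raw optics-level recordings.
#' @param artifacts [artifact_settings()] used when `include_raw`.
#' @param seed Master seed; the whole dataset is a deterministic function
#'   of the design.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = c(expert = 7, novice = 6),
                         conditions = c("physical", "VR"),
                         n_trials = 5,
                         trial_duration_s = 120,
                         rest_duration_s = 60,
                         sampling_rate_hz = 25,
                         base_network = default_study_truth(),
                         effect_map = default_effect_map(),
                         behavior_weights = c("RPFC.to.SMA" = 21),
                         behavior_intercept = 60,
                         behavior_noise_sd = c(expert = 3, novice = 6),
                         trial_jitter_sd = 0.35,
                         measurement_noise_sd = 0.01,
                         include_raw = FALSE,
                         artifacts = artifact_settings(),
                         seed = 1) {
  if (n_trials < 2) stop("n_trials must be >= 2 (trial variability is undefined otherwise)")
  if (trial_duration_s < 54) stop("trial_duration_s must cover one 54-s analysis window")
  if (any(n_subjects < 1) || sampling_rate_hz <= 0) stop("counts and rates must be positive")
  stopifnot(inherits(base_network, "gt_network"), length(conditions) == 2)
  if (is.null(names(n_subjects)) || !all(nzchar(names(n_subjects))))
    stop("n_subjects must be named by group")
  structure(list(n_subjects = n_subjects, groups = names(n_subjects),
                 conditions = conditions, n_trials = n_trials,
                 trial_duration_s = trial_duration_s,
                 rest_duration_s = rest_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 base_network = base_network, effect_map = effect_map,
                 behavior_weights = behavior_weights,
                 behavior_intercept = behavior_intercept,
                 behavior_noise_sd = behavior_noise_sd,
                 trial_jitter_sd = trial_jitter_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 include_raw = include_raw, artifacts = artifacts,
                 seed = seed),
            class = "study_design")
}

# internal: coupling matrix of one design cell (base + effect offsets)
cell_coupling <- function(design, group, condition) {
  A <- design$base_network$coupling
  rois <- design$base_network$rois
  is_high_group <- group == design$groups[1]        # first group = "expert"
  is_high_cond <- condition == design$conditions[2] # second condition = "VR"
  for (edge in names(design$effect_map %||% list())) {
    parts <- strsplit(edge, ".to.", fixed = TRUE)[[1]]
    src <- match(parts[1], rois); tgt <- match(parts[2], rois)
    if (is.na(src) || is.na(tgt)) stop("effect map names unknown edge: ", edge)
    eff <- design$effect_map[[edge]]
    off <- 0
    if (is_high_group) off <- off + (eff["skill"] %|NA|% 0)
    if (is_high_cond) off <- off + (eff["simulator"] %|NA|% 0)
    if (is_high_group && is_high_cond) off <- off + (eff["interaction"] %|NA|% 0)
    A[tgt, src, 1] <- A[tgt, src, 1] + off
  }
  A
}

`%|NA|%` <- function(a, b) if (is.null(a) || is.na(a)) b else unname(a)

# internal: jitter the off-diagonal couplings of a lag-1 array, rescaling
# if the jittered system drifts toward instability
jitter_coupling <- function(A, sd) {
  if (sd <= 0) return(A)
  offd <- row(A[, , 1]) != col(A[, , 1])
  J <- A
  J[, , 1][offd] <- A[, , 1][offd] * exp(rnorm(sum(offd), 0, sd))
  while (var_spectral_radius(J) >= 0.98) J[, , 1][offd] <- J[, , 1][offd] * 0.9
  J
}

#' Generate a full synthetic study
#'
#' Realizes a [study_design()]: per design cell a ground-truth network
#' (base couplings plus effect offsets), per trial a jittered copy of the
#' cell network, simulated ROI hemodynamics, a behavior score read out from
#' the trial's true band-averaged couplings, and optionally a raw
#' optics-level recording. Deterministic given the design seed.
#'
#' @param design A [study_design()].
#' @return Object of class `study_dataset`: `design`, `cells` (per
#'   group:condition, the `gt_network` and its population band-GC matrix),
#'   `records` (one per subject x condition x trial, each with
#'   `roi_series`, `score`, `truth_edges`, and `raw` when requested).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rois <- design$base_network$rois
  fs <- design$sampling_rate_hz
  n_task <- round(design$trial_duration_s * fs)
  weights <- design$behavior_weights
  cells <- list()
  for (g in design$groups) for (cond in design$conditions) {
    A <- cell_coupling(design, g, cond)
    net <- ground_truth_network(A, design$base_network$noise_cov, rois,
                                design$base_network$coupling_rate_hz)
    cells[[paste(g, cond, sep = ":")]] <-
      list(net = net, band_gc = population_band_gc(net))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  base_seed <- as.integer(design$seed %% 1000003L)
  records <- list()
  rec_i <- 0L
  for (g in design$groups) {
    n_sub <- design$n_subjects[[g]]
    for (s in seq_len(n_sub)) {
      subject_id <- sprintf("%s%d", toupper(substr(g, 1, 1)), s)
      for (cond in design$conditions) {
        cell <- cells[[paste(g, cond, sep = ":")]]
        for (tr in seq_len(design$n_trials)) {
          rec_i <- rec_i + 1L
          rec_seed <- (base_seed * 1009L + rec_i * 2063L) %% 2147483629L
          set.seed(rec_seed)
          A_tr <- jitter_coupling(cell$net$coupling, design$trial_jitter_sd)
          net_tr <- ground_truth_network(A_tr, cell$net$noise_cov, rois,
                                         cell$net$coupling_rate_hz)
          truth_edges <- if (length(weights)) {
            trial_edge_truth(net_tr, names(weights))
          } else numeric(0)
          roi <- simulate_var_network(
            net_tr, n_task, fs, seed = rec_seed + 1L,
            measurement_noise_sd = design$measurement_noise_sd)
          score <- simulate_behavior_scores(
            matrix(truth_edges, nrow = 1,
                   dimnames = list(NULL, names(truth_edges))),
            weights = weights,
            intercept = design$behavior_intercept,
            noise_sd = group_noise_sd(design$behavior_noise_sd, g),
            seed = rec_seed + 2L)
          rec <- list(subject_id = subject_id, group = g, condition = cond,
                      trial_index = tr, roi_series = roi,
                      score = as.numeric(score), truth_edges = truth_edges,
                      seed = rec_seed)
          if (design$include_raw) {
            rest <- matrix(0, round(design$rest_duration_s * fs), length(rois))
            full <- roi_timeseries(rbind(rest, roi$values), fs, rois)
            rec$raw <- synthesize_raw_intensity(
              full, artifacts = design$artifacts, seed = rec_seed + 3L)
          }
          records[[rec_i]] <- rec
        }
      }
    }
  }
  structure(list(design = design, cells = cells, records = records,
                 roi_labels = rois),
            class = "study_dataset")
}

group_noise_sd <- function(sd, group) {
  if (length(sd) == 1L && is.null(names(sd))) return(as.numeric(sd))
  if (!group %in% names(sd)) stop("behavior_noise_sd has no entry for group ", group)
  as.numeric(sd[[group]])
}

# population band GC of selected edges only (cheaper than the full matrix)
trial_edge_truth <- function(net, edges) {
  rois <- net$rois
  out <- setNames(numeric(length(edges)), edges)
  for (e in edges) {
    parts <- strsplit(e, ".to.", fixed = TRUE)[[1]]
    i <- match(parts[2], rois); j <- match(parts[1], rois)  # target, source
    sub <- pair_subnet_gc(net, j, i)
    out[e] <- sub
  }
  out
}

# pairwise population band GC source -> target for one ordered pair
pair_subnet_gc <- function(net, source, target, resolution_hz = 0.005) {
  fs <- net$coupling_rate_hz
  nfft <- 2 * ceiling(fs / (2 * resolution_hz))
  freqs <- (0:(nfft / 2)) * fs / nfft
  sp <- var_spectral_density(net, freqs)
  inb <- which(freqs >= net$band[1] & freqs <= net$band[2])
  pair <- c(source, target)
  S2 <- sp$S[pair, pair, , drop = FALSE]
  S1 <- S2; S1[, , 2:(length(freqs) - 1)] <- 2 * S1[, , 2:(length(freqs) - 1)]
  cs <- structure(list(freqs = freqs, S = S1, n_segments = NA_integer_, fs = fs),
                  class = "cross_spectrum")
  fact <- wilson_factorize(cs, tol = 1e-10, max_iter = 200)
  g <- geweke_gc_spectrum(cs, fact, source = 1, target = 2)
  mean(g$value[inb])
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- x$design
  cat(sprintf("<study_dataset> %s x %s, %d records (%d trials/subject/condition)\n",
              paste(d$groups, collapse = "/"),
              paste(d$conditions, collapse = "/"),
              length(x$records), d$n_trials))
  cat(sprintf("  %g s task @ %g Hz, seed %d, raw recordings: %s\n",
              d$trial_duration_s, d$sampling_rate_hz, d$seed,
              if (d$include_raw) "yes" else "no"))
  invisible(x)
}
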