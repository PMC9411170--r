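# Geweke frequency-domain Granger causality, band averaging, directed
# networks, surrogate nulls, and stationarity-guided window selection.

#' Geweke spectral Granger causality for one ordered pair
#'
#' Computes the frequency-resolved Granger causality from `source` to
#' `target` using the Geweke (1982) decomposition,
#' `f(omega) = ln[ S_tt / (S_tt - (Sigma_ss - Sigma_st^2 / Sigma_tt) |H_ts|^2) ]`
#' with `H` and `Sigma` from a (bivariate) Wilson factorization. The
#' denominator is evaluated from the factorized spectrum
#' `S = H Sigma H^*`, which is algebraically nonnegative; at convergence it
#' equals the input spectrum within tolerance. Any residual negative values
#' are clipped to zero and counted.
#'
#' @param cs The `cross_spectrum` the factorization was computed from.
#' @param fact A converged [wilson_factorize()] result.
#' @param source,target Channel indices (or label strings) with
#'   `source != target`.
#' @return Object of class `gc_spectrum`: `freqs`, `value` (nats, >= 0),
#'   `n_clipped`, `source`, `target`, `valid` (FALSE when the factorization
#'   had not converged).
#' @export
geweke_gc_spectrum <- function(cs, fact, source, target) {
  stopifnot(inherits(fact, "wilson_fact"))
  idx <- function(z) {
    if (is.character(z)) match(z, cs$labels) else as.integer(z)
  }
  s <- idx(source); t <- idx(target)
  if (is.na(s) || is.na(t)) stop("unknown channel")
  if (s == t) stop("source and target must differ")
  Sigma <- fact$Sigma
  Nf <- dim(fact$H)[3]
  s2 <- Sigma[s, s] - Sigma[s, t]^2 / Sigma[t, t]
  Hts <- fact$H[t, s, ]
  # S_tt reconstructed from the factorization (two-sided scale), vectorized
  R <- dim(fact$H)[1]
  Stt <- numeric(Nf)
  for (a in seq_len(R)) for (b in seq_len(R))
    Stt <- Stt + Re(fact$H[t, a, ] * Sigma[a, b] * Conj(fact$H[t, b, ]))
  den <- Stt - s2 * Mod(Hts)^2
  den <- pmax(den, .Machine$double.xmin)
  val <- log(Stt / den)
  n_clipped <- sum(val < 0)
  val <- pmax(val, 0)
  structure(list(freqs = fact$freqs, value = val, n_clipped = n_clipped,
                 source = source, target = target,
                 valid = isTRUE(fact$converged)),
            class = "gc_spectrum")
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("<gc_spectrum> %s -> %s over %d frequencies; mean %.4g nats%s\n",
              x$source, x$target, length(x$freqs), mean(x$value),
              if (x$valid) "" else " [INVALID: factorization not converged]"))
  invisible(x)
}

#' Band-average a Granger-causality spectrum
#'
#' Unweighted mean of the GC spectrum over grid frequencies inside the band
#' (endpoints inclusive).
#'
#' @param gc A [geweke_gc_spectrum()] result.
#' @param band Two-element frequency interval (Hz).
#' @return Scalar band-averaged GC (nats).
#' @export
band_average_gc <- function(gc, band = c(0.01, 0.07)) {
  inb <- gc$freqs >= band[1] & gc$freqs <= band[2]
  if (!any(inb)) stop("no grid frequencies inside band")
  if (sum(inb) < 3)
    warning("fewer than 3 grid frequencies inside band; increase padding")
  mean(gc$value[inb])
}

# internal: band GC in both directions for a 2-column window.
# Returns list(fwd = col1->col2, rev = col2->col1, valid, n_clipped).
band_gc_bivariate <- function(x2, fs, opts = gc_options()) {
  cs <- estimate_cross_spectrum(x2, fs, opts)
  fact <- wilson_factorize(cs, tol = opts$tol, max_iter = opts$max_iter,
                           ridge = opts$ridge)
  g12 <- geweke_gc_spectrum(cs, fact, source = 1, target = 2)
  g21 <- geweke_gc_spectrum(cs, fact, source = 2, target = 1)
  list(fwd = band_average_gc(g12, opts$band),
       rev = band_average_gc(g21, opts$band),
       valid = isTRUE(fact$converged),
       n_clipped = g12$n_clipped + g21$n_clipped,
       iterations = fact$iterations)
}

#' Directed functional network of one analysis window
#'
#' Runs the full nonparametric chain (cross-spectrum, Wilson factorization,
#' Geweke decomposition, band average) for every ordered pair of regions.
#' GC is computed pairwise: each unordered pair's 2-channel sub-series is
#' estimated and factorized on its own, yielding both directions at once.
#'
#' @param window A `roi_ts` window (or matrix plus `sampling_rate_hz`).
#' @param opts A [gc_options()].
#' @param sampling_rate_hz For bare matrices.
#' @return A [directed_network()] with `R*(R-1)` edges and per-edge validity
#'   flags (an edge is invalid when its pair's factorization did not
#'   converge); attribute `"n_clipped"` counts clipped frequency bins.
#' @export
pairwise_directed_network <- function(window, opts = gc_options(),
                                      sampling_rate_hz = NULL) {
  if (inherits(window, "roi_ts")) {
    x <- window$values; fs <- window$sampling_rate_hz; labs <- window$roi_labels
  } else {
    if (is.null(sampling_rate_hz)) stop("sampling_rate_hz required for bare matrices")
    x <- as.matrix(window); fs <- sampling_rate_hz
    labs <- colnames(x)
    if (is.null(labs)) labs <- paste0("V", seq_len(ncol(x)))
  }
  R <- ncol(x)
  if (R < 2) stop("need at least two regions")
  gcm <- matrix(NA_real_, R, R)
  valid <- matrix(TRUE, R, R)
  clipped <- 0L
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    bg <- band_gc_bivariate(x[, c(i, j), drop = FALSE], fs, opts)
    gcm[j, i] <- bg$fwd   # i -> j (row target, column source)
    gcm[i, j] <- bg$rev   # j -> i
    valid[j, i] <- valid[i, j] <- bg$valid
    clipped <- clipped + bg$n_clipped
  }
  nw <- directed_network(gcm, labs, opts$band,
                         valid = valid,
                         window_index = attr(window, "window_index") %||% NA_integer_)
  attr(nw, "n_clipped") <- clipped
  nw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First-window directed networks for every trial of a study
#'
#' Computes one directed network per trial record, always on the first
#' analysis window of the trial's task period. Trials shorter than one
#' window are skipped with a warning.
#'
#' @param study A `study_dataset` from [generate_study()] (or any list with
#'   `records` holding `roi_series` and design labels).
#' @param opts A [gc_options()].
#' @return List with `networks` (list of [directed_network()]s) and `meta`
#'   (`data.frame` of subject, group, condition, trial, score per network).
#' @export
first_window_networks <- function(study, opts = gc_options()) {
  networks <- list(); meta <- list()
  for (rec in study$records) {
    rs <- rec$roi_series
    if (nrow(rs$values) / rs$sampling_rate_hz < opts$window_s) {
      warning(sprintf("trial %s/%s/%d shorter than one %g-s window; skipped",
                      rec$subject_id, rec$condition, rec$trial_index,
                      opts$window_s))
      next
    }
    win <- segment_windows(rs, opts$window_s)[[1]]
    nw <- pairwise_directed_network(win, opts)
    networks[[length(networks) + 1L]] <- nw
    meta[[length(meta) + 1L]] <- data.frame(
      subject_id = rec$subject_id, group = rec$group,
      condition = rec$condition, trial = rec$trial_index,
      score = rec$score %||% NA_real_, stringsAsFactors = FALSE)
  }
  list(networks = networks, meta = do.call(rbind, meta))
}

#' Circular-shift surrogate threshold for band GC
#'
#' Null distribution of the band-averaged GC from `source` to `target`
#' obtained by circularly shifting the source channel by random offsets
#' (at least 10% of the window length), which destroys cross-channel timing
#' while preserving each channel's spectrum.
#'
#' @param x2 Two-column matrix (source, target) or `roi_ts` with 2 channels.
#' @param sampling_rate_hz For bare matrices.
#' @param opts A [gc_options()].
#' @param n_surrogates Number of surrogate shifts (default 200).
#' @param prob Quantile to return (default 0.95).
#' @param seed Integer seed for the shift offsets.
#' @return List with `threshold` (the quantile), `null` (all surrogate band
#'   GC values), `observed` (source -> target band GC of the data).
#' @export
gc_surrogate_threshold <- function(x2, sampling_rate_hz = NULL,
                                   opts = gc_options(), n_surrogates = 200,
                                   prob = 0.95, seed = 1) {
  if (inherits(x2, "roi_ts")) {
    x <- x2$values; fs <- x2$sampling_rate_hz
  } else {
    if (is.null(sampling_rate_hz)) stop("sampling_rate_hz required")
    x <- as.matrix(x2); fs <- sampling_rate_hz
  }
  stopifnot(ncol(x) == 2)
  n <- nrow(x)
  observed <- band_gc_bivariate(x, fs, opts)$fwd
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  lo <- max(2L, floor(0.1 * n))
  shifts <- sample(seq(lo, n - lo), n_surrogates, replace = TRUE)
  null <- vapply(shifts, function(s) {
    xs <- cbind(x[c((s + 1):n, 1:s), 1], x[, 2])
    band_gc_bivariate(xs, fs, opts)$fwd
  }, numeric(1))
  list(threshold = unname(quantile(null, prob)), null = null,
       observed = observed)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' ADF regression with intercept ("drift" case):
#' `diff(y)_t ~ y_(t-1) + diff(y)_(t-1..k) + 1`. The p-value interpolates
#' the Fuller critical-value table for the tau_mu statistic. Rejection
#' (small p) supports stationarity of the segment.
#'
#' @param x Numeric series.
#' @param lags Number of lagged differences; by default selected by AIC
#'   over `0..trunc(12 * (n/100)^(1/4))`.
#' @return List with `statistic`, `p_value` (clamped to [0.01, 0.99] at the
#'   table edges), `lags`.
#' @export
adf_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("series too short for an ADF regression")
  dy <- diff(x)
  m <- length(dy)
  ylag <- x[seq_len(m)]
  fit_k <- function(k, first) {
    X <- cbind(1, ylag)
    if (k > 0) {
      dl <- sapply(seq_len(k), function(j) c(rep(NA, j), dy[seq_len(m - j)]))
      X <- cbind(X, dl)
    }
    keep <- seq_len(m) >= first
    fit <- lm.fit(X[keep, , drop = FALSE], dy[keep])
    list(fit = fit, X = X[keep, , drop = FALSE], n = sum(keep))
  }
  if (is.null(lags)) {
    maxlag <- min(trunc(12 * (m / 100)^0.25), m %/% 4)
    aics <- vapply(0:maxlag, function(k) {
      f <- fit_k(k, maxlag + 1L)   # common sample across candidate lags
      f$n * log(sum(f$fit$residuals^2) / f$n) + 2 * (k + 2)
    }, numeric(1))
    lags <- (0:maxlag)[which.min(aics)]
  }
  f <- fit_k(lags, lags + 1L)
  res <- f$fit$residuals
  df <- f$n - ncol(f$X)
  s2 <- sum(res^2) / df
  XtXi <- chol2inv(chol(crossprod(f$X)))
  se <- sqrt(s2 * XtXi[2, 2])
  stat <- f$fit$coefficients[2] / se
  list(statistic = unname(stat), p_value = adf_p_value(stat, f$n),
       lags = lags)
}

# Fuller tau_mu critical values (constant, no trend), interpolated in both
# sample size and probability, as is conventional for table-based ADF
# p-values.
.ADF_TABLE <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  crit = matrix(c(
    -3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72,
    -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
    -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
    -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
    -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
    -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60),
    nrow = 6, byrow = TRUE))

adf_p_value <- function(stat, n) {
  tab <- .ADF_TABLE
  # interpolate critical values to this sample size
  crit_n <- vapply(seq_along(tab$p), function(j) {
    approx(tab$n, tab$crit[, j], xout = min(n, 500), rule = 2)$y
  }, numeric(1))
  p <- approx(crit_n, tab$p, xout = stat, rule = 2)$y
  min(max(p, 0.01), 0.99)
}

#' Stationarity-guided analysis window selection
#'
#' Returns the smallest candidate window length for which at least
#' `pass_rate` of all (ROI x window) segments reject an ADF unit root at
#' level `alpha`. With `candidates = NULL` selection is bypassed and the
#' configured default of 54 s is returned.
#'
#' @param roi_series A [roi_timeseries()].
#' @param candidates Ascending candidate window lengths (seconds), all
#'   `>= min_s` and no longer than the series.
#' @param min_s Minimum admissible window (50 s).
#' @param alpha ADF rejection level.
#' @param pass_rate Required fraction of rejecting segments (default 0.9).
#' @param default_s Returned when selection is bypassed.
#' @param analysis_rate_hz Series are decimated to this rate before testing
#'   (as for spectral estimation): at the acquisition rate a band-limited
#'   hemodynamic signal is so oversampled that any window looks like a unit
#'   root.
#' @return Selected window length in seconds, with attribute `"pass_rates"`.
#' @export
select_window_length <- function(roi_series, candidates = NULL, min_s = 50,
                                 alpha = 0.05, pass_rate = 0.9,
                                 default_s = 54, analysis_rate_hz = 2.5) {
  if (is.null(candidates)) return(default_s)
  stopifnot(inherits(roi_series, "roi_ts"))
  dec <- decimate_matrix(roi_series$values, roi_series$sampling_rate_hz,
                         analysis_rate_hz)
  roi_series <- roi_timeseries(dec$x, dec$fs, roi_series$roi_labels)
  dur <- nrow(roi_series$values) / roi_series$sampling_rate_hz
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending")
  if (any(candidates < min_s))
    stop(sprintf("candidates below the %g-s minimum window", min_s))
  if (any(candidates > dur))
    stop(sprintf("candidate longer than the series (%.1f s)", dur))
  rates <- vapply(candidates, function(w) {
    wins <- segment_windows(roi_series, w)
    passes <- unlist(lapply(wins, function(win) {
      apply(win$values, 2, function(col) adf_test(col)$p_value <= alpha)
    }))
    mean(passes)
  }, numeric(1))
  ok <- which(rates >= pass_rate)
  if (!length(ok))
    stop("no candidate passes the stationarity screen; pass rates: ",
         paste(sprintf("%gs=%.2f", candidates, rates), collapse = ", "))
  out <- candidates[ok[1]]
  attr(out, "pass_rates") <- setNames(rates, candidates)
  out
}
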