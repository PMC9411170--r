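# Statistical inference chain: screening tests, two-factor between-subject
# effects with partial eta squared, Benjamini-Hochberg control, backward
# elimination regression, and recursive path analysis.

#' Shapiro-Wilk normality screen
#'
#' Advisory normality screen of each dependent variable within each design
#' cell; it gates nothing downstream.
#'
#' @param data `data.frame` holding the dependent variables and factors.
#' @param dvs Character vector of dependent-variable column names.
#' @param by Factor columns defining cells (default group and condition).
#' @return `data.frame`: `dv`, one column per `by` factor, `n`, `W`, `p`,
#'   `flag` (`"constant"` when the test is undefined).
#' @export
normality_screen <- function(data, dvs, by = c("group", "condition")) {
  cells <- unique(data[, by, drop = FALSE])
  out <- list()
  for (dv in dvs) for (r in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(data))
    for (b in by) sel <- sel & data[[b]] == cells[r, b]
    x <- data[[dv]][sel]
    x <- x[!is.na(x)]
    row <- cbind(data.frame(dv = dv), cells[r, , drop = FALSE],
                 data.frame(n = length(x), W = NA_real_, p = NA_real_,
                            flag = ""))
    if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0) {
      sw <- shapiro.test(x)
      row$W <- unname(sw$statistic); row$p <- sw$p.value
    } else {
      row$flag <- if (length(x) >= 3 && sd(x) == 0) "constant" else "too_few"
    }
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out); rownames(out) <- NULL
  out
}

#' Levene test of variance homogeneity
#'
#' Levene statistic with mean centering (the classical form).
#'
#' @param dv Numeric response.
#' @param group Grouping factor (>= 2 groups, each with >= 2 values).
#' @return List: `statistic`, `df`, `p`.
#' @export
variance_homogeneity <- function(dv, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 values")
  lt <- car::leveneTest(dv ~ group, center = mean)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"])
}

#' Two-factor between-subject effects with partial eta squared
#'
#' For each dependent variable, fits the two-factor linear model with
#' interaction under effects (sum-to-zero) coding and Type-III sums of
#' squares, and reports per effect the F test and partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. Repeated trials are averaged to
#' one value per subject x condition by default (`"trial_mean"`); the
#' `"trial_as_replicate"` policy pools trials as rows instead.
#'
#' @param data `data.frame` with columns `subject_id`, the two factors, an
#'   optional `trial` column, and the dependent variables.
#' @param dvs Dependent-variable column names.
#' @param factors Two factor columns (default `c("group", "condition")`).
#' @param policy Trial handling policy.
#' @return `data.frame` of class `anova_table`: `dv`, `effect`, `SS`, `df`,
#'   `F`, `p`, `partial_eta_sq` (residual rows carry the error SS/df);
#'   attribute `"models"` holds the fitted `lm` objects for
#'   [estimated_marginal_means()].
#' @export
factorial_effects <- function(data, dvs, factors = c("group", "condition"),
                              policy = c("trial_mean", "trial_as_replicate")) {
  policy <- match.arg(policy)
  stopifnot(length(factors) == 2)
  f1 <- factors[1]; f2 <- factors[2]
  tab <- table(data[[f1]], data[[f2]])
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", f1,
                 rownames(tab)[empty[1]], f2, colnames(tab)[empty[2]]))
  }
  if (policy == "trial_mean" && "trial" %in% names(data)) {
    agg <- aggregate(data[dvs],
                     by = data[c("subject_id", f1, f2)],
                     FUN = mean, na.rm = TRUE)
  } else {
    agg <- data[, c("subject_id", f1, f2, dvs)]
  }
  n_per_cell <- table(unique(agg[c("subject_id", f1, f2)])[, c(f1, f2)])
  if (any(n_per_cell < 2)) stop("need at least 2 subjects per cell")
  agg[[f1]] <- factor(agg[[f1]]); agg[[f2]] <- factor(agg[[f2]])
  contr <- setNames(list("contr.sum", "contr.sum"), factors)
  out <- list(); models <- list()
  for (dv in dvs) {
    d <- agg[!is.na(agg[[dv]]), , drop = FALSE]
    fml <- as.formula(sprintf("`%s` ~ `%s` * `%s`", dv, f1, f2))
    fit <- lm(fml, data = d, contrasts = contr)
    a3 <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
    if (is.null(a3)) {
      # zero residual variance (e.g. a constant dv): report null effects
      effs <- c(f1, f2, paste0(f1, ":", f2))
      out[[dv]] <- rbind(
        data.frame(dv = dv, effect = effs, SS = 0, df = 1, F = 0, p = 1,
                   partial_eta_sq = 0),
        data.frame(dv = dv, effect = "Residuals", SS = 0,
                   df = fit$df.residual, F = NA_real_, p = NA_real_,
                   partial_eta_sq = NA_real_))
      models[[dv]] <- fit
      next
    }
    ss_err <- a3["Residuals", "Sum Sq"]
    effects <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
    rows <- lapply(effects, function(e) {
      ss <- a3[e, "Sum Sq"]
      degenerate <- ss < 1e-25 && ss_err < 1e-25   # dv without any variation
      data.frame(dv = dv, effect = gsub("`", "", e), SS = ss,
                 df = a3[e, "Df"],
                 F = if (degenerate) 0 else a3[e, "F value"],
                 p = if (degenerate) 1 else a3[e, "Pr(>F)"],
                 partial_eta_sq = if (degenerate) 0 else ss / (ss + ss_err))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      dv = dv, effect = "Residuals", SS = ss_err,
      df = a3["Residuals", "Df"], F = NA_real_, p = NA_real_,
      partial_eta_sq = NA_real_)
    out[[dv]] <- do.call(rbind, rows)
    models[[dv]] <- fit
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  attr(res, "models") <- models
  class(res) <- c("anova_table", class(res))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values `p_(i) <- min_(j>=i)(p_(j) * m / j)` capped at 1, with
#' rejection flags at level `q`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q False-discovery-rate level (default 0.05).
#' @return List: `adjusted`, `reject` (logical), `q`.
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q, q = q)
}

#' Backward-elimination multiple regression
#'
#' Ordinary least squares with iterated removal: at each step the predictor
#' with the largest partial-F p-value is dropped if that p-value is at or
#' above `removal_p`, until every retained predictor has p below
#' `removal_p` or none remain.
#'
#' @param y Response vector.
#' @param predictors `data.frame` or matrix of candidate predictors.
#' @param removal_p Probability-of-F-for-removal threshold (default 0.1).
#' @return Object of class `backward_reg`: `retained`, `coefficients`
#'   (estimate, se, t, p per term), `F`, `df`, `p`, `r_squared`, `trace`
#'   (`data.frame` of removals), `model` (the final `lm`).
#' @export
backward_regression <- function(y, predictors, removal_p = 0.1) {
  X <- as.data.frame(predictors)
  n <- length(y)
  if (n <= ncol(X) + 2) stop("need n > k + 2 observations")
  d <- cbind(data.frame(.y = y), X)
  d <- d[complete.cases(d), , drop = FALSE]
  mm <- model.matrix(~ ., data = d[, -1, drop = FALSE])
  if (qr(mm)$rank < ncol(mm)) {
    qq <- qr(mm)
    dropped <- colnames(mm)[qq$pivot[(qq$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  vars <- names(X)
  trace <- list(); step <- 0L
  repeat {
    fml <- if (length(vars))
      as.formula(paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + ")))
    else as.formula(".y ~ 1")
    fit <- lm(fml, data = d)
    if (!length(vars)) break
    st <- summary(fit)$coefficients
    pv <- st[-1, 4]   # partial-F p == t-test p for single-df terms
    names(pv) <- vars
    worst <- which.max(pv)
    if (pv[worst] >= removal_p) {
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, removed = vars[worst],
                                  p_at_removal = unname(pv[worst]))
      vars <- vars[-worst]
    } else break
  }
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  structure(list(
    retained = vars,
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              row.names = NULL),
    F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
    p = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared = sm$r.squared,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(), removed = character(),
                 p_at_removal = numeric()),
    model = fit), class = "backward_reg")
}

#' @export
print.backward_reg <- function(x, ...) {
  cat("<backward_reg>\n  retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(intercept only)",
      "\n")
  if (!is.na(x$F))
    cat(sprintf("  F(%g, %g) = %.3f, p = %.4g, R^2 = %.3f\n",
                x$df[1], x$df[2], x$F, x$p, x$r_squared))
  if (nrow(x$trace)) {
    cat("  removed:", paste(sprintf("%s (p=%.3f)", x$trace$removed,
                                    x$trace$p_at_removal), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Path model specification
#'
#' A recursive (acyclic) path model given as a set of directed arrows.
#'
#' @param arrows `data.frame` with columns `independent` and `dependent`
#'   (one row per arrow), or a list of `c(independent, dependent)` pairs.
#' @return Object of class `path_spec` with the arrows in topological
#'   order of their dependent variables.
#' @export
path_spec <- function(arrows) {
  if (is.list(arrows) && !is.data.frame(arrows))
    arrows <- do.call(rbind, lapply(arrows, function(a)
      data.frame(independent = a[1], dependent = a[2])))
  stopifnot(all(c("independent", "dependent") %in% names(arrows)))
  nodes <- unique(c(arrows$independent, arrows$dependent))
  # Kahn topological sort to reject cycles
  incoming <- lapply(setNames(nodes, nodes),
                     function(nd) arrows$independent[arrows$dependent == nd])
  sorted <- character(0); remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nd)
      all(incoming[[nd]] %in% sorted), logical(1))]
    if (!length(ready)) stop("path model specification is cyclic")
    sorted <- c(sorted, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(arrows = arrows, order = sorted), class = "path_spec")
}

#' Fit a recursive path model
#'
#' Estimates the model equation-wise: each endogenous (dependent) variable
#' is regressed by ordinary least squares on its parents. Reported per
#' arrow: the unstandardized estimate, its conventional OLS standard error,
#' the critical ratio `C.R. = Estimate / S.E.`, and the two-sided
#' standard-normal tail probability of the critical ratio (the convention
#' of path-analysis software).
#'
#' @param spec A [path_spec()].
#' @param data `data.frame` holding every model variable; complete cases
#'   only.
#' @return Object of class `path_fit`: `table` (`data.frame` with columns
#'   `dependent`, `independent`, `estimate`, `se`, `cr`, `p`), `n`,
#'   `r_squared` per equation, `models`.
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- unique(c(spec$arrows$independent, spec$arrows$dependent))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("data lacks model variables: ", paste(missing_vars, collapse = ", "))
  d <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  deps <- unique(spec$arrows$dependent)
  max_parents <- max(table(spec$arrows$dependent))
  if (nrow(d) < max_parents + 2)
    stop("too few complete cases for the largest equation")
  rows <- list(); models <- list(); r2 <- numeric(0)
  for (dep in deps) {
    parents <- spec$arrows$independent[spec$arrows$dependent == dep]
    fml <- as.formula(paste(sprintf("`%s`", dep), "~",
                            paste(sprintf("`%s`", parents), collapse = " + ")))
    fit <- lm(fml, data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    for (pv in parents) {
      idx <- if (sprintf("`%s`", pv) %in% rownames(co))
        sprintf("`%s`", pv) else pv
      est <- co[idx, 1]; se <- co[idx, 2]
      cr <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        dependent = dep, independent = pv, estimate = est, se = se,
        cr = cr, p = 2 * pnorm(-abs(cr)), row.names = NULL)
    }
    models[[dep]] <- fit
    r2[dep] <- sm$r.squared
    if (any(!is.finite(co[, 2])) || any(co[-1, 2] < 1e-12))
      warning(sprintf("degenerate equation for '%s': a parent explains it exactly", dep))
  }
  structure(list(table = do.call(rbind, rows), n = nrow(d),
                 r_squared = r2, models = models, estimator = "OLS"),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<path_fit> %d arrows, n = %d (equation-wise OLS)\n",
              nrow(x$table), x$n))
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$cr <- round(tab$cr, 2)
  tab$p <- signif(tab$p, 2)
  names(tab) <- c("Dependent var.", "Independent variable",
                  "Weight Estimate", "S.E.", "C.R.", "P")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Estimated marginal means
#'
#' Model-adjusted means per factor level (or factor combination) with
#' standard errors, from a fitted factorial model; the quantities plotted
#' in marginal-means figures.
#'
#' @param model A fitted `lm` (e.g. from the `"models"` attribute of
#'   [factorial_effects()]).
#' @param specs Factor name(s): one name for main-effect means, two for
#'   cell means.
#' @return `data.frame` with the factor level columns, `emmean`, `SE`,
#'   `df`, confidence bounds.
#' @export
estimated_marginal_means <- function(model, specs) {
  if (!inherits(model, "lm")) stop("model must be a fitted lm")
  em <- emmeans::emmeans(model, specs = specs)
  as.data.frame(em)
}
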