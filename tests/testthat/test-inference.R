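mk_factorial <- function(n_per_cell = 8, effects = c(g = 0, c = 0, gc = 0),
                         sd = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = seq_len(n_per_cell * 2),
                   condition = c("physical", "VR"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject_id <= n_per_cell, "expert", "novice")
  gg <- ifelse(d$group == "expert", 1, -1)
  cc <- ifelse(d$condition == "VR", 1, -1)
  d$dv <- effects["g"] * gg + effects["c"] * cc + effects["gc"] * gg * cc +
    rnorm(nrow(d), sd = sd)
  d
}

test_that("normality screen reports per-cell Shapiro-Wilk and flags constants", {
  d <- mk_factorial(10)
  out <- normality_screen(d, "dv")
  expect_equal(nrow(out), 4)
  expect_true(all(out$p > 0 & out$p < 1))
  d$flat <- 1
  out2 <- normality_screen(d, "flat")
  expect_true(all(out2$flag == "constant"))
})

test_that("skewed samples fail the normality screen", {
  set.seed(2)
  hits <- replicate(20, {
    d <- data.frame(group = "g", condition = "c", dv = rexp(50)^2)
    normality_screen(d, "dv")$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Levene test behaves at its boundaries", {
  x <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_lt(variance_homogeneity(x, g)$statistic, 1e-10)
  expect_error(variance_homogeneity(1:4, rep("a", 4)), "two groups")
  expect_error(variance_homogeneity(c(1, 2), c("a", "b")), "at least 2")
  set.seed(3)
  hits <- replicate(30, {
    y <- c(rnorm(50, sd = 1), rnorm(50, sd = 2))
    variance_homogeneity(y, rep(c("a", "b"), each = 50))$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("factorial effects: degenerate, power, and guard cases", {
  d <- mk_factorial(6)
  d$dv <- 1
  tab <- factorial_effects(d, "dv")
  eff <- tab[tab$effect != "Residuals", ]
  expect_equal(eff$F, rep(0, 3))
  expect_equal(eff$partial_eta_sq, rep(0, 3))
  # a pure skill effect is detected as the smallest p among the three effects
  set.seed(4)
  wins <- replicate(40, {
    d <- mk_factorial(8, effects = c(g = 1, c = 0, gc = 0),
                      seed = sample.int(1e6, 1))
    tab <- factorial_effects(d, "dv")
    eff <- tab[tab$effect != "Residuals", ]
    eff$effect[which.min(eff$p)] == "group"
  })
  expect_gte(mean(wins), 0.9)
  # empty cell guard
  d2 <- mk_factorial(4)
  d2 <- d2[!(d2$group == "expert" & d2$condition == "VR"), ]
  expect_error(factorial_effects(d2, "dv"), "empty design cell")
})

test_that("partial eta squared is recomputable from the SS columns", {
  d <- mk_factorial(7, effects = c(g = 0.6, c = 0.3, gc = 0.2), seed = 5)
  tab <- factorial_effects(d, "dv")
  ss_err <- tab$SS[tab$effect == "Residuals"]
  eff <- tab[tab$effect != "Residuals", ]
  expect_equal(eff$partial_eta_sq, eff$SS / (eff$SS + ss_err))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("trial means are taken before the factorial model by default", {
  d <- mk_factorial(4, seed = 6)
  d5 <- d[rep(seq_len(nrow(d)), each = 5), ]
  d5$trial <- rep(1:5, nrow(d))
  set.seed(7)
  d5$dv <- d5$dv + rnorm(nrow(d5), sd = 2)
  tm <- factorial_effects(d5, "dv", policy = "trial_mean")
  agg <- aggregate(dv ~ subject_id + group + condition, d5, mean)
  direct <- factorial_effects(agg, "dv")
  expect_equal(tm$F, direct$F)
  rep_mode <- factorial_effects(d5, "dv", policy = "trial_as_replicate")
  expect_gt(rep_mode$df[rep_mode$effect == "Residuals"],
            tm$df[tm$effect == "Residuals"])
})

test_that("BH adjustment equals the step-up definition and flags a prefix", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_equal(out$adjusted, rep(0.05, 5))
  expect_true(all(out$reject))
  expect_false(any(bh_adjust(rep(1, 6))$reject))
  one <- bh_adjust(0.04)
  expect_equal(one$adjusted, 0.04)
  expect_true(one$reject)
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    out <- bh_adjust(p)
    expect_equal(out$adjusted, oracle_bh(p))
    o <- order(p)
    expect_true(all(diff(out$adjusted[o]) >= -1e-12))       # monotone
    expect_true(all(diff(out$reject[o] * 1) <= 0))          # prefix property
  }
  expect_error(bh_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("backward elimination honors the removal threshold", {
  set.seed(9)
  n <- 120
  x1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = 0.5)
  X <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  fit <- backward_regression(y, X)
  expect_true("x1" %in% fit$retained)
  # removal_p = 1 keeps everything
  full <- backward_regression(y, X, removal_p = 1)
  expect_setequal(full$retained, c("x1", "x2", "x3"))
  # a single predictor at p ~ 0.05 stays below the 0.1 threshold
  repeat {
    xs <- rnorm(60); ys <- 0.3 * xs + rnorm(60)
    p <- summary(lm(ys ~ xs))$coefficients[2, 4]
    if (p > 0.03 && p < 0.09) break
  }
  kept <- backward_regression(ys, data.frame(x = xs))
  expect_equal(kept$retained, "x")
  # collinear designs are refused with the offending terms named
  X2 <- data.frame(a = x1, b = 2 * x1)
  expect_error(backward_regression(y, X2), "collinear")
  expect_error(backward_regression(y[1:4], X[1:4, ]), "n > k")
})

test_that("elimination trace records every removal in order", {
  set.seed(10)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 1.5 * X$x1 + rnorm(n, sd = 0.4)
  fit <- backward_regression(y, X)
  expect_true(all(fit$trace$p_at_removal >= 0.1))
  expect_false("x1" %in% fit$trace$removed)
  expect_equal(sort(c(fit$retained, fit$trace$removed)), c("x1", "x2", "x3"))
})

test_that("a single-equation path model equals plain OLS exactly", {
  set.seed(11)
  d <- data.frame(a = rnorm(40), b = rnorm(40))
  d$y <- 1 + 0.5 * d$a - 0.3 * d$b + rnorm(40, sd = 0.2)
  ps <- path_spec(data.frame(independent = c("a", "b"), dependent = "y"))
  fit <- fit_path_model(ps, d)
  ols <- summary(lm(y ~ a + b, d))$coefficients
  expect_equal(fit$table$estimate, unname(ols[c("a", "b"), 1]))
  expect_equal(fit$table$se, unname(ols[c("a", "b"), 2]))
  expect_equal(fit$table$cr, unname(ols[c("a", "b"), 3]))
  expect_equal(fit$table$p, unname(2 * pnorm(-abs(ols[c("a", "b"), 3]))))
})

test_that("cyclic path specifications are rejected; degenerate fits flagged", {
  expect_error(path_spec(data.frame(independent = c("a", "b"),
                                    dependent = c("b", "a"))), "cyclic")
  d <- data.frame(x = rnorm(30))
  d$m <- d$x                     # mediator equals its parent exactly
  ps <- path_spec(data.frame(independent = "x", dependent = "m"))
  w <- capture_warnings(fit <- fit_path_model(ps, d))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(fit$table$estimate, 1, tolerance = 1e-10)
})

test_that("path-model estimates recover a known recursive system", {
  set.seed(12)
  ok <- replicate(20, {
    n <- 500
    g <- sample(c(-1, 1), n, replace = TRUE)
    s <- sample(c(-1, 1), n, replace = TRUE)
    m1 <- 0.4 * g - 0.2 * s + rnorm(n)
    m2 <- -0.3 * g + 0.1 * s + rnorm(n)
    y <- 2 * m1 - 1 * m2 + rnorm(n)
    d <- data.frame(g = g, s = s, m1 = m1, m2 = m2, y = y)
    ps <- path_spec(rbind(
      expand.grid(independent = c("g", "s"), dependent = c("m1", "m2"),
                  stringsAsFactors = FALSE),
      data.frame(independent = c("m1", "m2"), dependent = "y")))
    fit <- fit_path_model(ps, d)
    key <- paste(fit$table$dependent, fit$table$independent)
    truth_map <- c("m1 g" = 0.4, "m1 s" = -0.2, "m2 g" = -0.3, "m2 s" = 0.1,
                   "y m1" = 2, "y m2" = -1)
    abs(fit$table$estimate - truth_map[key]) <= 2 * fit$table$se
  })
  # pooled per-arrow 2-S.E. coverage (the calibrated ~95% statement)
  expect_gte(mean(ok), 0.9)
})

test_that("estimated marginal means reduce to raw means in balanced designs", {
  d <- mk_factorial(6, effects = c(g = 1, c = 0.5, gc = 0), seed = 13)
  tab <- factorial_effects(d, "dv")
  m <- attr(tab, "models")$dv
  em <- estimated_marginal_means(m, "group")
  raw <- tapply(d$dv, d$group, mean)
  expect_equal(em$emmean, as.numeric(raw[as.character(em$group)]),
               tolerance = 1e-10)
  # unbalanced 2x2 toy: LS means are means of cell means
  d2 <- d[-c(1, 2, 3), ]
  tab2 <- factorial_effects(d2, "dv")
  em2 <- estimated_marginal_means(attr(tab2, "models")$dv, "group")
  cellm <- aggregate(dv ~ group + condition, d2, mean)
  byg <- tapply(cellm$dv, cellm$group, mean)
  expect_equal(em2$emmean, as.numeric(byg[as.character(em2$group)]),
               tolerance = 1e-8)
})
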