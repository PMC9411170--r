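# Trial-to-trial variability: coefficients of variation of edge values and
# behavior scores across the repeated trials of each subject x condition.

#' Coefficient of variation across trials
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Defined
#' only for at least two values with a mean bounded away from zero.
#'
#' @param values Numeric vector of trial measurements.
#' @param mean_tol Smallest admissible `|mean|` (default 1e-12).
#' @return Dimensionless scalar; `NA` with attribute `"reason"` when the
#'   mean is ~0 (flagged, excluded downstream).
#' @export
trial_cov <- function(values, mean_tol = 1e-12) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CoV needs at least 2 trial values")
  m <- mean(values)
  if (abs(m) <= mean_tol) {
    out <- NA_real_
    attr(out, "reason") <- "mean ~ 0; CoV undefined"
    return(out)
  }
  sd(values) / m
}

#' Build the per-subject CoV table
#'
#' One row per subject x condition: the CoV across trials of each directed
#' edge and of the behavior score. Edges with any invalid trial value are
#' masked (CoV computed on the remaining trials when at least 2 are valid,
#' and flagged).
#'
#' @param edge_table Long-format edge table from [network_edge_table()],
#'   with columns `subject_id`, `group`, `condition`, `trial`, `source_roi`,
#'   `target_roi`, `gc_value`, `valid`, and `score`.
#' @return Object of class `cov_table`: a `data.frame` with `subject_id`,
#'   `group`, `condition`, one `cov_<edge>` column per directed edge,
#'   `cov_score`, and attribute `"masked"` listing (row, edge) pairs that
#'   used fewer trials than expected.
#' @export
build_cov_table <- function(edge_table) {
  need <- c("subject_id", "group", "condition", "trial", "source_roi",
            "target_roi", "gc_value", "valid")
  missing_cols <- setdiff(need, names(edge_table))
  if (length(missing_cols))
    stop("edge table lacks columns: ", paste(missing_cols, collapse = ", "))
  edge_table$edge <- edge_name(edge_table$source_roi, edge_table$target_roi)
  edges <- unique(edge_table$edge)
  keys <- unique(edge_table[, c("subject_id", "group", "condition")])
  rownames(keys) <- NULL
  masked <- list()
  cov_cols <- matrix(NA_real_, nrow(keys), length(edges),
                     dimnames = list(NULL, paste0("cov_", edges)))
  cov_score <- rep(NA_real_, nrow(keys))
  for (r in seq_len(nrow(keys))) {
    sel <- edge_table$subject_id == keys$subject_id[r] &
      edge_table$condition == keys$condition[r]
    sub <- edge_table[sel, , drop = FALSE]
    n_trials <- length(unique(sub$trial))
    for (e in edges) {
      se <- sub[sub$edge == e, , drop = FALSE]
      vals <- se$gc_value[se$valid]
      if (length(vals) < 2) next
      if (length(vals) < n_trials)
        masked[[length(masked) + 1L]] <- data.frame(
          row = r, edge = e, n_used = length(vals))
      cov_cols[r, paste0("cov_", e)] <- trial_cov(vals)
    }
    if ("score" %in% names(sub)) {
      sc <- sub$score[!duplicated(sub$trial)]
      if (length(sc) >= 2 && !anyNA(sc)) cov_score[r] <- trial_cov(sc)
    }
  }
  out <- cbind(keys, as.data.frame(cov_cols), cov_score = cov_score)
  attr(out, "masked") <- if (length(masked)) do.call(rbind, masked) else NULL
  class(out) <- c("cov_table", class(out))
  out
}
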