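# Two-stage calibration: fit all indicators, apply the retention
# filter, refit the survivors, and assemble the calibration report.

#' Per-indicator outcome correlations
#'
#' Correlation (Pearson on the categorical scores, i.e. the phi
#' coefficient for dichotomous pairs) between each procedural indicator
#' and the task-outcome indicator of its task.  Outcome indicators are
#' exempt (`NA`), as are indicators of tasks with no outcome indicator.
#'
#' @param scores a `"cps_scores"` object whose metadata carries
#'   `rule_type` (outcome indicators have `rule_type == "outcome"`).
#' @return named numeric vector, `NA` where the criterion does not
#'   apply.
#' @export
outcome_correlations <- function(scores) {
  meta <- scores$meta
  m <- scores$scores
  out <- stats::setNames(rep(NA_real_, nrow(meta)), meta$name)
  if (is.null(meta$rule_type) || all(is.na(meta$rule_type))) return(out)
  task <- sub("^(T[0-9]+).*$", "\\1", meta$name)
  for (j in seq_len(nrow(meta))) {
    if (identical(meta$rule_type[j], "outcome")) next
    oc <- which(task == task[j] & meta$rule_type == "outcome")
    if (length(oc) != 1) next
    x <- m[, j]; y <- m[, oc]
    ok <- !(is.na(x) | is.na(y))
    if (sum(ok) > 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      out[j] <- stats::cor(x[ok], y[ok])
  }
  out
}

#' Two-stage calibration of a dyad CPS assessment
#'
#' Stage 1 calibrates every indicator with the two-dimensional Rasch
#' model and computes the indicator quality statistics (CTT
#' discrimination, difficulty with SE, infit MNSQ with its null
#' interval and T, outcome correlation).  Indicators with MNSQ outside
#' `[0.77, 1.33]`, negative discrimination, or negative outcome
#' correlation are excluded; stage 2 refits the survivors and those
#' estimates are the ones used for ability estimation.  Degenerate
#' indicators (fewer than two observed categories) are dropped with a
#' warning before stage 1.
#'
#' @param scores a `"cps_scores"` object (or a score matrix plus
#'   `meta`).
#' @param meta per-indicator metadata when `scores` is a bare matrix.
#' @param two_stage apply the retention filter and refit (`FALSE` stops
#'   after stage 1).
#' @param nodes,max_iter,tol passed to [fit_mml_em()].
#' @param mnsq_range retention band for the infit MNSQ.
#' @return an object of class `"cps_calibration"`: `stage1` and
#'   `stage2` fits, `fit_records` (Table-style per-indicator data
#'   frame), `retention` (kept/dropped), `abilities`, and `report`
#'   (deviance, separation reliability, per-dimension EAP reliability,
#'   dimension correlation, sample size).
#' @export
calibrate <- function(scores, meta = NULL, two_stage = TRUE, nodes = 31,
                      max_iter = 500, tol = 1e-4,
                      mnsq_range = c(0.77, 1.33)) {
  if (!inherits(scores, "cps_scores")) {
    if (is.null(meta)) stop("meta is required when scores is a matrix")
    scores <- structure(list(raw = scores, scores = as.matrix(scores),
                             meta = meta), class = "cps_scores")
  }
  meta <- scores$meta[!is.na(scores$meta$K), , drop = FALSE]
  m <- scores$scores[, meta$name, drop = FALSE]
  n_cat <- apply(m, 2, function(x) length(unique(x[!is.na(x)])))
  if (any(n_cat < 2)) {
    warning("dropping degenerate indicator(s) before calibration: ",
            paste(meta$name[n_cat < 2], collapse = ", "))
    meta <- meta[n_cat >= 2, , drop = FALSE]
    m <- m[, meta$name, drop = FALSE]
  }
  model1 <- build_matrices(meta)
  fit1 <- fit_mml_em(m, model1, nodes = nodes, max_iter = max_iter,
                     tol = tol)
  ab1 <- estimate_abilities_eap(m, fit1)
  infit1 <- infit_mnsq(m, fit1, ab1)
  disc <- ctt_discrimination(m, meta)
  ocor <- outcome_correlations(
    structure(list(scores = m, meta = meta), class = "cps_scores"))
  steps <- split_delta(model1, fit1$delta)
  ses <- split_delta(model1, fit1$se)
  fit_records <- data.frame(
    name = meta$name,
    discrimination = unname(disc[meta$name]),
    difficulty = vapply(steps, mean, numeric(1)),
    error = vapply(ses, mean, numeric(1)),
    mnsq = infit1$mnsq, ci_low = infit1$ci_low, ci_high = infit1$ci_high,
    t = infit1$t, outcome_cor = unname(ocor[meta$name]),
    stringsAsFactors = FALSE)
  retention <- retention_filter(fit_records, mnsq_range)
  if (two_stage && length(retention$kept) &&
      nrow(retention$dropped) > 0) {
    meta2 <- meta[meta$name %in% retention$kept, , drop = FALSE]
    model2 <- build_matrices(meta2)
    fit2 <- fit_mml_em(m[, meta2$name, drop = FALSE], model2,
                       nodes = nodes, max_iter = max_iter, tol = tol)
    ab2 <- estimate_abilities_eap(m[, meta2$name, drop = FALSE], fit2)
  } else {
    fit2 <- fit1
    ab2 <- ab1
  }
  steps2 <- split_delta(fit2$model, fit2$delta)
  ses2 <- split_delta(fit2$model, fit2$se)
  report <- data.frame(
    n_dyads = fit2$n_dyads,
    deviance = fit2$deviance,
    separation_reliability = item_separation_reliability(
      vapply(steps2, mean, numeric(1)), vapply(ses2, mean, numeric(1))),
    reliability_dim1 = eap_reliability(ab2, 1),
    reliability_dim2 = eap_reliability(ab2, 2),
    dimension_correlation = dimension_correlation(ab2))
  structure(list(stage1 = fit1, stage2 = fit2, fit_records = fit_records,
                 retention = retention, abilities = ab2, report = report,
                 two_stage = two_stage),
            class = "cps_calibration")
}

#' @export
print.cps_calibration <- function(x, ...) {
  cat("<cps_calibration>\n")
  cat(sprintf("  stage 1: %d indicators; dropped %d (%s)\n",
              nrow(x$fit_records), nrow(x$retention$dropped),
              if (nrow(x$retention$dropped))
                paste(x$retention$dropped$name, collapse = ", ")
              else "none"))
  cat(sprintf("  stage 2: %d indicators, deviance %.3f\n",
              nrow(x$stage2$model$meta), x$report$deviance))
  cat(sprintf(paste0("  separation reliability %.3f; EAP reliability ",
                     "%.3f / %.3f; dimension correlation %.3f\n"),
              x$report$separation_reliability, x$report$reliability_dim1,
              x$report$reliability_dim2, x$report$dimension_correlation))
  invisible(x)
}
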