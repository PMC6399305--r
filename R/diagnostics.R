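# Indicator- and test-level quality statistics: CTT discrimination,
# infit mean squares with confidence intervals and T values, separation
# and EAP reliabilities, dimension correlation, the retention filter,
# Cohen's kappa agreement, and Wright-map data.

#' Corrected point-biserial discrimination (CTT)
#'
#' Correlation between an indicator's score and the rest-score total of
#' all indicators sharing its dimension, the indicator itself excluded.
#' A- and B-indicators total over their own dimension's indicators plus
#' the group indicators; group indicators correlate against the dyad
#' total.
#'
#' @param scores dyads x indicators matrix (or `"cps_scores"`).
#' @param meta per-indicator data frame with `name` and `level`
#'   (`"A"`, `"B"`, `"G"`); taken from the object when `scores` is a
#'   `"cps_scores"`.
#' @param indicator name of one indicator, or `NULL` for all.
#' @return named numeric vector of discriminations (`NA` with a warning
#'   where the indicator or rest-score has zero variance).
#' @export
ctt_discrimination <- function(scores, meta = NULL, indicator = NULL) {
  if (inherits(scores, "cps_scores")) {
    meta <- scores$meta; scores <- scores$scores
  }
  scores <- as.matrix(scores)
  meta <- meta[match(colnames(scores), meta$name), , drop = FALSE]
  which_ind <- if (is.null(indicator)) colnames(scores) else indicator
  out <- stats::setNames(rep(NA_real_, length(which_ind)), which_ind)
  for (nm in which_ind) {
    j <- match(nm, colnames(scores))
    lev <- meta$level[j]
    share <- if (lev == "G") rep(TRUE, ncol(scores)) else
      meta$level %in% c(lev, "G")
    share[j] <- FALSE
    if (!any(share)) { warning("no rest-score items for ", nm); next }
    rest <- rowSums(scores[, share, drop = FALSE], na.rm = TRUE)
    x <- scores[, j]
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0 || stats::sd(rest[ok]) == 0) {
      warning("zero variance: discrimination undefined for ", nm)
      next
    }
    out[nm] <- stats::cor(x[ok], rest[ok])
  }
  out
}

# model-implied conditional moments of each indicator at given theta:
# E (mean), W (variance), C4 (fourth central moment); each N x I.
item_moments <- function(fit, theta_mat) {
  steps <- split_delta(fit$model, fit$delta)
  I <- nrow(fit$model$meta)
  N <- nrow(theta_mat)
  E <- W <- C4 <- matrix(NA_real_, N, I,
                         dimnames = list(NULL, fit$model$meta$name))
  for (i in seq_len(I)) {
    P <- exp(item_logprob(theta_mat, fit$model$meta$level[i], steps[[i]]))
    k <- 0:(fit$model$meta$K[i] - 1L)
    Ei <- colSums(P * k)
    E[, i] <- Ei
    W[, i] <- colSums(P * k^2) - Ei^2
    C4[, i] <- colSums(P * outer(k, Ei, "-")^4)
  }
  list(E = E, W = W, C4 = C4)
}

#' Information-weighted mean-square fit (infit MNSQ)
#'
#' For each indicator, the ratio of summed squared residuals to summed
#' model variances, with expectations and variances evaluated at each
#' dyad's EAP ability estimate; missing cells are excluded from both
#' sums.  MNSQ is 1 under model fit, above 1 for underfitting
#' (noisier-than-expected) indicators, below 1 for overfitting ones.
#' Also returns the fit variance `q` (from the model-implied variance
#' of the squared standardized residuals, using the conditional fourth
#' moment), the null 95% interval `1 +/- 1.96 sqrt(q)` and the
#' Wilson-Hilferty standardized `T`.
#'
#' @param scores dyads x indicators score matrix (or `"cps_scores"`).
#' @param fit a `"dyad_fit"`.
#' @param abilities a `"dyad_abilities"` data frame; recomputed when
#'   `NULL`.
#' @return data frame with columns `name`, `mnsq`, `q`, `ci_low`,
#'   `ci_high`, `t`, `n_obs`.
#' @export
infit_mnsq <- function(scores, fit, abilities = NULL) {
  if (inherits(scores, "cps_scores")) scores <- scores$scores
  scores <- as.matrix(scores)[, fit$model$meta$name, drop = FALSE]
  if (is.null(abilities)) abilities <- estimate_abilities_eap(scores, fit)
  th <- as.matrix(abilities[, c("theta_A", "theta_B")])
  mom <- item_moments(fit, th)
  I <- ncol(scores)
  out <- data.frame(name = colnames(scores), mnsq = NA_real_, q = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, t = NA_real_,
                    n_obs = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(I)) {
    obs <- !is.na(scores[, i])
    out$n_obs[i] <- sum(obs)
    if (!any(obs)) next
    res2 <- (scores[obs, i] - mom$E[obs, i])^2
    Wi <- mom$W[obs, i]
    out$mnsq[i] <- sum(res2) / sum(Wi)
    q <- sum(mom$C4[obs, i] - Wi^2) / sum(Wi)^2
    out$q[i] <- max(q, 1e-12)
    it <- mnsq_interval_t(out$mnsq[i], out$q[i])
    out$ci_low[i] <- it[["ci_low"]]
    out$ci_high[i] <- it[["ci_high"]]
    out$t[i] <- it[["t"]]
  }
  out
}

#' Null confidence interval and standardized T for an MNSQ
#'
#' The 95% interval for an MNSQ of 1 is `1 +/- 1.96 sqrt(q)` (floored
#' at 0); the standardized fit statistic uses the Wilson-Hilferty
#' cube-root transformation
#' `T = (MNSQ^(1/3) - 1) * 3 / sqrt(q) + sqrt(q) / 3`.
#'
#' @param mnsq an infit mean square (> 0).
#' @param q its sampling variance under the model (> 0).
#' @return named numeric vector `ci_low`, `ci_high`, `t`.
#' @export
mnsq_interval_t <- function(mnsq, q) {
  if (!is.finite(q) || q <= 0) stop("fit variance q must be positive")
  c(ci_low = max(0, 1 - 1.96 * sqrt(q)), ci_high = 1 + 1.96 * sqrt(q),
    t = (mnsq^(1 / 3) - 1) * 3 / sqrt(q) + sqrt(q) / 3)
}

#' Item separation reliability
#'
#' The proportion of observed difficulty-estimate variance not
#' attributable to estimation error:
#' `(var(difficulties) - mean(SE^2)) / var(difficulties)`, truncated to
#' `[0, 1]`.
#'
#' @param difficulties numeric vector of difficulty estimates (logits).
#' @param ses their standard errors.
#' @return reliability in `[0, 1]`.
#' @export
item_separation_reliability <- function(difficulties, ses) {
  ok <- is.finite(difficulties) & is.finite(ses)
  if (sum(ok) < 2) stop("need at least 2 difficulties with finite SEs")
  v <- stats::var(difficulties[ok])
  if (v == 0) { warning("zero variance in difficulties"); return(0) }
  min(1, max(0, (v - mean(ses[ok]^2)) / v))
}

#' EAP reliability of one latent dimension
#'
#' `var(EAP estimates) / (var(EAP estimates) + mean posterior
#' variance)`: the degree of person separation on the dimension.
#'
#' @param abilities a `"dyad_abilities"` data frame.
#' @param dimension 1 (member A) or 2 (member B).
#' @return reliability in `[0, 1]`.
#' @export
eap_reliability <- function(abilities, dimension = 1) {
  stopifnot(dimension %in% c(1, 2))
  th <- abilities[[c("theta_A", "theta_B")[dimension]]]
  psd <- abilities[[c("sd_A", "sd_B")[dimension]]]
  if (length(th) < 2) stop("need at least 2 dyads")
  v <- stats::var(th)
  if (v == 0) { warning("zero variance in EAP estimates"); return(0) }
  v / (v + mean(psd^2))
}

#' Correlation between the two dyad-member dimensions
#'
#' Pearson correlation of the EAP ability estimates of members A and B
#' across dyads; quantifies the dependence between dyad partners.
#'
#' @param abilities a `"dyad_abilities"` data frame.
#' @return correlation in `[-1, 1]` (`NA` with a warning if either
#'   dimension has zero variance).
#' @export
dimension_correlation <- function(abilities) {
  if (nrow(abilities) < 3) stop("need at least 3 dyads")
  if (stats::sd(abilities$theta_A) == 0 || stats::sd(abilities$theta_B) == 0) {
    warning("zero variance in an ability dimension; correlation undefined")
    return(NA_real_)
  }
  stats::cor(abilities$theta_A, abilities$theta_B)
}

#' Retention filter for calibrated indicators
#'
#' An indicator is excluded when its infit MNSQ falls outside
#' `[0.77, 1.33]`, its CTT discrimination is below zero, or its
#' correlation with the task outcome is below zero.  Outcome indicators
#' themselves are exempt from the outcome-correlation criterion (pass
#' `NA` for them); `NA` statistics never trigger a drop.
#'
#' @param fit_records data frame with columns `name`, `mnsq`,
#'   `discrimination`, `outcome_cor`.
#' @param mnsq_range acceptance band for MNSQ.
#' @return list with `kept` (character vector) and `dropped` (data
#'   frame `name`, `reason`).
#' @export
retention_filter <- function(fit_records, mnsq_range = c(0.77, 1.33)) {
  reasons <- lapply(seq_len(nrow(fit_records)), function(i) {
    r <- fit_records[i, ]
    msg <- character()
    if (!is.na(r$mnsq) && (r$mnsq < mnsq_range[1] || r$mnsq > mnsq_range[2]))
      msg <- c(msg, sprintf("MNSQ %.3f out of [%.2f, %.2f]", r$mnsq,
                            mnsq_range[1], mnsq_range[2]))
    if (!is.na(r$discrimination) && r$discrimination < 0)
      msg <- c(msg, sprintf("discrimination %.3f below zero",
                            r$discrimination))
    if (!is.na(r$outcome_cor) && r$outcome_cor < 0)
      msg <- c(msg, sprintf("outcome correlation %.3f below zero",
                            r$outcome_cor))
    msg
  })
  drop <- lengths(reasons) > 0
  list(kept = fit_records$name[!drop],
       dropped = data.frame(name = fit_records$name[drop],
                            reason = vapply(reasons[drop], paste,
                                            character(1), collapse = "; "),
                            stringsAsFactors = FALSE))
}

#' Cohen's kappa between two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement, plus the conventional magnitude
#' label: excellent above 0.75, fair to good between 0.4 and 0.75, poor
#' below 0.4.
#'
#' @param x,y paired categorical vectors (e.g. program scores and human
#'   ratings).
#' @return list with `kappa`, `magnitude`, `p_obs`, `p_exp`.
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y)) stop("ratings must be paired (equal length)")
  ok <- !(is.na(x) | is.na(y))
  x <- factor(x[ok]); y <- factor(y[ok])
  lev <- union(levels(x), levels(y))
  if (length(lev) < 2) {
    warning("fewer than 2 categories observed; kappa undefined")
    return(list(kappa = NA_real_, magnitude = NA_character_,
                p_obs = NA_real_, p_exp = NA_real_))
  }
  x <- factor(x, lev); y <- factor(y, lev)
  tab <- table(x, y) / length(x)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    warning("chance agreement is 1 (both raters constant); kappa undefined")
    return(list(kappa = NA_real_, magnitude = NA_character_,
                p_obs = p_o, p_exp = p_e))
  }
  k <- (p_o - p_e) / (1 - p_e)
  list(kappa = k, magnitude = kappa_magnitude(k), p_obs = p_o, p_exp = p_e)
}

#' @rdname cohens_kappa
#' @param kappa a kappa value.
#' @export
kappa_magnitude <- function(kappa) {
  ifelse(is.na(kappa), NA_character_,
         ifelse(kappa > 0.75, "excellent",
                ifelse(kappa >= 0.4, "fair to good", "poor")))
}

#' Wright map: abilities and difficulties on the common logit scale
#'
#' Histograms the EAP abilities of each dimension into logit bins and
#' places each indicator at its difficulty on the same scale, flagging
#' indicators easier than the lowest observed ability.
#'
#' @param fit a `"dyad_fit"` (per-indicator difficulty = mean of its
#'   step parameters).
#' @param abilities a `"dyad_abilities"` data frame.
#' @param bin_width bin width in logits.
#' @return list of class `"wright_map"`: `bins` (data frame `dimension`,
#'   `mid`, `count`), `items` (data frame `name`, `difficulty`,
#'   `below_all_abilities`), `bin_width`.
#' @export
wright_map <- function(fit, abilities, bin_width = 0.25) {
  steps <- split_delta(fit$model, fit$delta)
  diffs <- vapply(steps, mean, numeric(1))
  items <- data.frame(name = fit$model$meta$name, difficulty = diffs,
                      stringsAsFactors = FALSE)
  th <- c(abilities$theta_A, abilities$theta_B)
  lo <- floor(min(th, diffs) / bin_width) * bin_width
  hi <- ceiling(max(th, diffs) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bins <- do.call(rbind, lapply(1:2, function(d) {
    x <- abilities[[c("theta_A", "theta_B")[d]]]
    h <- hist(x, breaks = breaks, plot = FALSE)
    data.frame(dimension = d, mid = h$mids, count = h$counts)
  }))
  items$below_all_abilities <- items$difficulty < min(th)
  structure(list(bins = bins, items = items, bin_width = bin_width),
            class = "wright_map")
}

#' @export
print.wright_map <- function(x, ...) {
  mids <- sort(unique(x$bins$mid), decreasing = TRUE)
  c1 <- x$bins[x$bins$dimension == 1, ]
  c2 <- x$bins[x$bins$dimension == 2, ]
  cat(sprintf("%8s | %-12s | %-12s | indicators\n", "logit", "dim 1 (A)",
              "dim 2 (B)"))
  for (m in mids) {
    n1 <- c1$count[match(m, c1$mid)]
    n2 <- c2$count[match(m, c2$mid)]
    in_bin <- x$items$name[abs(x$items$difficulty - m) <= x$bin_width / 2]
    cat(sprintf("%8.2f | %-12s | %-12s | %s\n", m,
                strrep("X", min(n1, 12L)), strrep("X", min(n2, 12L)),
                paste(in_bin, collapse = " ")))
  }
  flagged <- x$items$name[x$items$below_all_abilities]
  if (length(flagged))
    cat("below all abilities:", paste(flagged, collapse = " "), "\n")
  invisible(x)
}
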