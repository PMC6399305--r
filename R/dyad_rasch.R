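# Within-item two-dimensional Rasch model for dyad data.
#
# The two dyad members are two correlated latent dimensions
# theta = (theta_A, theta_B).  Individual indicators load on one
# dimension; group indicators load on both (within-item
# multidimensionality).  The model is the multidimensional random
# coefficients multinomial logit model (MRCMLM):
#
#   P(X_ik = 1 | theta) = exp(b_ik' theta + a_ik' xi) /
#                         sum_k' exp(b_ik'' theta + a_ik'' xi)
#
# with scoring rows b_ik = (k, 0), (0, k) or (k, k) for A-, B- and
# group indicators, and a partial-credit design matrix A assigning
# category k the coefficient -1 on each of the first k step parameters
# of its indicator (larger xi = harder).  Estimation is marginal
# maximum likelihood by EM over a bivariate-normal population with mean
# fixed at (0, 0) for identification and free covariance Sigma,
# integrated on a Cholesky-rotated tensor Gauss-Hermite grid.

#' Build the design and scoring matrices for a dyad model
#'
#' Each indicator contributes `K_i` category rows (category 0 is
#' all-zero in both matrices) and `K_i - 1` free difficulty/step
#' parameter columns.  A dichotomous A-indicator and a trichotomous
#' B-indicator therefore produce a 5-row design matrix — rows 1–2 for
#' the first indicator and 3–5 for the second — with 3 parameter
#' columns.
#'
#' @param meta a data frame with columns `name`, `level` (`"A"`, `"B"`
#'   or `"G"`) and `K` (category count, >= 2), e.g. the `meta` element
#'   of a `"cps_scores"` object (count columns without categories are
#'   dropped with a message).
#' @return an object of class `"dyad_model"`: list with `meta`, the
#'   design matrix `A` (sum K_i rows x sum (K_i - 1) columns), the
#'   scoring matrix `B` (same rows x 2 dimension columns), `row_item`
#'   (indicator index per row), `row_cat` (category per row) and
#'   `par_names`.
#' @export
build_matrices <- function(meta) {
  stopifnot(all(c("name", "level", "K") %in% names(meta)))
  drop <- is.na(meta$K)
  if (any(drop)) {
    message("dropping ", sum(drop),
            " unconverted count indicator(s) from the model: ",
            paste(meta$name[drop], collapse = ", "))
    meta <- meta[!drop, , drop = FALSE]
  }
  if (!nrow(meta)) stop("no categorical indicators to model")
  if (any(meta$K < 2))
    stop("indicator(s) with K < 2: ",
         paste(meta$name[meta$K < 2], collapse = ", "))
  if (!all(meta$level %in% c("A", "B", "G")))
    stop("indicator level must be 'A', 'B' or 'G'")
  K <- as.integer(meta$K)
  n_rows <- sum(K)
  n_par <- sum(K - 1L)
  A <- matrix(0, n_rows, n_par)
  B <- matrix(0, n_rows, 2, dimnames = list(NULL, c("theta_A", "theta_B")))
  row_item <- integer(n_rows); row_cat <- integer(n_rows)
  par_names <- character(n_par)
  r <- 0L; p <- 0L
  for (i in seq_len(nrow(meta))) {
    cols <- p + seq_len(K[i] - 1L)
    par_names[cols] <- if (K[i] == 2L) meta$name[i] else
      paste0(meta$name[i], "_s", seq_len(K[i] - 1L))
    for (k in 0:(K[i] - 1L)) {
      r <- r + 1L
      row_item[r] <- i; row_cat[r] <- k
      if (k > 0) A[r, p + seq_len(k)] <- -1
      B[r, ] <- switch(meta$level[i], A = c(k, 0), B = c(0, k), G = c(k, k))
    }
    p <- p + K[i] - 1L
  }
  colnames(A) <- par_names
  if (qr(A)$rank < n_par) stop("design matrix is column-rank deficient")
  structure(list(meta = meta, A = A, B = B, row_item = row_item,
                 row_cat = row_cat, par_names = par_names),
            class = "dyad_model")
}

#' @export
print.dyad_model <- function(x, ...) {
  cat(sprintf(paste0("<dyad_model> %d indicators (%d A / %d B / %d group), ",
                     "%d category rows, %d parameters\n"),
              nrow(x$meta), sum(x$meta$level == "A"),
              sum(x$meta$level == "B"), sum(x$meta$level == "G"),
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

# split a stacked parameter vector into per-item step vectors
split_delta <- function(model, delta) {
  K <- model$meta$K
  idx <- rep(seq_along(K), K - 1L)
  lapply(seq_along(K), function(i) delta[idx == i])
}

# fast row maxima (avoids apply() overhead on large matrices)
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# K x Q matrix of log category probabilities for one indicator at a
# Q x 2 matrix of latent points; `steps` is the K-1 step vector.
item_logprob <- function(theta, level, steps) {
  K <- length(steps) + 1L
  u <- switch(level, A = theta[, 1], B = theta[, 2],
              G = theta[, 1] + theta[, 2])
  # logits: category k scores k on its dimension(s), minus cumulative steps
  lp <- outer(0:(K - 1L), u) - c(0, cumsum(steps))
  lp <- sweep(lp, 2, row_max(t(lp)))
  sweep(lp, 2, log(colSums(exp(lp))))
}

# (K-1) x Q upper-tail probabilities P(category >= j), j = 1..K-1
cum_tail <- function(P) {
  K <- nrow(P)
  tri <- outer(seq_len(K - 1L), 0:(K - 1L), function(j, k) (k >= j) + 0)
  tri %*% P
}

# stacked (sum K_i) x Q log-probability matrix over all indicators
stack_logprob <- function(model, delta, theta) {
  steps <- split_delta(model, delta)
  do.call(rbind, lapply(seq_len(nrow(model$meta)), function(i)
    item_logprob(theta, model$meta$level[i], steps[[i]])))
}

# N x (sum K_i) category-membership indicator matrix (missing = all 0)
make_ystack <- function(scores, model) {
  K <- model$meta$K
  offs <- cumsum(c(0L, K))
  Y <- matrix(0, nrow(scores), sum(K))
  for (i in seq_len(ncol(scores))) {
    obs <- which(!is.na(scores[, i]))
    Y[cbind(obs, offs[i] + scores[obs, i] + 1L)] <- 1
  }
  Y
}

#' Category response probabilities
#'
#' Evaluates the MRCMLM category probabilities for one indicator at one
#' ability pair, with max-subtraction for overflow safety.  For a
#' dichotomous indicator this reduces to
#' `P(1) = plogis(theta_d - delta)` for an individual indicator on
#' dimension d and `P(1) = plogis(theta_A + theta_B - delta)` for a
#' group indicator.
#'
#' @param theta numeric ability pair `c(theta_A, theta_B)`.
#' @param level `"A"`, `"B"` or `"G"`.
#' @param steps numeric vector of the indicator's `K - 1` step
#'   parameters (a single difficulty when dichotomous).
#' @return numeric probability vector of length `K` (sums to 1).
#' @export
category_probabilities <- function(theta, level, steps) {
  stopifnot(length(theta) == 2, all(is.finite(theta)), all(is.finite(steps)))
  level <- match.arg(level, c("A", "B", "G"))
  drop(exp(item_logprob(matrix(theta, 1, 2), level, steps)))
}

#' Gauss-Hermite grid for a bivariate normal
#'
#' Tensor product of `nodes` Gauss-Hermite points per dimension,
#' rescaled to a standard normal and rotated by the Cholesky factor of
#' `Sigma` (mean fixed at zero).
#'
#' @param nodes points per dimension.
#' @param Sigma 2x2 positive-definite covariance.
#' @return list with `theta` (Q x 2 matrix), `logw` (length-Q log
#'   weights) and the standard-normal `z` grid.
#' @export
gh_grid <- function(nodes, Sigma) {
  gh <- pracma::gaussHermite(nodes)
  z1 <- sqrt(2) * gh$x
  lw1 <- log(gh$w) - 0.5 * log(pi)
  z <- as.matrix(expand.grid(z1, z1))
  colnames(z) <- NULL
  logw <- as.vector(outer(lw1, lw1, "+"))
  U <- chol(Sigma)
  list(theta = z %*% U, logw = logw, z = z)
}

# N x Q matrix of per-dyad log conditional likelihoods on the grid:
# one dense product of the category-membership matrix with the stacked
# log-probabilities (missing cells contribute zero).
cond_loglik <- function(scores, model, delta, theta, Ystack = NULL) {
  if (is.null(Ystack)) Ystack <- make_ystack(scores, model)
  Ystack %*% stack_logprob(model, delta, theta)
}

#' Marginal log-likelihood of a dyad Rasch model
#'
#' Sum over dyads of the log of the response-pattern probability
#' integrated over the bivariate-normal population, evaluated on a
#' Cholesky-rotated tensor Gauss-Hermite grid; missing cells are
#' skipped in the conditional product (ignorable missingness).
#'
#' @param scores dyads x indicators integer matrix of category scores
#'   (`NA` missing), columns matching `model$meta$name`.
#' @param model a [build_matrices()] result.
#' @param delta stacked step-parameter vector (length `ncol(model$A)`).
#' @param Sigma 2x2 population covariance.
#' @param nodes Gauss-Hermite points per dimension.
#' @return the marginal log-likelihood (0 for a model with no
#'   indicators).
#' @export
log_likelihood <- function(scores, model, delta, Sigma, nodes = 31) {
  if (!nrow(model$meta) || !ncol(scores)) return(0)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma is not positive-definite")
  grid <- gh_grid(nodes, Sigma)
  ll <- cond_loglik(scores, model, delta, grid$theta)
  lw <- sweep(ll, 2, grid$logw, "+")
  m <- row_max(lw)
  sum(m + log(rowSums(exp(lw - m))))
}

# Newton update of one item's step vector given expected category
# counts R (K x Q) on latent grid theta; returns updated steps.
newton_item <- function(R, theta, level, steps, max_iter = 30,
                        tol = 1e-10) {
  K <- length(steps) + 1L
  mq <- colSums(R)
  # observed cumulative sums S_j = sum over categories k >= j of counts
  Scum <- rev(cumsum(rev(rowSums(R))))[-1]  # length K-1, j = 1..K-1
  obj <- function(s) {
    lp <- item_logprob(theta, level, s)
    sum(R * lp)
  }
  f0 <- obj(steps)
  for (it in seq_len(max_iter)) {
    lp <- item_logprob(theta, level, steps)
    P <- exp(lp)
    # Pcum[j, q] = P(category >= j | theta_q), j = 1..K-1
    Pcum <- cum_tail(P)
    grad <- -Scum + as.vector(Pcum %*% mq)
    H <- matrix(0, K - 1L, K - 1L)
    for (j in seq_len(K - 1L)) for (l in seq_len(j)) {
      H[j, l] <- H[l, j] <-
        sum(mq * (Pcum[j, ] * Pcum[l, ] - Pcum[max(j, l), ]))
    }
    # H is negative definite; the Newton ascent direction is -H^{-1} grad
    dir <- tryCatch(-solve(H, grad),
                    error = function(e) grad / pmax(1, -diag(H)))
    size <- 1
    repeat {
      cand <- steps + size * dir
      f1 <- obj(cand)
      if (f1 >= f0 - 1e-12 || size < 1e-4) break
      size <- size / 2
    }
    if (f1 >= f0) { steps <- cand } else break
    if (max(abs(size * dir)) < tol) { f0 <- f1; break }
    f0 <- f1
  }
  steps
}

#' Fit the dyad Rasch model by marginal maximum likelihood (EM)
#'
#' E-step: posterior weights for each dyad on the quadrature grid.
#' M-step: per-indicator Newton updates of the step parameters against
#' expected category counts, and (unless fixed) re-estimation of the
#' population covariance from averaged posterior second moments (means
#' held at zero).  Standard errors come from the empirical cross-product
#' of per-dyad score contributions.
#'
#' @param scores dyads x indicators integer matrix (or a
#'   `"cps_scores"` object) of category scores; `NA` = missing.
#' @param model a `"dyad_model"`; built from the score metadata when
#'   `NULL`.
#' @param nodes Gauss-Hermite points per dimension (default 31).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the largest absolute change in
#'   any step parameter or Sigma entry.
#' @param Sigma_fixed optional 2x2 covariance held fixed (useful in
#'   oracle comparisons); `NULL` estimates it.
#' @param start optional starting values for the step parameters.
#' @param verbose print per-iteration progress.
#' @return an object of class `"dyad_fit"`: `delta` (named estimates),
#'   `se`, `Sigma`, `rho`, `loglik`, `deviance`, `n_dyads`,
#'   `iterations`, `converged`, `loglik_trace`, plus the `model` and
#'   quadrature settings.
#' @export
fit_mml_em <- function(scores, model = NULL, nodes = 31, max_iter = 500,
                       tol = 1e-4, Sigma_fixed = NULL, start = NULL,
                       verbose = FALSE) {
  if (inherits(scores, "cps_scores")) {
    if (is.null(model)) model <- build_matrices(scores$meta)
    scores <- scores$scores
  }
  if (is.null(model)) stop("a dyad_model is required when scores is a matrix")
  scores <- as.matrix(scores)[, model$meta$name, drop = FALSE]
  storage.mode(scores) <- "integer"
  # pre-check: every indicator needs >= 2 observed categories
  n_cat <- apply(scores, 2, function(x) length(unique(x[!is.na(x)])))
  if (any(n_cat < 2))
    stop("degenerate indicator(s) with < 2 observed categories: ",
         paste(colnames(scores)[n_cat < 2], collapse = ", "))
  bad <- which(scores < 0 | sweep(scores, 2, model$meta$K - 1L, ">"),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("score(s) outside 0..K-1 for indicator ",
         colnames(scores)[bad[1, 2]])
  N <- nrow(scores); I <- ncol(scores)
  delta <- if (is.null(start)) numeric(ncol(model$A)) else start
  Sigma <- if (is.null(Sigma_fixed)) diag(2) else Sigma_fixed
  Ystack <- make_ystack(scores, model)
  offs <- cumsum(c(0L, model$meta$K))
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    grid <- gh_grid(nodes, Sigma)
    ll <- cond_loglik(scores, model, delta, grid$theta, Ystack)
    lw <- sweep(ll, 2, grid$logw, "+")
    m <- row_max(lw)
    liks <- exp(lw - m)
    rs <- rowSums(liks)
    loglik <- sum(m + log(rs))
    loglik_trace <- c(loglik_trace, loglik)
    post <- liks / rs                               # N x Q posterior weights
    if (verbose)
      message(sprintf("iter %3d  logLik %.6f", iter, loglik))
    delta_new <- delta
    steps <- split_delta(model, delta)
    Rall <- crossprod(Ystack, post)                 # (sum K) x Q counts
    pos <- 0L
    for (i in seq_len(I)) {
      R <- Rall[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]
      s_new <- newton_item(R, grid$theta, model$meta$level[i], steps[[i]])
      delta_new[pos + seq_along(s_new)] <- s_new
      pos <- pos + length(s_new)
    }
    if (is.null(Sigma_fixed)) {
      cq <- colSums(post)
      M2 <- crossprod(grid$theta, grid$theta * cq) / N
      Sigma_new <- (M2 + t(M2)) / 2
      # guard against collapse
      if (min(eigen(Sigma_new, symmetric = TRUE,
                    only.values = TRUE)$values) < 1e-6)
        Sigma_new <- Sigma_new + diag(1e-6, 2)
    } else Sigma_new <- Sigma
    dpar <- max(abs(delta_new - delta), abs(Sigma_new - Sigma))
    delta <- delta_new; Sigma <- Sigma_new
    if (dpar < tol && iter > 1) { converged <- TRUE; break }
  }
  # final likelihood and SEs at the converged parameters
  grid <- gh_grid(nodes, Sigma)
  ll <- cond_loglik(scores, model, delta, grid$theta, Ystack)
  lw <- sweep(ll, 2, grid$logw, "+")
  m <- row_max(lw)
  liks <- exp(lw - m); rs <- rowSums(liks)
  loglik <- sum(m + log(rs))
  post <- liks / rs
  se <- em_se(scores, model, delta, post, grid)
  names(delta) <- model$par_names
  names(se) <- model$par_names
  rho <- Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
  structure(list(delta = delta, se = se, Sigma = Sigma, rho = rho,
                 loglik = loglik, deviance = -2 * loglik, n_dyads = N,
                 iterations = length(loglik_trace), converged = converged,
                 loglik_trace = loglik_trace, model = model, nodes = nodes,
                 tol = tol,
                 Sigma_fixed = !is.null(Sigma_fixed)),
            class = "dyad_fit")
}

# empirical cross-product information SEs for the step parameters
em_se <- function(scores, model, delta, post, grid) {
  steps <- split_delta(model, delta)
  N <- nrow(scores)
  S <- matrix(0, N, length(delta))
  pos <- 0L
  for (i in seq_len(ncol(scores))) {
    K <- model$meta$K[i]
    lp <- item_logprob(grid$theta, model$meta$level[i], steps[[i]])
    P <- exp(lp)
    Pcum <- cum_tail(P)
    # score for dyad n, step j: -1{x_ni >= j} + E_post[Pcum_j(theta)]
    x <- scores[, i]
    obs <- !is.na(x)
    Epost <- post %*% t(Pcum)                       # N x (K-1)
    for (j in seq_len(K - 1L)) {
      sc <- numeric(N)
      sc[obs] <- -(x[obs] >= j) + Epost[obs, j]
      S[, pos + j] <- sc
    }
    pos <- pos + K - 1L
  }
  info <- crossprod(S)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, length(delta)))
  se
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat(sprintf(paste0("<dyad_fit> %d dyads, %d parameters, logLik %.3f ",
                     "(deviance %.3f)\n"),
              x$n_dyads, length(x$delta), x$loglik, x$deviance))
  cat(sprintf("  EM %s in %d iterations (tol %g, %d nodes/dim)\n",
              if (x$converged) "converged" else "did NOT converge",
              x$iterations, x$tol, x$nodes))
  cat(sprintf("  Sigma: var_A %.3f, var_B %.3f, rho %.3f%s\n",
              x$Sigma[1, 1], x$Sigma[2, 2], x$rho,
              if (x$Sigma_fixed) " (fixed)" else ""))
  invisible(x)
}

#' EAP ability estimates for each dyad
#'
#' Posterior means and standard deviations of `(theta_A, theta_B)` on
#' the fitted model's quadrature grid.  Dyads with no observed
#' indicators fall back to the population prior: mean (0, 0) with the
#' prior SDs.
#'
#' @param scores dyads x indicators integer score matrix (or
#'   `"cps_scores"`), columns matching the fitted model.
#' @param fit a `"dyad_fit"` object.
#' @return a data frame of class `"dyad_abilities"` with columns
#'   `group_id`, `theta_A`, `theta_B`, `sd_A`, `sd_B` and an
#'   `estimator` attribute `"EAP"`.
#' @export
estimate_abilities_eap <- function(scores, fit) {
  if (inherits(scores, "cps_scores")) scores <- scores$scores
  scores <- as.matrix(scores)[, fit$model$meta$name, drop = FALSE]
  grid <- gh_grid(fit$nodes, fit$Sigma)
  ll <- cond_loglik(scores, fit$model, fit$delta, grid$theta)
  lw <- sweep(ll, 2, grid$logw, "+")
  m <- row_max(lw)
  liks <- exp(lw - m)
  post <- liks / rowSums(liks)
  mu <- post %*% grid$theta
  m2 <- post %*% (grid$theta^2)
  sds <- sqrt(pmax(m2 - mu^2, 0))
  out <- data.frame(group_id = rownames(scores) %||%
                      as.character(seq_len(nrow(scores))),
                    theta_A = mu[, 1], theta_B = mu[, 2],
                    sd_A = sds[, 1], sd_B = sds[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "estimator") <- "EAP"
  class(out) <- c("dyad_abilities", "data.frame")
  out
}
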