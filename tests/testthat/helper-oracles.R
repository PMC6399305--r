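# independent dense-grid marginal log-likelihood (trapezoid rule over a
# wide rectangle; truncation beyond |theta| = lim is negligible for
# Gaussian tails).  Written from the multinomial-logit formula directly,
# not via the package's probability code.
oracle_loglik <- function(scores, meta, delta, Sigma, n_grid = 201,
                          lim = 8, per_row = FALSE) {
  g <- seq(-lim, lim, length.out = n_grid)
  h <- g[2] - g[1]
  gr <- as.matrix(expand.grid(g, g))
  w <- rep(h^2, nrow(gr))
  edge <- (abs(gr[, 1]) == lim) + (abs(gr[, 2]) == lim)
  w <- w / 2^edge
  dens <- exp(-0.5 * rowSums((gr %*% solve(Sigma)) * gr)) /
    (2 * pi * sqrt(det(Sigma)))
  idx <- rep(seq_len(nrow(meta)), meta$K - 1L)
  Plist <- lapply(seq_len(nrow(meta)), function(i) {
    steps <- delta[idx == i]
    K <- meta$K[i]
    u <- switch(meta$level[i], A = gr[, 1], B = gr[, 2],
                G = gr[, 1] + gr[, 2])
    logits <- vapply(0:(K - 1), function(k)
      k * u - sum(steps[seq_len(k)]), numeric(nrow(gr)))
    el <- exp(logits)
    el / rowSums(el)
  })
  lls <- vapply(seq_len(nrow(scores)), function(n) {
    like <- dens * w
    for (i in seq_len(nrow(meta)))
      like <- like * Plist[[i]][, scores[n, i] + 1L]
    log(sum(like))
  }, numeric(1))
  if (per_row) lls else sum(lls)
}
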