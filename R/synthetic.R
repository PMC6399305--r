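# Seeded synthetic dyads: correlated latent abilities, model-consistent
# indicator responses, and full event logs with planted indicator
# values, so the whole pipeline is testable without any external data.

#' Simulate the dyad population
#'
#' Draws per-dyad ability pairs from a mean-(0, 0) bivariate normal
#' with variances `var_A`, `var_B` and correlation `rho`.  The default
#' correlation of 0.56 is in the regime observed for dyad members who
#' depend on each other to progress through asymmetric tasks.
#'
#' @param n_dyads number of dyads.
#' @param rho latent correlation, `|rho| < 1`.
#' @param var_A,var_B latent variances (> 0).
#' @param seed optional RNG seed.
#' @return data frame with `group_id`, `theta_A`, `theta_B`.
#' @export
simulate_population <- function(n_dyads, rho = 0.56, var_A = 1, var_B = 1,
                                seed = NULL) {
  stopifnot(n_dyads >= 1)
  if (abs(rho) >= 1) stop("rho must satisfy |rho| < 1")
  if (var_A <= 0 || var_B <= 0) stop("latent variances must be positive")
  if (!is.null(seed)) set.seed(seed)
  Sigma <- matrix(c(var_A, rho * sqrt(var_A * var_B),
                    rho * sqrt(var_A * var_B), var_B), 2, 2)
  th <- MASS::mvrnorm(n_dyads, mu = c(0, 0), Sigma = Sigma)
  th <- matrix(th, ncol = 2)
  data.frame(group_id = sprintf("G%04d", seq_len(n_dyads)),
             theta_A = th[, 1], theta_B = th[, 2],
             stringsAsFactors = FALSE)
}

#' Build an indicator roster for model simulation
#'
#' A roster names each indicator, assigns its loading level and category
#' count, and carries its true step parameters.  The default layout
#' spreads difficulties evenly over `delta_range`.
#'
#' @param n_A,n_B,n_G counts of A-, B- and group indicators.
#' @param K category count applied to every indicator (vectorized; use
#'   3 for trichotomous).
#' @param delta_range range over which true difficulties are spread.
#' @return data frame with columns `name`, `level`, `K` and list-column
#'   `delta`.
#' @export
model_roster <- function(n_A = 11, n_B = 11, n_G = 8, K = 2,
                         delta_range = c(-2, 2)) {
  level <- c(rep("A", n_A), rep("B", n_B), rep("G", n_G))
  n <- length(level)
  K <- rep_len(K, n)
  idx <- unlist(lapply(c(A = n_A, B = n_B, G = n_G), seq_len))
  name <- sprintf("T1%s%02d", level, idx)
  centers <- seq(delta_range[1], delta_range[2], length.out = n)
  delta <- lapply(seq_len(n), function(i) {
    if (K[i] == 2) centers[i] else
      centers[i] + seq(-0.5, 0.5, length.out = K[i] - 1)
  })
  out <- data.frame(name = name, level = level, K = K,
                    stringsAsFactors = FALSE)
  out$delta <- delta
  out
}

#' Simulate indicator responses from the dyad Rasch model
#'
#' Each cell is drawn from the model's category probabilities at the
#' dyad's abilities: A-indicators depend on `theta_A`, B-indicators on
#' `theta_B`, group indicators on `theta_A + theta_B`.
#'
#' @param abilities data frame from [simulate_population()].
#' @param roster data frame from [model_roster()] (columns `name`,
#'   `level`, `K`, list-column `delta`).
#' @param seed optional RNG seed.
#' @return a `"cps_scores"` object (raw = scores; all categorical).
#' @export
simulate_scores <- function(abilities, roster, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- as.matrix(abilities[, c("theta_A", "theta_B")])
  N <- nrow(th)
  m <- matrix(NA_integer_, N, nrow(roster),
              dimnames = list(abilities$group_id, roster$name))
  for (i in seq_len(nrow(roster))) {
    P <- t(exp(item_logprob(th, roster$level[i], roster$delta[[i]])))
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(N)
    m[, i] <- rowSums(u > cum)  # category index 0..K-1
  }
  meta <- data.frame(name = roster$name, level = roster$level,
                     output = "binary", rule_type = NA_character_,
                     K = roster$K, cutoff = NA_integer_,
                     stringsAsFactors = FALSE)
  structure(list(raw = m, scores = m, meta = meta), class = "cps_scores")
}

#' The simulator's synthetic task: indicator specifications
#'
#' Eight indicators per task over the synthetic event vocabulary (chat,
#' controlA-controlD, apply, task result, task start/end), mirroring
#' the standard indicator families: per-role activeness counts (with
#' empirical mean-minus-SD conversion), direct presence indicators,
#' inferred ordered-sequence indicators, the interactive chat-block
#' count, and the task outcome.
#'
#' @param tasks character vector of task ids, e.g. `c("T1", "T2")`.
#' @return list of [indicator_spec()] objects (8 per task).
#' @export
example_indicator_specs <- function(tasks = paste0("T", 1:4)) {
  out <- list()
  for (tt in tasks) {
    tn <- sub("^T", "", tt)
    out <- c(out, list(
      indicator_spec(sprintf("T%sA01", tn), "A", rule_count_events(),
                     output = "count",
                     conversion = threshold_rule("empirical_mean_minus_sd"),
                     element = "Action"),
      indicator_spec(sprintf("T%sA02", tn), "A", rule_presence("controlA"),
                     element = "Task regulation"),
      indicator_spec(sprintf("T%sA03", tn), "A",
                     rule_sequence(c("controlB", "apply")),
                     element = "Systematicity"),
      indicator_spec(sprintf("T%sB01", tn), "B", rule_count_events(),
                     output = "count",
                     conversion = threshold_rule("empirical_mean_minus_sd"),
                     element = "Action"),
      indicator_spec(sprintf("T%sB02", tn), "B", rule_presence("controlC"),
                     element = "Task regulation"),
      indicator_spec(sprintf("T%sB03", tn), "B",
                     rule_sequence(c("controlD", "apply")),
                     element = "Systematicity"),
      indicator_spec(sprintf("T%sG01", tn), "G", rule_outcome(),
                     element = "Goal attainment"),
      indicator_spec(sprintf("T%sG02", tn), "G", rule_chat_blocks(),
                     output = "count",
                     conversion = threshold_rule("empirical_mean_minus_sd"),
                     element = "Interaction")))
  }
  out
}

synthetic_event_vocabulary <- function() {
  c("task start", "task end", "chat", "controlA", "controlB", "controlC",
    "controlD", "apply", "task result")
}

# minimum event counts implied by a planted row (see simulate_event_logs)
plant_minima <- function(p) {
  list(a = 1L + p$a2 + 2L * p$a3 + p$g2,
       b = 2L + p$b2 + 2L * p$b3 + p$g2)
}

#' Synthesize event logs that realize planted indicator values
#'
#' The inverse of indicator extraction: for each (dyad, task) row of
#' `planted`, emits a complete stream — bracketed by task start/end,
#' with an uninterrupted alternating chat run, role-attributed control
#' and apply actions, padding actions, and a task-result event — such
#' that scoring the logs with [example_indicator_specs()] reproduces
#' the planted values exactly.  Timestamps are strictly increasing at
#' one-second spacing.
#'
#' @param planted data frame with columns `group_id`, `task_id` and the
#'   planted values `a1` (total A events), `a2` (controlA presence
#'   0/1), `a3` (controlB-then-apply sequence 0/1), `b1`, `b2`, `b3`
#'   (B analogues over controlC/controlD), `g1` (task success 0/1),
#'   `g2` (interactive chat blocks).
#' @param start_time timestamp of the first event of the first stream.
#' @return a `"cps_stream_set"` keyed by (group, task).
#' @export
simulate_event_logs <- function(planted,
                                start_time = as.POSIXct("2024-03-01 09:00:00",
                                                        tz = "UTC")) {
  needed <- c("group_id", "task_id", "a1", "a2", "a3", "b1", "b2", "b3",
              "g1", "g2")
  missing_cols <- setdiff(needed, names(planted))
  if (length(missing_cols))
    stop("planted table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rows <- list()
  t0 <- as.numeric(start_time)
  for (r in seq_len(nrow(planted))) {
    p <- planted[r, ]
    mins <- plant_minima(p)
    if (p$a1 < mins$a)
      stop(sprintf("unachievable plant for T?A01: dyad %s task %s needs a1 >= %d, got %d",
                   p$group_id, p$task_id, mins$a, p$a1))
    if (p$b1 < mins$b)
      stop(sprintf("unachievable plant for T?B01: dyad %s task %s needs b1 >= %d, got %d",
                   p$group_id, p$task_id, mins$b, p$b1))
    role <- character(); name <- character(); content <- character()
    emit <- function(ro, nm, ct = "") {
      role[length(role) + 1L] <<- ro
      name[length(name) + 1L] <<- nm
      content[length(content) + 1L] <<- ct
    }
    emit("A", "task start")
    if (p$a2) emit("A", "controlA", "status: on")
    if (p$a3) { emit("A", "controlB", "status: 2"); emit("A", "apply", "A") }
    if (p$g2 > 0) for (i in seq_len(2L * p$g2))
      emit(if (i %% 2L) "A" else "B", "chat",
           sprintf("message %d", i))
    if (p$b2) emit("B", "controlC", "status: on")
    if (p$b3) { emit("B", "controlD", "status: 1"); emit("B", "apply", "B") }
    pad_a <- p$a1 - mins$a
    if (pad_a > 0) for (i in seq_len(pad_a)) emit("A", "controlB",
                                                  "status: adjust")
    pad_b <- p$b1 - mins$b
    if (pad_b > 0) for (i in seq_len(pad_b)) emit("B", "controlD",
                                                  "status: adjust")
    emit("B", "task result", if (p$g1) "success" else "failure")
    emit("B", "task end")
    n <- length(role)
    rows[[r]] <- data.frame(group_id = p$group_id, task_id = p$task_id,
                            role = role, event_name = name,
                            content = content,
                            timestamp = as.POSIXct(t0 + seq_len(n),
                                                   tz = "UTC",
                                                   origin = "1970-01-01"),
                            stringsAsFactors = FALSE)
    t0 <- t0 + n + 60  # one-minute gap between streams
  }
  ev <- do.call(rbind, rows)
  read_event_log(ev, schema = event_schema())
}

#' Simulate a complete synthetic study
#'
#' Draws correlated latent abilities, generates ability-linked planted
#' indicator values for every (dyad, task) — binary indicators from the
#' dyad Rasch model, activeness counts and chat-block counts from
#' ability-linked negative-binomial distributions — synthesizes the
#' event logs realizing them, and returns the logs together with the
#' planted-truth sidecar.  Fully reproducible under a fixed seed.
#'
#' @param n_dyads number of dyads.
#' @param tasks task ids.
#' @param rho,var_A,var_B population parameters.
#' @param seed RNG seed (recorded in the config echo).
#' @param count_mean,count_size negative-binomial mean and size for the
#'   activeness-count padding; the defaults give per-role event counts
#'   with a mean near 37 and SD near 16.
#' @param chat_mean mean number of interactive chat blocks per task.
#' @return list with `streams` (a `"cps_stream_set"`), `truth` (wide
#'   data frame of planted values per dyad, columns named like the
#'   indicator roster), `planted` (long per-(dyad, task) table),
#'   `abilities`, and `config` (echo including the seed).
#' @export
simulate_study <- function(n_dyads = 50, tasks = paste0("T", 1:4),
                           rho = 0.56, var_A = 1, var_B = 1, seed = 1,
                           count_mean = 33, count_size = 5,
                           chat_mean = 6) {
  set.seed(seed)
  abilities <- simulate_population(n_dyads, rho, var_A, var_B)
  rows <- list()
  for (tt in tasks) {
    tn <- sub("^T", "", tt)
    thA <- abilities$theta_A; thB <- abilities$theta_B
    a2 <- stats::rbinom(n_dyads, 1, stats::plogis(thA + 0.5))
    a3 <- stats::rbinom(n_dyads, 1, stats::plogis(thA))
    b2 <- stats::rbinom(n_dyads, 1, stats::plogis(thB + 0.5))
    b3 <- stats::rbinom(n_dyads, 1, stats::plogis(thB))
    g1 <- stats::rbinom(n_dyads, 1, stats::plogis(thA + thB))
    g2 <- stats::rnbinom(n_dyads, mu = chat_mean *
                           exp(0.2 * (thA + thB)), size = 8)
    p <- data.frame(group_id = abilities$group_id, task_id = tt,
                    a2 = a2, a3 = a3, b2 = b2, b3 = b3, g1 = g1, g2 = g2,
                    stringsAsFactors = FALSE)
    base_a <- 1L + a2 + 2L * a3 + g2
    base_b <- 2L + b2 + 2L * b3 + g2
    p$a1 <- base_a + stats::rnbinom(n_dyads,
                                    mu = count_mean * exp(0.15 * thA),
                                    size = count_size)
    p$b1 <- base_b + stats::rnbinom(n_dyads,
                                    mu = count_mean * exp(0.15 * thB),
                                    size = count_size)
    rows[[tt]] <- p
  }
  planted <- do.call(rbind, rows)
  rownames(planted) <- NULL
  streams <- simulate_event_logs(planted)
  # wide truth sidecar, columns named like the extracted indicators
  truth <- data.frame(group_id = abilities$group_id,
                      stringsAsFactors = FALSE)
  cols <- c(a1 = "A01", a2 = "A02", a3 = "A03", b1 = "B01", b2 = "B02",
            b3 = "B03", g1 = "G01", g2 = "G02")
  for (tt in tasks) {
    tn <- sub("^T", "", tt)
    sub <- planted[planted$task_id == tt, ]
    sub <- sub[match(truth$group_id, sub$group_id), ]
    for (src in names(cols))
      truth[[sprintf("T%s%s", tn, cols[[src]])]] <- sub[[src]]
  }
  list(streams = streams, truth = truth, planted = planted,
       abilities = abilities,
       config = list(n_dyads = n_dyads, tasks = tasks, rho = rho,
                     var_A = var_A, var_B = var_B, seed = seed,
                     count_mean = count_mean, count_size = count_size,
                     chat_mean = chat_mean))
}
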