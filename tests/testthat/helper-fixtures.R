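# Shared fixtures: streams built in code, small rosters, and a cached
# large-sample fit reused by the calibration-quality tests.

# a stream from role / event-name vectors at 1-second spacing
make_stream <- function(roles, names = rep("chat", length(roles)),
                        contents = rep("", length(roles)),
                        group = "g1", task = "T1",
                        t0 = as.POSIXct("2024-03-01 09:00:00", tz = "UTC")) {
  n <- length(roles)
  cps_stream(data.frame(group_id = rep(group, n), task_id = rep(task, n),
                        role = roles, event_name = names,
                        content = contents, timestamp = t0 + seq_len(n),
                        stringsAsFactors = FALSE),
             group_id = group, task_id = task)
}

# a complete bracketed stream with the given body
make_complete_stream <- function(roles, names, contents = NULL, ...) {
  roles <- c("A", roles, "B")
  names <- c("task start", names, "task end")
  if (is.null(contents)) contents <- rep("", length(roles)) else
    contents <- c("", contents, "")
  make_stream(roles, names, contents, ...)
}

# events data frame for read_event_log(data.frame)
events_df <- function(group, task, roles, names,
                      contents = rep("", length(roles)),
                      t0 = as.POSIXct("2024-03-01 09:00:00", tz = "UTC")) {
  data.frame(group_id = group, task_id = task, role = roles,
             event_name = names, content = contents,
             timestamp = format(t0 + seq_along(roles),
                                "%Y-%m-%dT%H:%M:%S"),
             stringsAsFactors = FALSE)
}

# the informative recovery roster: trichotomous individual indicators,
# dichotomous group indicators, difficulties spread over [-2, 2]
recovery_roster <- function() {
  model_roster(n_A = 11, n_B = 11, n_G = 8, K = c(rep(3, 22), rep(2, 8)),
               delta_range = c(-2, 2))
}

# large-sample recovery fit, computed once per test run and cached
.fit_cache <- new.env(parent = emptyenv())
recovery_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    set.seed(42)
    roster <- recovery_roster()
    abilities <- simulate_population(2000, rho = 0.56)
    scores <- simulate_scores(abilities, roster)
    fit <- fit_mml_em(scores, nodes = 31)
    .fit_cache$fit <- list(roster = roster, abilities = abilities,
                           scores = scores, fit = fit,
                           eap = estimate_abilities_eap(scores, fit))
  }
  .fit_cache$fit
}
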