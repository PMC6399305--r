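# Indicator extraction rules, frequency discretization, and the score
# matrix contract.

test_that("count_events counts all of one role's events by default", {
  s <- make_stream(c(rep("A", 5), rep("B", 4)))
  expect_equal(count_events(s, "A"), 5)
  expect_equal(count_events(s, "B"), 4)
  expect_equal(count_events(make_stream(character()), "A"), 0)
  # bracket events are excludable but included by default
  s2 <- make_stream(c("A", "A", "A"), c("task start", "chat", "task end"))
  expect_equal(count_events(s2, "A"), 3)
  expect_equal(count_events(s2, "A", exclude = c("task start", "task end")),
               1)
})

test_that("chat-block counting follows the two-step pairing rule", {
  expect_equal(count_chat_blocks(make_stream(c("A", "B", "A", "B"))), 2)
  expect_equal(count_chat_blocks(make_stream(c("A", "A", "B", "A", "B"))), 2)
  expect_equal(count_chat_blocks(make_stream(c("A", "A"), rep("apply", 2))), 0)
  # an interrupting action splits the run: two runs of one pair each
  s <- make_stream(c("A", "B", "A", "A", "B"),
                   c("chat", "chat", "apply", "chat", "chat"))
  expect_equal(count_chat_blocks(s), 2)
  # a B-initiated exchange also counts
  expect_equal(count_chat_blocks(make_stream(c("B", "A"))), 1)
})

test_that("chat blocks are bounded by floor(total chats / 2)", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(0:15, 1)
    roles <- sample(c("A", "B"), n, replace = TRUE)
    names <- sample(c("chat", "apply", "controlA"), n, replace = TRUE,
                    prob = c(.6, .2, .2))
    s <- make_stream(roles, names)
    cb <- count_chat_blocks(s)
    expect_gte(cb, 0)
    expect_lte(cb, sum(names == "chat") %/% 2)
  }
})

test_that("direct and inferred predicates score presence and order", {
  s <- make_stream(c("A", "A", "B"), c("apply", "controlA", "chat"))
  expect_equal(eval_direct(s, rule_presence("apply")), 1)
  expect_equal(eval_direct(s, rule_presence("controlD")), 0)
  # ordered sequence: controlA then apply must appear in that order
  expect_equal(eval_direct(s, rule_sequence(c("controlA", "apply"))), 0)
  s2 <- make_stream(c("A", "A"), c("controlA", "apply"))
  expect_equal(eval_direct(s2, rule_sequence(c("controlA", "apply"))), 1)
  # content pattern restricts presence matches
  s3 <- make_stream("B", "task result", contents = "failure")
  expect_equal(eval_direct(s3, rule_presence("task result", "success")), 0)
  expect_error(eval_direct(s, rule_presence("warp"),
                           known_events = c("apply", "chat")),
               "unknown event")
})

test_that("task outcome requires a complete stream", {
  done <- make_complete_stream("B", "task result", "success")
  expect_equal(task_outcome(done), 1)
  failed <- make_complete_stream("B", "task result", "failure")
  expect_equal(task_outcome(failed), 0)
  truncated <- make_stream(c("A", "B"), c("chat", "task result"),
                           contents = c("", "success"))
  expect_error(task_outcome(truncated), "incomplete")
})

test_that("empirical cut-off is ceiling(mean - sample SD), floored at 0", {
  expect_equal(empirical_cutoff(c(2, 4, 6, 8)), 3)  # ceiling(5 - 2.582)
  expect_equal(empirical_cutoff(rep(10, 5)), 10)    # SD 0
  expect_equal(empirical_cutoff(c(0, 1)), 0)        # negative floors at 0
  expect_error(empirical_cutoff(7), "at least 2")
})

test_that("apply_cutoff scores 1 at or above the threshold, monotonically", {
  rule <- threshold_rule("fixed", cutoff = 22)
  expect_equal(apply_cutoff(21, rule), 0)
  expect_equal(apply_cutoff(22, rule), 1)
  expect_equal(apply_cutoff(0, rule), 0)
  vals <- 0:60
  expect_true(all(diff(apply_cutoff(vals, rule)) >= 0))
  # ordinal bins return the bin index
  orule <- threshold_rule("fixed", bins = c(5, 10))
  expect_equal(apply_cutoff(c(0, 5, 9, 10, 99), orule), c(0, 1, 1, 2, 2))
  expect_error(threshold_rule("fixed", bins = c(5, 5)), "increasing")
  expect_error(apply_cutoff(3, threshold_rule("empirical_mean_minus_sd")),
               "unresolved")
})

test_that("indicator names must follow the task/level coding rule", {
  expect_error(indicator_spec("X1A01", "A", rule_presence("apply")),
               "coding rule")
  expect_error(indicator_spec("T1A01", "G", rule_presence("apply")),
               "disagrees")
  expect_error(indicator_spec("T1A02", "A", rule_presence("apply"),
                              output = "binary",
                              conversion = threshold_rule("fixed", 1)),
               "conversion")
  sp <- indicator_spec("T10G03", "G", rule_chat_blocks(), output = "count")
  expect_equal(sp$task_id, "T10")
})

test_that("score_streams fills cells by level, resolves cutoffs, flags missing", {
  sim <- simulate_study(n_dyads = 6, tasks = c("T1", "T2"), seed = 9)
  specs <- example_indicator_specs(c("T1", "T2"))
  sc <- score_streams(sim$streams, specs)
  expect_s3_class(sc, "cps_scores")
  expect_equal(dim(sc$scores), c(6, 16))
  expect_false(anyNA(sc$scores))
  # empirical cutoffs resolved over the sample
  expect_equal(sc$meta$cutoff[sc$meta$name == "T1A01"],
               empirical_cutoff(sc$raw[, "T1A01"]))
  # a dyad missing task 2 gets missing task-2 cells, others filled
  streams_sub <- sim$streams[!grepl("^G0001::T2$", names(sim$streams))]
  class(streams_sub) <- "cps_stream_set"
  sc2 <- score_streams(streams_sub, specs)
  expect_true(all(is.na(sc2$scores["G0001", grepl("^T2", colnames(sc2$scores))])))
  expect_false(anyNA(sc2$scores["G0001", grepl("^T1", colnames(sc2$scores))]))
  expect_error(score_streams(sim$streams, specs[c(1, 1)]), "duplicate")
})

test_that("scoring is deterministic and role-separated", {
  sim <- simulate_study(n_dyads = 4, tasks = "T1", seed = 13)
  specs <- example_indicator_specs("T1")
  sc1 <- score_streams(sim$streams, specs)
  sc2 <- score_streams(sim$streams, specs)
  expect_identical(sc1$scores, sc2$scores)
  # permuting B's events within a stream never changes an A column
  streams_perm <- sim$streams
  set.seed(2)
  for (k in names(streams_perm)) {
    ev <- streams_perm[[k]]$events
    bidx <- which(ev$role == "B" &
                    !ev$event_name %in% c("task start", "task end",
                                          "task result"))
    ev$event_name[bidx] <- ev$event_name[sample(bidx)]
    streams_perm[[k]]$events <- ev
  }
  sc3 <- score_streams(streams_perm, specs)
  acols <- sc1$meta$name[sc1$meta$level == "A"]
  expect_equal(sc3$raw[, acols], sc1$raw[, acols])
})

test_that("indicator spec YAML files load with validated entries", {
  path <- system.file("extdata", "indicators_t1.yaml", package = "cpsdyad")
  loaded <- read_indicator_specs(path)
  expect_length(loaded$specs, 8)
  expect_true("task result" %in% loaded$events)
  kinds <- vapply(loaded$specs, function(s) s$rule$type, character(1))
  expect_setequal(unique(kinds), c("count_events", "presence", "sequence",
                                   "outcome", "chat_blocks"))
  # a malformed entry reports its position and name
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(indicators = list(
    list(name = "T1Z01", level = "A", output = "binary",
         rule = list(type = "presence", event = "apply")))), bad)
  expect_error(read_indicator_specs(bad), "entry 1")
})

test_that("the packaged example log scores against the packaged spec", {
  ev <- system.file("extdata", "events_example.csv", package = "cpsdyad")
  sp <- system.file("extdata", "indicators_t1.yaml", package = "cpsdyad")
  loaded <- read_indicator_specs(sp)
  streams <- read_event_log(ev)
  sc <- score_streams(streams, loaded$specs, known_events = loaded$events)
  expect_equal(dim(sc$scores), c(2, 8))
  # dyad G0001: one uninterrupted A,B,A,B chat run -> 2 blocks
  expect_equal(unname(sc$raw["G0001", "T1G02"]), 2)
  expect_equal(unname(sc$scores["G0001", "T1G01"]), 1)
  expect_equal(unname(sc$scores["G0002", "T1G01"]), 0)
  expect_equal(unname(sc$raw["G0001", "T1A01"]), 6)
  expect_equal(unname(sc$scores["G0002", "T1B03"]), 0)
})

test_that("score matrices round-trip through CSV with metadata", {
  sim <- simulate_study(n_dyads = 5, tasks = "T1", seed = 21)
  sc <- score_streams(sim$streams, example_indicator_specs("T1"))
  f <- tempfile(fileext = ".csv")
  write_scores(sc, f)
  back <- read_scores(f)
  expect_equal(back$scores, sc$scores)
  expect_equal(back$raw, sc$raw)
  expect_equal(back$meta$K, sc$meta$K)
})
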