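# Indicator extraction: evaluate named rule-based indicator
# specifications against process streams, producing the dyad x indicator
# score matrix, and convert frequency indicators to categories.
#
# Indicator names follow the field's coding rule T<task><A|B|G><index>:
# "T1A01" is the first indicator of task 1, identified for student A
# (an individual indicator); the letter G marks a group indicator
# computed from the joint stream.

INDICATOR_NAME_RE <- "^T[0-9]+[ABG][0-9]{2}$"

#' Define an indicator specification
#'
#' An indicator is a scored feature extracted from a process stream by
#' rule.  Individual indicators (levels `"A"`/`"B"`) are evaluated on the
#' corresponding role slice of the stream; group indicators (level
#' `"G"`) on the full stream.
#'
#' @param name coded name matching `T<task><A|B|G><2-digit index>`,
#'   e.g. `"T1A01"`.  The level letter must agree with `level`.
#' @param level `"A"`, `"B"` or `"G"`.
#' @param rule a rule list created by one of [rule_count_events()],
#'   [rule_presence()], [rule_sequence()], [rule_chat_blocks()],
#'   [rule_outcome()].
#' @param output `"count"`, `"binary"` or `"ordinal"`.
#' @param conversion for `"count"` output only: a [threshold_rule()]
#'   turning raw counts into categories, or `NULL` to keep raw counts.
#' @param element name of the CPS-framework element the indicator maps
#'   to (documentation only).
#' @return a list of class `"indicator_spec"`.
#' @export
indicator_spec <- function(name, level, rule, output = "binary",
                           conversion = NULL, element = NA_character_) {
  if (!grepl(INDICATOR_NAME_RE, name))
    stop("indicator name '", name,
         "' does not match the coding rule T<task><A|B|G><2 digits>")
  level <- match.arg(level, c("A", "B", "G"))
  letter <- sub("^T[0-9]+([ABG])[0-9]{2}$", "\\1", name)
  if (letter != level)
    stop("indicator '", name, "': level '", level,
         "' disagrees with the name's level letter '", letter, "'")
  output <- match.arg(output, c("count", "binary", "ordinal"))
  if (output != "count" && !is.null(conversion))
    stop("indicator '", name, "': only count indicators take a conversion rule")
  structure(list(name = name, level = level,
                 task_id = sub("^(T[0-9]+).*$", "\\1", name),
                 rule = rule, output = output, conversion = conversion,
                 element = element),
            class = "indicator_spec")
}

#' Extraction-rule constructors
#'
#' The rule vocabulary covers the indicator algorithms used in
#' process-stream CPS assessment: event counts, single-event presence
#' (direct indicators), ordered action sequences (inferred indicators),
#' interactive chat blocks, and task outcomes.
#'
#' @param exclude event names excluded from the count (default: none —
#'   every event attributed to the role counts).
#' @param event an event name the rule looks for.
#' @param events for [rule_sequence()], the ordered vector of event names
#'   that must occur as a (not necessarily contiguous) subsequence.
#' @param pattern for [rule_presence()]/[rule_outcome()], an optional
#'   regular expression the event content must match.
#' @return a list of class `"cps_rule"`.
#' @name rules
NULL

#' @rdname rules
#' @export
rule_count_events <- function(exclude = character()) {
  structure(list(type = "count_events", exclude = exclude),
            class = "cps_rule")
}

#' @rdname rules
#' @export
rule_presence <- function(event, pattern = NULL) {
  structure(list(type = "presence", event = event, pattern = pattern),
            class = "cps_rule")
}

#' @rdname rules
#' @export
rule_sequence <- function(events) {
  events <- unlist(events)
  stopifnot(length(events) >= 2)
  structure(list(type = "sequence", events = events), class = "cps_rule")
}

#' @rdname rules
#' @export
rule_chat_blocks <- function(event = "chat") {
  structure(list(type = "chat_blocks", event = event), class = "cps_rule")
}

#' @rdname rules
#' @export
rule_outcome <- function(event = "task result", pattern = "success") {
  structure(list(type = "outcome", event = event, pattern = pattern),
            class = "cps_rule")
}

#' Count the events attributed to one role
#'
#' The activeness-style indicator: in the process stream of one dyad
#' member, count all the events (actions and chat messages) that the
#' member generated.  By default nothing is excluded; pass bracket
#' events via `exclude` to leave them out.
#'
#' @param stream a [cps_stream()].
#' @param role `"A"` or `"B"`.
#' @param exclude event names not counted.
#' @return integer count.
#' @export
count_events <- function(stream, role, exclude = character()) {
  sl <- slice_role(stream, role)
  sum(!(sl$events$event_name %in% exclude))
}

#' Count interactive chat blocks
#'
#' The interaction indicator: step 1 finds all maximal sequences of
#' consecutive chat messages uninterrupted by any non-chat action;
#' step 2 collapses consecutive chats from the same student into one
#' speaker block and counts adjacent block pairs (an exchange between
#' the two members), i.e. `floor(blocks / 2)` per sequence, summed over
#' sequences.  Speaker orders A,B,A,B and A,A,B,A,B both give 2.
#'
#' @param stream a [cps_stream()].
#' @param chat_event the event name identifying chat messages.
#' @return integer count of interactive chat blocks.
#' @export
count_chat_blocks <- function(stream, chat_event = "chat") {
  ev <- stream$events
  if (!nrow(ev)) return(0L)
  is_chat <- ev$event_name == chat_event
  if (!any(is_chat)) return(0L)
  runs <- rle(is_chat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  total <- 0L
  for (r in which(runs$values)) {
    roles <- ev$role[starts[r]:ends[r]]
    n_blocks <- length(rle(roles)$lengths)
    total <- total + n_blocks %/% 2L
  }
  total
}

match_events <- function(events, event, pattern = NULL) {
  hit <- events$event_name == event
  if (!is.null(pattern)) hit <- hit & grepl(pattern, events$content)
  hit
}

#' Evaluate a direct or inferred presence indicator
#'
#' Scores 1 if the specified action (or ordered action sequence) occurs
#' in the stream, 0 otherwise.
#'
#' @param stream a [cps_stream()].
#' @param rule a [rule_presence()] or [rule_sequence()].
#' @param known_events optional character vector of the task's declared
#'   event vocabulary; rules referring to undeclared events raise an
#'   error instead of silently scoring 0.
#' @return 0 or 1.
#' @export
eval_direct <- function(stream, rule, known_events = NULL) {
  refs <- switch(rule$type, presence = rule$event, sequence = rule$events,
                 outcome = rule$event,
                 stop("eval_direct expects a presence/sequence/outcome rule"))
  if (!is.null(known_events)) {
    unknown <- setdiff(refs, known_events)
    if (length(unknown))
      stop("rule references unknown event name(s): ",
           paste(unknown, collapse = ", "))
  }
  ev <- stream$events
  if (rule$type %in% c("presence", "outcome")) {
    as.integer(any(match_events(ev, rule$event, rule$pattern)))
  } else {
    # ordered subsequence match on event names
    pos <- 0L
    for (target in rule$events) {
      nxt <- which(ev$event_name == target & seq_len(nrow(ev)) > pos)
      if (!length(nxt)) return(0L)
      pos <- nxt[1]
    }
    1L
  }
}

#' Score the group-level task outcome
#'
#' The success or failure of a task, read from the stream's recorded
#' outcome event.  The stream must be complete (bracketed by task
#' start/end): an outcome read off a truncated stream is not trusted.
#'
#' @param stream a complete [cps_stream()].
#' @param rule a [rule_outcome()]: the event name plus a content pattern
#'   that signals success.
#' @return 0 (failure) or 1 (success).
#' @export
task_outcome <- function(stream, rule = rule_outcome()) {
  v <- validate_stream(stream)
  if (!v$complete)
    stop("task outcome requested on an incomplete stream (group ",
         stream$group_id, ", task ", stream$task_id, ")")
  eval_direct(stream, rule)
}

#' Empirical cut-off for a frequency indicator
#'
#' The mean-minus-one-standard-deviation rule: the cut-off is
#' `ceiling(mean(values) - sd(values))` ("rounded up"), floored at zero.
#' With a sample mean of 37.18 and SD of 15.74 the difference 21.44
#' rounds up to 22.  The SD uses the sample (n - 1) convention.
#'
#' @param values raw counts across the full sample.
#' @return integer cut-off.
#' @export
empirical_cutoff <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("empirical cut-off needs at least 2 observed values")
  max(0L, as.integer(ceiling(mean(values) - stats::sd(values))))
}

#' Threshold rule for converting counts to categories
#'
#' @param kind `"empirical_mean_minus_sd"` (cut-off resolved from the
#'   sample by [empirical_cutoff()]) or `"fixed"` (user-supplied,
#'   meaning-based threshold).
#' @param cutoff for `kind = "fixed"` with binary output: score 1 iff
#'   value >= cutoff.
#' @param bins for ordinal output: strictly increasing lower bin edges;
#'   the score is the number of edges at or below the value.
#' @return a list of class `"threshold_rule"`.
#' @export
threshold_rule <- function(kind = c("empirical_mean_minus_sd", "fixed"),
                           cutoff = NULL, bins = NULL) {
  kind <- match.arg(kind)
  if (!is.null(bins)) {
    if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  }
  if (kind == "fixed" && is.null(cutoff) && is.null(bins))
    stop("a fixed threshold rule needs a cutoff or bin edges")
  structure(list(kind = kind, cutoff = cutoff, bins = bins),
            class = "threshold_rule")
}

#' Apply a resolved threshold rule to a raw count
#'
#' Binary rules score 1 iff the value is at or above the cut-off (a
#' count of 21 against cut-off 22 scores 0; a count of 22 scores 1).
#' Ordinal rules return the bin index.  Monotone non-decreasing in the
#' raw value.
#'
#' @param value raw count (vectorized).
#' @param rule a [threshold_rule()] whose cut-off has been resolved.
#' @return integer category score(s).
#' @export
apply_cutoff <- function(value, rule) {
  if (!is.null(rule$bins)) {
    return(vapply(value, function(v)
      if (is.na(v)) NA_integer_ else sum(v >= rule$bins), integer(1)))
  }
  if (is.null(rule$cutoff))
    stop("threshold rule is unresolved: no cutoff; resolve it from the ",
         "sample first")
  as.integer(value >= rule$cutoff)
}

eval_raw_indicator <- function(stream, spec, known_events = NULL) {
  target <- if (spec$level == "G") stream else slice_role(stream, spec$level)
  switch(spec$rule$type,
         count_events = if (spec$level == "G")
           sum(!(stream$events$event_name %in% spec$rule$exclude))
         else count_events(stream, spec$level, spec$rule$exclude),
         chat_blocks = count_chat_blocks(target, chat_event = spec$rule$event),
         presence = eval_direct(target, spec$rule, known_events),
         sequence = eval_direct(target, spec$rule, known_events),
         outcome = task_outcome(stream, spec$rule),
         stop("unknown rule type: ", spec$rule$type))
}

#' Score a collection of streams against indicator specifications
#'
#' The automatic scoring program: one row per dyad, one column per
#' indicator.  Individual indicators are computed from the role slices,
#' group indicators from the full stream.  Raw counts are retained
#' alongside converted categorical scores; empirical cut-offs are
#' resolved over the full sample before conversion.  A dyad lacking the
#' indicator's task gets a missing cell.
#'
#' @param streams a `"cps_stream_set"` from [read_event_log()] (or any
#'   named list of streams).
#' @param specs a list of [indicator_spec()] objects.
#' @param known_events optional declared event vocabulary for rule
#'   validation.
#' @return an object of class `"cps_scores"`: a list with `raw` and
#'   `scores` (dyads x indicators integer matrices, `NA` for missing),
#'   and `meta` (per-indicator data frame with level, output kind,
#'   category count `K`, resolved cut-off, rule type).
#' @export
score_streams <- function(streams, specs, known_events = NULL) {
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate indicator name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  groups <- sort(unique(vapply(streams, function(s) s$group_id, character(1))))
  key <- vapply(streams, function(s) paste(s$group_id, s$task_id, sep = "::"),
                character(1))
  raw <- matrix(NA_integer_, length(groups), length(specs),
                dimnames = list(groups, nm))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    for (i in seq_along(groups)) {
      k <- which(key == paste(groups[i], sp$task_id, sep = "::"))
      if (length(k) == 1)
        raw[i, j] <- eval_raw_indicator(streams[[k]], sp, known_events)
    }
  }
  scores <- raw
  meta <- data.frame(name = nm,
                     level = vapply(specs, function(s) s$level, character(1)),
                     output = vapply(specs, function(s) s$output, character(1)),
                     rule_type = vapply(specs, function(s) s$rule$type,
                                        character(1)),
                     K = NA_integer_, cutoff = NA_integer_,
                     stringsAsFactors = FALSE)
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (sp$output == "count" && !is.null(sp$conversion)) {
      rule <- sp$conversion
      if (rule$kind == "empirical_mean_minus_sd" && is.null(rule$cutoff))
        rule$cutoff <- empirical_cutoff(raw[, j])
      scores[, j] <- apply_cutoff(raw[, j], rule)
      meta$cutoff[j] <- if (!is.null(rule$bins)) NA_integer_ else rule$cutoff
      meta$K[j] <- if (!is.null(rule$bins)) length(rule$bins) + 1L else 2L
    } else if (sp$output == "count") {
      meta$K[j] <- NA_integer_  # raw count retained, no categories
    } else {
      meta$K[j] <- max(2L, max(scores[, j], na.rm = TRUE) + 1L)
    }
  }
  structure(list(raw = raw, scores = scores, meta = meta),
            class = "cps_scores")
}

#' @export
print.cps_scores <- function(x, ...) {
  cat(sprintf("<cps_scores> %d dyads x %d indicators (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%s:%d", c("A", "B", "G"),
                            tabulate(factor(x$meta$level,
                                            c("A", "B", "G")), 3)),
                    collapse = " ")))
  invisible(x)
}

#' Read / write indicator specifications (YAML)
#'
#' The specification file is a YAML list; each entry carries `name`,
#' `level`, `output`, a `rule` mapping (`type` plus its parameters) and
#' an optional `conversion` mapping.  An optional top-level `events`
#' vector declares the task's event vocabulary.
#'
#' @param path YAML file path.
#' @return for `read_indicator_specs`: a list with `specs` (list of
#'   [indicator_spec()]) and `events` (declared vocabulary or `NULL`).
#' @export
read_indicator_specs <- function(path) {
  if (!file.exists(path)) stop("indicator spec file not found: ", path)
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$indicators)) doc$indicators else doc
  specs <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    tryCatch({
      rule <- do.call(switch(e$rule$type,
                             count_events = rule_count_events,
                             presence = rule_presence,
                             sequence = rule_sequence,
                             chat_blocks = rule_chat_blocks,
                             outcome = rule_outcome,
                             stop("unknown rule type '", e$rule$type, "'")),
                      e$rule[setdiff(names(e$rule), "type")])
      conv <- if (!is.null(e$conversion))
        do.call(threshold_rule, e$conversion) else NULL
      indicator_spec(e$name, e$level, rule, output = e$output %||% "binary",
                     conversion = conv, element = e$element %||% NA_character_)
    }, error = function(err)
      stop("indicator spec entry ", i, " (", e$name %||% "<unnamed>", "): ",
           conditionMessage(err), call. = FALSE))
  })
  list(specs = specs, events = doc$events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a score matrix and its metadata sidecar
#'
#' @param scores a `"cps_scores"` object.
#' @param path output CSV for the categorical scores (dyad rows); the raw
#'   counts go to `<path base>_raw.csv` and the per-indicator metadata to
#'   `<path base>_meta.csv`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  base <- sub("\\.csv$", "", path)
  df <- data.frame(group_id = rownames(scores$scores), scores$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  dfr <- data.frame(group_id = rownames(scores$raw), scores$raw,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(dfr, paste0(base, "_raw.csv"), row.names = FALSE)
  utils::write.csv(scores$meta, paste0(base, "_meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#'
#' @param path the categorical-score CSV path.
#' @return a `"cps_scores"` object (raw matrix present only if the
#'   sidecar exists).
#' @export
read_scores <- function(path) {
  base <- sub("\\.csv$", "", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$group_id
  meta_path <- paste0(base, "_meta.csv")
  raw_path <- paste0(base, "_raw.csv")
  meta <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  raw <- if (file.exists(raw_path)) {
    dfr <- utils::read.csv(raw_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    mr <- as.matrix(dfr[, -1, drop = FALSE])
    storage.mode(mr) <- "integer"
    rownames(mr) <- dfr$group_id
    mr
  } else m
  if (is.null(meta))
    meta <- data.frame(name = colnames(m),
                       level = sub("^T[0-9]+([ABG])[0-9]{2}$", "\\1",
                                   colnames(m)),
                       output = "binary", rule_type = NA_character_,
                       K = apply(m, 2, function(col)
                         max(2L, max(col, na.rm = TRUE) + 1L)),
                       cutoff = NA_integer_, stringsAsFactors = FALSE)
  structure(list(raw = raw, scores = m, meta = meta), class = "cps_scores")
}
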