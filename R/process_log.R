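# Process-stream event logs: parsing, validation, slicing.
#
# An event log is tabular: one row per recorded event, tagged with the
# dyad (group) identifier, the task identifier, the role of the actor
# (A or B), the event name, free-text content and a timestamp.  Logs are
# sliced into per-(group, task) ordered streams before indicator scoring.

#' Default column schema for event logs
#'
#' Describes how the logical columns of an event log map onto the columns
#' of a concrete file, and how timestamps are formatted.  Raw exports from
#' testing platforms rarely agree on column names, so every logical column
#' is remappable.
#'
#' @param group_id,task_id,role,event_name,content,timestamp names of the
#'   physical columns holding each logical column.
#' @param timestamp_format a [base::strptime()] format string; the default
#'   accepts ISO-8601 `"2024-01-01T09:00:00"` style stamps (a literal space
#'   separator also parses).
#' @param tz timezone used when parsing timestamps.
#' @return a list of class `"cps_schema"`.
#' @export
event_schema <- function(group_id = "group_id", task_id = "task_id",
                         role = "role", event_name = "event_name",
                         content = "content", timestamp = "timestamp",
                         timestamp_format = "%Y-%m-%dT%H:%M:%OS",
                         tz = "UTC") {
  structure(list(columns = c(group_id = group_id, task_id = task_id,
                             role = role, event_name = event_name,
                             content = content, timestamp = timestamp),
                 timestamp_format = timestamp_format, tz = tz),
            class = "cps_schema")
}

#' Construct a process stream
#'
#' A process stream holds every event generated by one dyad within one
#' task, ordered in time from task start to task end.
#'
#' @param events a data frame with columns `group_id`, `task_id`, `role`,
#'   `event_name`, `content`, `timestamp` (`POSIXct`).
#' @param group_id,task_id identifiers; taken from `events` when missing.
#' @return an object of class `"cps_stream"`.
#' @export
cps_stream <- function(events, group_id = NULL, task_id = NULL) {
  needed <- c("group_id", "task_id", "role", "event_name", "content",
              "timestamp")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols))
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(group_id)) group_id <- if (nrow(events)) events$group_id[1] else NA_character_
  if (is.null(task_id)) task_id <- if (nrow(events)) events$task_id[1] else NA_character_
  rownames(events) <- NULL
  structure(list(group_id = group_id, task_id = task_id,
                 events = events[needed]),
            class = "cps_stream")
}

#' @export
print.cps_stream <- function(x, ...) {
  cat(sprintf("<cps_stream> group %s, task %s: %d events\n",
              x$group_id, x$task_id, nrow(x$events)))
  if (nrow(x$events)) {
    rng <- range(x$events$timestamp)
    cat(sprintf("  %s .. %s\n", format(rng[1]), format(rng[2])))
  }
  invisible(x)
}

#' @export
length.cps_stream <- function(x) nrow(x$events)

parse_timestamps <- function(raw, schema) {
  ts <- as.POSIXct(raw, format = schema$timestamp_format, tz = schema$tz)
  if (anyNA(ts)) {
    # tolerate a space where the format expects 'T' (common in DB exports)
    alt <- gsub("T", " ", schema$timestamp_format, fixed = TRUE)
    bad <- is.na(ts)
    ts[bad] <- as.POSIXct(gsub(" ", "T", raw[bad], fixed = TRUE),
                          format = schema$timestamp_format, tz = schema$tz)
    ts[is.na(ts)] <- as.POSIXct(raw[is.na(ts)], format = alt, tz = schema$tz)
  }
  ts
}

#' Read an event log into per-(group, task) process streams
#'
#' Each row of the file is one event.  Rows are partitioned by
#' (group, task), sorted by timestamp with the original file order
#' preserved for ties, and returned as a named collection of streams.
#'
#' @param source path to a CSV file (RFC 4180) or JSON-lines file, or a
#'   data frame already holding the physical columns.
#' @param schema an [event_schema()] mapping logical to physical columns.
#' @param sort_events if `FALSE`, rows are kept in file order and any
#'   out-of-order timestamps are left for [validate_stream()] to flag;
#'   the default re-sorts (stably) within each stream.
#' @return a named list of [cps_stream()] objects (class
#'   `"cps_stream_set"`), keyed `"<group_id>::<task_id>"`.
#' @export
read_event_log <- function(source, schema = event_schema(),
                           sort_events = TRUE) {
  if (is.data.frame(source)) {
    raw <- source
  } else {
    if (!file.exists(source)) stop("event log file not found: ", source)
    if (grepl("\\.(jsonl|ndjson)$", source)) {
      raw <- jsonlite::stream_in(file(source), verbose = FALSE)
    } else {
      raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
    }
  }
  cols <- schema$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols))
    stop("event log is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  ev <- data.frame(group_id = as.character(raw[[cols["group_id"]]]),
                   task_id = as.character(raw[[cols["task_id"]]]),
                   role = as.character(raw[[cols["role"]]]),
                   event_name = as.character(raw[[cols["event_name"]]]),
                   content = as.character(raw[[cols["content"]]]),
                   stringsAsFactors = FALSE)
  ev$content[is.na(ev$content)] <- ""
  ts <- parse_timestamps(as.character(raw[[cols["timestamp"]]]), schema)
  if (anyNA(ts))
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(which(is.na(ts)), 10L), collapse = ", "))
  ev$timestamp <- ts
  bad_role <- !(ev$role %in% c("A", "B"))
  if (any(bad_role))
    stop("unknown role value(s) at row(s): ",
         paste(utils::head(which(bad_role), 10L), collapse = ", "),
         " (expected 'A' or 'B')")
  if (any(!nzchar(ev$event_name)))
    stop("empty event_name at row(s): ",
         paste(utils::head(which(!nzchar(ev$event_name)), 10L), collapse = ", "))
  key <- paste(ev$group_id, ev$task_id, sep = "::")
  out <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    sub <- ev[idx, , drop = FALSE]
    if (sort_events) sub <- sub[order(sub$timestamp, method = "radix"), ,
                                drop = FALSE]
    cps_stream(sub)
  })
  structure(out[order(names(out))], class = "cps_stream_set")
}

#' Write process streams back to a canonical event-log CSV
#'
#' @param streams a `"cps_stream_set"`, a single stream, or a list of
#'   streams.
#' @param path output CSV path.
#' @param schema controls the timestamp format of the output.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(streams, path, schema = event_schema()) {
  if (inherits(streams, "cps_stream")) streams <- list(streams)
  ev <- do.call(rbind, lapply(streams, function(s) s$events))
  if (is.null(ev)) ev <- cps_stream(empty_events())$events
  ev$timestamp <- format(ev$timestamp, format = schema$timestamp_format,
                         tz = schema$tz)
  utils::write.csv(ev, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

empty_events <- function() {
  data.frame(group_id = character(), task_id = character(),
             role = character(), event_name = character(),
             content = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             stringsAsFactors = FALSE)
}

#' Validate a process stream against the event-log contract
#'
#' Checks role values, event names, timestamp ordering, identifier
#' consistency, and whether the stream is `complete`: bracketed by a
#' "task start" event before all others and a "task end" event after all
#' others.  Violations are reported, never raised.
#'
#' @param stream a [cps_stream()].
#' @param start_event,end_event names of the bracketing events.
#' @return a list with elements `complete` (logical) and `violations`
#'   (data frame with columns `index`, `message`; `index` is `NA` for
#'   stream-level violations).
#' @export
validate_stream <- function(stream, start_event = "task start",
                            end_event = "task end") {
  stopifnot(inherits(stream, "cps_stream"))
  ev <- stream$events
  viol <- list()
  add <- function(index, message)
    viol[[length(viol) + 1L]] <<- data.frame(index = index, message = message,
                                             stringsAsFactors = FALSE)
  n <- nrow(ev)
  for (i in seq_len(n)) {
    if (!ev$role[i] %in% c("A", "B"))
      add(i, sprintf("invalid role '%s'", ev$role[i]))
    if (is.na(ev$event_name[i]) || !nzchar(ev$event_name[i]))
      add(i, "empty event name")
    if (!is.na(ev$group_id[i]) && !identical(ev$group_id[i], stream$group_id))
      add(i, "group_id differs from stream group_id")
    if (!is.na(ev$task_id[i]) && !identical(ev$task_id[i], stream$task_id))
      add(i, "task_id differs from stream task_id")
  }
  if (n > 1) {
    dts <- diff(as.numeric(ev$timestamp))
    for (i in which(dts < 0))
      add(i + 1L, "timestamp earlier than predecessor")
  }
  complete <- FALSE
  if (n == 0) {
    add(NA_integer_, "empty stream")
  } else {
    has_start <- identical(ev$event_name[1], start_event)
    has_end <- identical(ev$event_name[n], end_event)
    inner <- ev$event_name[seq_len(n)[-c(1L, n)]]
    if (!has_start) add(NA_integer_, "missing task start")
    if (!has_end) add(NA_integer_, "missing task end")
    stray <- which(ev$event_name %in% c(start_event, end_event))
    stray <- setdiff(stray, c(if (has_start) 1L, if (has_end) n))
    for (i in stray) add(i, "bracket event inside stream body")
    complete <- has_start && has_end && n >= 2 && length(stray) == 0
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(index = integer(), message = character(),
               stringsAsFactors = FALSE)
  list(complete = complete && nrow(violations) == 0, violations = violations)
}

#' Slice a stream down to one actor's events
#'
#' Individual indicators are computed from the unique process stream of a
#' single dyad member; this returns the sub-stream of events attributed
#' to that role, order preserved.
#'
#' @param stream a [cps_stream()].
#' @param role `"A"` or `"B"`.
#' @return a [cps_stream()] holding only that role's events.
#' @export
slice_role <- function(stream, role) {
  stopifnot(inherits(stream, "cps_stream"))
  if (!(is.character(role) && length(role) == 1 && role %in% c("A", "B")))
    stop("role must be 'A' or 'B'")
  cps_stream(stream$events[stream$events$role == role, , drop = FALSE],
             group_id = stream$group_id, task_id = stream$task_id)
}
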