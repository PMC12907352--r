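# Event logs: timestamped coded behavior events, one row per event.

#' Construct an event log
#'
#' An event log is the tabular form of a coded behavior stream: one row per
#' behavior event with onset/offset in seconds from session start. Intervals
#' are half-open `[onset, offset)`. Events are validated against the alphabet,
#' sorted by `(child_id, session, onset, offset)`, and checked for within-
#' session overlap.
#'
#' @param events Data frame with columns `child_id`, `session`, `category`,
#'   `onset`, `offset` (seconds).
#' @param alphabet A [behavior_alphabet()].
#' @param check Validate invariants (default `TRUE`).
#' @return An `event_log` data frame carrying the alphabet as an attribute.
#' @examples
#' ab <- behavior_alphabet()
#' ev <- data.frame(child_id = "c1", session = 1,
#'                  category = c("avoidance", "joint_attention"),
#'                  onset = c(0, 5), offset = c(4, 7))
#' event_log(ev, ab)
#' @export
event_log <- function(events, alphabet = behavior_alphabet(), check = TRUE) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("child_id", "session", "category", "onset", "offset")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event log is missing column(s): ", paste(miss, collapse = ", "))
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)
  if (check && nrow(events)) {
    .check_codes(events$category, alphabet)
    bad <- which(!(events$offset > events$onset))
    if (length(bad))
      stop("offset must exceed onset (half-open intervals); bad row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  o <- order(events$child_id, events$session, events$onset, events$offset)
  events <- events[o, req, drop = FALSE]
  rownames(events) <- NULL
  if (check && nrow(events) > 1) {
    same <- events$child_id[-1] == events$child_id[-nrow(events)] &
      events$session[-1] == events$session[-nrow(events)]
    ovl <- which(same & events$onset[-1] < events$offset[-nrow(events)])
    if (length(ovl))
      stop("overlapping events within a child/session at sorted row(s): ",
           paste(utils::head(ovl + 1L, 5), collapse = ", "))
  }
  structure(events, alphabet = alphabet, class = c("event_log", "data.frame"))
}

#' @export
print.event_log <- function(x, ...) {
  cat("Event log: ", nrow(x), " events, ",
      length(unique(paste(x$child_id, x$session))), " child-session(s), ",
      alphabet_size(attr(x, "alphabet")), "-category alphabet\n", sep = "")
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read an event log from a delimited file
#'
#' Expects a header `child_id,session,category,onset_s,offset_s`. Unknown
#' categories and degenerate intervals are reported with their row numbers.
#'
#' @param path File path (CSV by default).
#' @param alphabet A [behavior_alphabet()].
#' @param sep Field separator (default `","`).
#' @return An [event_log()].
#' @export
read_event_log <- function(path, alphabet = behavior_alphabet(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("child_id", "session", "category", "onset_s", "offset_s")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("event file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(raw$category), alphabet$code)
  if (length(bad))
    stop("event file contains categories not in the alphabet: ",
         paste(bad, collapse = ", "))
  deg <- which(!(as.numeric(raw$offset_s) > as.numeric(raw$onset_s)))
  if (length(deg))
    stop("offset_s <= onset_s at data row(s): ", paste(deg, collapse = ", "))
  event_log(data.frame(child_id = raw$child_id, session = raw$session,
                       category = raw$category, onset = raw$onset_s,
                       offset = raw$offset_s, stringsAsFactors = FALSE),
            alphabet)
}

#' Write an event log to a delimited file
#' @param log An [event_log()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, sep = ",") {
  out <- data.frame(child_id = log$child_id, session = log$session,
                    category = log$category, onset_s = log$onset,
                    offset_s = log$offset)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge fragmented events and enforce minimum durations
#'
#' Preprocessing for coded streams: consecutive events of the same category
#' within a child/session whose gap is below `min_interval` are merged into a
#' single event spanning both; events shorter than their category's minimum
#' codable duration are then dropped. Merging precedes filtering so that a
#' long behavior fragmented by sub-threshold coding gaps survives. The
#' operation is idempotent.
#'
#' @param log An [event_log()].
#' @param min_interval Merge threshold in seconds (default 0.5).
#' @return A preprocessed [event_log()].
#' @export
segment_events <- function(log, min_interval = 0.5) {
  if (min_interval < 0) stop("min_interval must be >= 0")
  alphabet <- attr(log, "alphabet")
  if (!nrow(log)) return(log)
  pieces <- split(as.data.frame(log), paste(log$child_id, log$session, sep = "\r"))
  merged <- lapply(pieces, function(d) {
    d <- d[order(d$onset), , drop = FALSE]
    keep <- list()
    cur <- d[1, ]
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      nxt <- d[i, ]
      gap <- nxt$onset - cur$offset
      if (nxt$category == cur$category && gap < min_interval) {
        cur$offset <- max(cur$offset, nxt$offset)
      } else {
        keep[[length(keep) + 1L]] <- cur
        cur <- nxt
      }
    }
    keep[[length(keep) + 1L]] <- cur
    do.call(rbind, keep)
  })
  out <- do.call(rbind, merged)
  mind <- alphabet$min_duration[match(out$category, alphabet$code)]
  out <- out[(out$offset - out$onset) >= mind, , drop = FALSE]
  event_log(out, alphabet)
}

#' Duration summary for one behavior category
#'
#' Computes the mean duration `T = sum(D_i)/N` over the `N` events of the
#' category, with the individual durations retained.
#'
#' @param log An [event_log()].
#' @param category Category code.
#' @return A list of class `duration_summary` with elements `category`, `T`
#'   (mean seconds; `NA` with `undefined = TRUE` when no events), `N`, and
#'   `durations`.
#' @export
mean_duration <- function(log, category) {
  alphabet <- attr(log, "alphabet")
  .check_codes(category, alphabet)
  d <- log$offset[log$category == category] - log$onset[log$category == category]
  structure(list(category = category,
                 T = if (length(d)) mean(d) else NA_real_,
                 N = length(d), durations = d,
                 undefined = length(d) == 0L),
            class = "duration_summary")
}

#' @export
print.duration_summary <- function(x, ...) {
  if (x$undefined)
    cat("Duration summary [", x$category, "]: no events (T undefined)\n", sep = "")
  else
    cat("Duration summary [", x$category, "]: T = ",
        format(x$T, digits = 4), " s over N = ", x$N, " events\n", sep = "")
  invisible(x)
}

#' Total coded time in a log
#' @param log An [event_log()].
#' @return Total event duration in seconds.
#' @export
total_coded_time <- function(log) sum(log$offset - log$onset)
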