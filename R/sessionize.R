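## Sessionization: a session is a maximal run of one user's events with no
## inactivity gap exceeding a threshold. The default threshold of 60 minutes
## is deliberately generous, to allow for users re-watching videos or
## composing long textual entries without the pause being counted as
## absence.

#' Segment event streams into sessions
#'
#' Splits each user's time-sorted events wherever the gap to the previous
#' event is *strictly greater* than the threshold ("longer than" the
#' threshold; a gap exactly equal to it does not split). Sessions may span
#' midnight — the calendar plays no role in segmentation.
#'
#' @param events A data frame with `user_id` and `timestamp` (POSIXct)
#'   columns, time-sorted within user (as produced by [read_event_log()]).
#' @param gap_minutes Inactivity threshold in minutes; must be > 0.
#'   Default 60.
#' @return The input tibble with an integer `session_index` column
#'   (1-based, per user, in time order) appended.
#' @examples
#' ev <- tibble::tibble(
#'   user_id = "u1",
#'   timestamp = as.POSIXct("2012-03-08 12:00", tz = "UTC") +
#'     60 * c(0, 59, 120),
#'   event_id = ""
#' )
#' sessionize(ev)  # 59-min gap keeps, 61-min gap splits
#' @export
sessionize <- function(events, gap_minutes = 60) {
  stopifnot(is.numeric(gap_minutes), length(gap_minutes) == 1, gap_minutes > 0)
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) {
    events$session_index <- integer(0)
    return(events)
  }
  check_sorted(events)
  events |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      session_index = 1L + cumsum(
        as.integer(c(FALSE, diff(as.numeric(.data$timestamp)) / 60 > gap_minutes))
      )
    ) |>
    dplyr::ungroup()
}

check_sorted <- function(events) {
  unsorted <- events |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!unsorted$ok)) {
    stop("events not time-sorted within user(s): ",
         paste(unsorted$user_id[!unsorted$ok], collapse = ", "),
         " — sort by (timestamp, input row) first", call. = FALSE)
  }
  invisible(events)
}

#' Usage days per user
#'
#' The set of day offsets on which a user touched the system: the calendar
#' difference in days between an event's date and the date of that user's
#' first event. Day 0 is always present for a user with any events. A
#' session spanning midnight contributes both dates.
#'
#' @param events A data frame with `user_id` and `timestamp` columns.
#' @return A tibble `(user_id, day)` with one row per (user, used day),
#'   sorted; `day` is a non-negative integer offset.
#' @export
usage_days <- function(events) {
  tibble::as_tibble(events) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(day = as.integer(as.Date(.data$timestamp) -
                                     min(as.Date(.data$timestamp)))) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$user_id, .data$day) |>
    dplyr::arrange(.data$user_id, .data$day)
}

#' Glance at a sessionized log
#'
#' @param x A tibble of labeled, sessionized events.
#' @param ... Unused.
#' @return A one-row tibble: users, events, sessions, distinct usage days,
#'   and unmapped-event count.
#' @export
glance.engagement_log <- function(x, ...) {
  sessions <- if ("session_index" %in% names(x)) {
    nrow(dplyr::distinct(x, .data$user_id, .data$session_index))
  } else NA_integer_
  tibble::tibble(
    n_users = length(unique(x$user_id)),
    n_events = nrow(x),
    n_sessions = sessions,
    n_usage_days = nrow(usage_days(x)),
    n_unmapped = if ("kind" %in% names(x)) sum(x$kind == "unmapped") else NA_integer_
  )
}

#' Full log preparation: read, label, sessionize
#'
#' Convenience wrapper chaining [read_event_log()], [label_events()] and
#' [sessionize()]; returns a tibble carrying the `engagement_log` class so
#' [glance()] reports a cohort summary.
#'
#' @inheritParams read_event_log
#' @inheritParams label_events
#' @inheritParams sessionize
#' @param log Path to the raw log, or an already-read events data frame.
#' @param key Path to the key file, or a [keymap()].
#' @return A labeled, sessionized tibble of events.
#' @export
prepare_log <- function(log, key, gap_minutes = 60, strict = FALSE, ...) {
  events <- if (is.data.frame(log)) tibble::as_tibble(log) else read_event_log(log, ...)
  if (!inherits(key, "keymap")) key <- read_key_file(key)
  out <- sessionize(label_events(events, key, strict = strict), gap_minutes)
  class(out) <- c("engagement_log", class(out))
  attr(out, "keymap") <- key
  out
}
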