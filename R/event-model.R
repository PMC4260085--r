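## Raw-log ingestion and view-table spreadsheet I/O.
##
## A raw log is one row per logged action: user identifier, timestamp, event
## identifier (typically a URL path; may be empty — the platform landing
## page is logged with a blank URL). Timestamps default to the day-first
## "DD/MM/YYYY HH:MM" dialect common in UK-originated logs; ISO-8601 is
## accepted automatically.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return(",")
  if (stringr::str_count(header, "\t") > stringr::str_count(header, ",")) "\t" else ","
}

## Parse character timestamps: ISO-8601 first, then the configured dialect.
## Returns POSIXct (naive local time, no zone conversion).
parse_timestamps <- function(x, date_format = "%d/%m/%Y %H:%M") {
  x <- stringr::str_trim(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  iso <- stringr::str_detect(x, "^\\d{4}-\\d{2}-\\d{2}[ T]")
  if (any(iso, na.rm = TRUE)) {
    w <- which(iso)
    out[w] <- as.POSIXct(x[w], tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                        "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M"))
  }
  w <- which(!iso | is.na(iso))
  if (length(w)) out[w] <- as.POSIXct(x[w], format = date_format, tz = "UTC")
  out
}

#' Read a raw event log
#'
#' Reads a delimited log (comma or tab, auto-detected), resolves the three
#' required columns, parses timestamps, and sorts each user's events by
#' time with input order breaking ties (same-minute rows are common at
#' minute resolution and their order is meaningful).
#'
#' @param path Path to the log file.
#' @param columns Named character vector resolving the required fields to
#'   header names; defaults `c(user_id = "id", timestamp = "datetime",
#'   event_id = "url")`.
#' @param date_format `strptime` format for non-ISO timestamps; default
#'   day-first `"%d/%m/%Y %H:%M"`. ISO-8601 rows are parsed regardless.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @return A tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct), `event_id` (character; empty string is a valid identifier)
#'   and `.row` (original row number), grouped by user and sorted by
#'   `(timestamp, .row)` within user. Rows whose timestamp cannot be parsed
#'   are dropped, collected in the `parse_errors` attribute (a tibble of
#'   row numbers and offending values), and reported as a warning.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,datetime,url", "8,08/03/2012 12:47,bns/main/"), f)
#' read_event_log(f)
#' @export
read_event_log <- function(path,
                           columns = c(user_id = "id", timestamp = "datetime",
                                       event_id = "url"),
                           date_format = "%d/%m/%Y %H:%M",
                           delim = NULL) {
  if (!file.exists(path)) stop("log file not found: ", path, call. = FALSE)
  defaults <- c(user_id = "id", timestamp = "datetime", event_id = "url")
  columns <- c(columns, defaults[setdiff(names(defaults), names(columns))])
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
  for (field in names(defaults)) {
    if (!columns[[field]] %in% names(raw)) {
      stop("log file ", path, " is missing required column '",
           columns[[field]], "' (", field, ")", call. = FALSE)
    }
  }
  events <- tibble::tibble(
    user_id = raw[[columns[["user_id"]]]],
    timestamp = parse_timestamps(raw[[columns[["timestamp"]]]], date_format),
    event_id = raw[[columns[["event_id"]]]],
    .row = seq_len(nrow(raw))
  )
  bad <- is.na(events$timestamp)
  errors <- tibble::tibble(row = events$.row[bad],
                           value = raw[[columns[["timestamp"]]]][bad])
  if (nrow(errors)) {
    warning(nrow(errors), " row(s) with unparseable timestamps dropped (rows ",
            paste(utils::head(errors$row, 5), collapse = ", "),
            if (nrow(errors) > 5) ", ..." else "", ")", call. = FALSE)
    events <- events[!bad, ]
  }
  events <- dplyr::arrange(events, .data$user_id, .data$timestamp, .data$.row)
  attr(events, "parse_errors") <- errors
  events
}

## Column schemas for the four view spreadsheets, so a written file can be
## read back with value-identical types.
view_schemas <- list(
  navigation = readr::cols(
    user_id = "c", step = "i", session_index = "i", kind = "c",
    label = "c", ordinal = "i", category = "c"
  ),
  stripe = readr::cols(user_id = "c", day = "i", used = "l"),
  start_finish = readr::cols(
    user_id = "c", session_index = "i",
    start_label = "c", end_label = "c",
    start_ordinal = "i", end_ordinal = "i",
    start_module = "i", end_module = "i"
  ),
  next_action = readr::cols(
    from_index = "i", from_state = "c", from_kind = "c",
    to_index = "i", to_state = "c", to_kind = "c",
    count = "i", prob = "d"
  )
)

view_kind <- function(view) {
  kinds <- c(navigation = "nav_view", stripe = "stripe_view",
             start_finish = "start_finish_view", next_action = "next_action_view")
  hit <- names(kinds)[vapply(kinds, function(cl) inherits(view, cl), logical(1))]
  if (length(hit) != 1) stop("not a recognized view table", call. = FALSE)
  hit
}

#' Write / read a view table spreadsheet
#'
#' Each of the four views is backed by a plain table written as CSV so the
#' intermediate products can be checked for correctness, archived, or fed to
#' other tools. A written file reads back value-identical.
#'
#' @param view A view table from [navigation_view()], [stripe_view()],
#'   [start_finish_view()] or [next_action_view()].
#' @param path Output (input) CSV path.
#' @return `write_view_table` returns `path` invisibly; `read_view_table`
#'   returns the view tibble with its view class restored.
#' @export
write_view_table <- function(view, path) {
  kind <- view_kind(view)
  out <- tibble::as_tibble(view)
  class(out) <- class(tibble::tibble())
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_view_table
#' @param kind One of `"navigation"`, `"stripe"`, `"start_finish"`,
#'   `"next_action"`; `NULL` infers it from the file's header columns.
#' @export
read_view_table <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("view table not found: ", path, call. = FALSE)
  if (is.null(kind)) {
    header <- strsplit(readLines(path, n = 1L, warn = FALSE), ",")[[1]]
    match_n <- vapply(view_schemas, function(sc) {
      all(header %in% names(sc$cols)) && all(names(sc$cols) %in% header)
    }, logical(1))
    if (!any(match_n)) stop("cannot infer view kind from columns of ", path,
                            call. = FALSE)
    kind <- names(view_schemas)[which(match_n)[1]]
  }
  kind <- match.arg(kind, names(view_schemas))
  out <- readr::read_csv(path, col_types = view_schemas[[kind]],
                         na = "NA", progress = FALSE)
  classes <- c(navigation = "nav_view", stripe = "stripe_view",
               start_finish = "start_finish_view", next_action = "next_action_view")
  class(out) <- c(classes[[kind]], class(out))
  out
}
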