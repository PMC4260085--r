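## The four visualization-backing tables. All constructors take labeled,
## sessionized events (see prepare_log()) and return plain tibbles carrying
## a view class so autoplot()/render_view()/write_view_table() dispatch.

included_events <- function(events, content_only = FALSE) {
  keep <- events$kind == "content" |
    (!content_only & events$kind == "feature" & events$category != "Home")
  events[keep, , drop = FALSE]
}

new_view <- function(df, class, ...) {
  out <- tibble::as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(tibble::tibble()))
  out
}

#' Navigation trace
#'
#' The per-user sequence backing the navigation graph: every content page
#' viewed or app used, in temporal order, tagged with its session so a
#' renderer can demarcate sessions by space and color. Home (landing page)
#' events and unmapped events are excluded; consecutive repeats of the same
#' page are retained — repetition of content is signal, not noise.
#'
#' @param events Labeled, sessionized events ([prepare_log()]).
#' @param key Optional [keymap()]; fixes the content-axis height for
#'   rendering (otherwise inferred from the data).
#' @return A `nav_view` tibble: `user_id`, `step` (0-based position among
#'   that user's included events), `session_index`, `kind`, `label`,
#'   `ordinal` (content rows), `category` (feature rows).
#' @export
navigation_view <- function(events, key = NULL) {
  if (is.null(key)) key <- attr(events, "keymap")
  inc <- included_events(tibble::as_tibble(events)) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(step = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("user_id", "step", "session_index", "kind",
                  "label", "ordinal", "category")
  n_content <- if (!is.null(key)) nrow(key$content) else
    max(c(inc$ordinal, -1L), na.rm = TRUE) + 1L
  new_view(inc, "nav_view", n_content = n_content)
}

#' Stripe matrix
#'
#' The per-cohort usage calendar backing the stripe graph: for every user
#' and every day offset 0..D (D = latest usage day in the cohort), whether
#' the user touched the system that day. Users are ordered by first-event
#' date, then user id. The formally supported treatment period (default 56
#' days = 8 weeks) is carried as an attribute so renderers can mark it;
#' usage beyond it is common and retained.
#'
#' @param events Events with `user_id` and `timestamp` columns.
#' @param period_end Day index of the formal treatment-period end
#'   (default 56).
#' @return A `stripe_view` tibble `(user_id, day, used)` over the full
#'   user x day grid, with attributes `period_end` and `user_order`.
#' @export
stripe_view <- function(events, period_end = 56) {
  events <- tibble::as_tibble(events)
  days <- usage_days(events)
  user_order <- events |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(first_event = min(.data$timestamp), .groups = "drop") |>
    dplyr::arrange(.data$first_event, .data$user_id) |>
    dplyr::pull("user_id")
  d_max <- if (nrow(days)) max(days$day) else 0L
  grid <- tidyr::expand_grid(user_id = user_order, day = 0:d_max) |>
    dplyr::left_join(dplyr::mutate(days, used = TRUE),
                     by = c("user_id", "day")) |>
    dplyr::mutate(used = !is.na(.data$used))
  new_view(grid, "stripe_view", period_end = period_end, user_order = user_order)
}

#' Start-finish rows
#'
#' One row per session with at least one content event: the first and last
#' content page viewed in the session (by time — the "finish" page is the
#' last viewed, not the furthest along). Rows are sorted by module of the
#' finishing page, then its ordinal, with ties broken by user id and
#' session index for reproducible output.
#'
#' @param events Labeled, sessionized events ([prepare_log()]).
#' @return A `start_finish_view` tibble: `user_id`, `session_index`,
#'   `start_label`, `end_label`, `start_ordinal`, `end_ordinal`,
#'   `start_module`, `end_module`.
#' @export
start_finish_view <- function(events) {
  rows <- tibble::as_tibble(events) |>
    dplyr::filter(.data$kind == "content") |>
    dplyr::group_by(.data$user_id, .data$session_index) |>
    dplyr::summarise(
      start_label = dplyr::first(.data$label),
      end_label = dplyr::last(.data$label),
      start_ordinal = dplyr::first(.data$ordinal),
      end_ordinal = dplyr::last(.data$ordinal),
      start_module = dplyr::first(.data$module),
      end_module = dplyr::last(.data$module),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$end_module, .data$end_ordinal,
                   .data$user_id, .data$session_index)
  new_view(rows, "start_finish_view")
}

## State axes of the transition matrix: content ordinals 0..K-1 followed by
## the five app categories as extra indices K..K+4.
transition_states <- function(key, include_apps = TRUE) {
  states <- tibble::tibble(
    index = key$content$ordinal,
    state = key$content$label,
    kind = "content"
  )
  if (include_apps) {
    states <- dplyr::bind_rows(states, tibble::tibble(
      index = nrow(key$content) + seq_along(.stripe_lanes) - 1L,
      state = .stripe_lanes,
      kind = "feature"
    ))
  }
  states
}

#' Next-action transition matrix
#'
#' Counts, for every content page (and optionally every app category), how
#' often the next included action was each other page or app, and the
#' row-normalized empirical likelihoods. Transitions are counted between
#' consecutive included events within each session only — returning days
#' later is not a click. A cohort navigating strictly linearly puts all
#' mass on the one-off diagonal (the "red diagonal from the lower left" of
#' the rendered heat map).
#'
#' @param events Labeled, sessionized events ([prepare_log()]).
#' @param key A [keymap()] (taken from the events' attribute if absent);
#'   defines the content axes 0..K-1.
#' @param include_apps If `TRUE` (default), the five app categories are
#'   appended as extra indices after the content ordinals; if `FALSE`, the
#'   matrix is content x content and pairs are re-formed over content
#'   events only.
#' @param across_sessions If `TRUE`, also count the pair spanning each
#'   session boundary (off by default; documented as a deliberately
#'   different question).
#' @param collapse_repeats If `TRUE`, merge consecutive duplicates of the
#'   same state before pairing, removing the self-transition diagonal.
#' @param per_user_average If `TRUE`, compute each user's probability
#'   matrix separately and average them (counts are then summed raw but
#'   `prob` is the mean of per-user rows); default pools all transitions.
#' @return A `next_action_view` tibble over the full state x state grid:
#'   `from_index`, `from_state`, `from_kind`, `to_index`, `to_state`,
#'   `to_kind`, `count`, `prob`. Rows with no outgoing transitions have
#'   `prob` 0.
#' @export
next_action_view <- function(events, key = NULL, include_apps = TRUE,
                             across_sessions = FALSE, collapse_repeats = FALSE,
                             per_user_average = FALSE) {
  if (is.null(key)) key <- attr(events, "keymap")
  if (is.null(key)) stop("next_action_view() needs a keymap for its axes",
                         call. = FALSE)
  states <- transition_states(key, include_apps)
  inc <- included_events(tibble::as_tibble(events), content_only = !include_apps)
  inc$state <- ifelse(inc$kind == "content", inc$label, inc$category)
  inc$state_index <- states$index[match(inc$state, states$state)]

  unit <- if (across_sessions) c("user_id") else c("user_id", "session_index")
  pairs <- inc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::group_modify(function(g, ...) {
      s <- g$state_index
      if (collapse_repeats) s <- s[c(TRUE, diff(s) != 0)]
      if (length(s) < 2) return(tibble::tibble(from = integer(0), to = integer(0)))
      tibble::tibble(from = s[-length(s)], to = s[-1])
    }) |>
    dplyr::ungroup()

  grid <- tidyr::expand_grid(from_index = states$index, to_index = states$index)
  counts <- pairs |>
    dplyr::count(.data$user_id, .data$from, .data$to, name = "count")

  if (per_user_average && nrow(counts)) {
    per_user <- counts |>
      dplyr::group_by(.data$user_id, .data$from) |>
      dplyr::mutate(prob = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
    n_users <- length(unique(counts$user_id))
    probs <- per_user |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(prob = sum(.data$prob) / n_users, .groups = "drop")
  } else {
    probs <- NULL
  }

  pooled <- counts |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out <- grid |>
    dplyr::left_join(pooled, by = c(from_index = "from", to_index = "to")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$from_index) |>
    dplyr::mutate(prob = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else 0) |>
    dplyr::ungroup()
  if (!is.null(probs)) {
    out <- out |>
      dplyr::select(-"prob") |>
      dplyr::left_join(probs, by = c(from_index = "from", to_index = "to")) |>
      dplyr::mutate(prob = dplyr::coalesce(.data$prob, 0))
  }
  out <- out |>
    dplyr::left_join(stats::setNames(states, c("from_index", "from_state", "from_kind")),
                     by = "from_index") |>
    dplyr::left_join(stats::setNames(states, c("to_index", "to_state", "to_kind")),
                     by = "to_index") |>
    dplyr::select("from_index", "from_state", "from_kind",
                  "to_index", "to_state", "to_kind", "count", "prob")
  new_view(out, "next_action_view", states = states)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a transition matrix
#'
#' @param x A `next_action_view`.
#' @param ... Unused.
#' @return The nonzero transitions as a plain tibble, highest count first.
#' @export
tidy.next_action_view <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  dplyr::arrange(dplyr::filter(out, .data$count > 0), dplyr::desc(.data$count))
}

#' Transition matrix as a base matrix
#'
#' @param x A `next_action_view`.
#' @param value `"count"` or `"prob"`.
#' @param ... Unused.
#' @return A square matrix with states as dimnames, `from` in rows.
#' @export
as.matrix.next_action_view <- function(x, value = c("count", "prob"), ...) {
  value <- match.arg(value)
  states <- attr(x, "states")
  m <- matrix(0, nrow(states), nrow(states),
              dimnames = list(from = states$state, to = states$state))
  m[cbind(x$from_index + 1L, x$to_index + 1L)] <- x[[value]]
  m
}
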