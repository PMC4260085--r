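## Synthetic intervention-log generator. Emulates the structure of real
## e-health platform logs — ordered content modules, interleaved feature
## events, sessions separated by inactivity, multi-week usage — with known
## ground truth, so the whole pipeline is testable without access to any
## real cohort. Inter-session gaps are sampled bounded away from the
## 60-minute threshold (within-session gaps <= 45 min, between-session
## gaps >= 90 min) so that session recovery is exact, not probabilistic.

.archetypes <- c("linear_completer", "repeater", "app_focused", "burst_user")

#' Synthetic cohort configuration
#'
#' Defaults mirror a typical 8-week guided intervention: 8 content modules
#' numbered 0-7 (0 an introduction, 6-7 review/optional), each with an
#' intro label plus 3 subsections of 2 pages (56 content labels in all), a
#' 70-day observation period (use continues beyond the formally supported
#' 56 days), about 2 sessions per week, and an even mix of four usage
#' archetypes: the linear completer (content in strictly increasing
#' ordinal order), the repeater (returns to earlier modules), the
#' app-focused user (at least 70% feature events, nonlinear content), and
#' the burst user (sessions concentrated in 2-4 day clusters separated by
#' at least a quiet week).
#'
#' @param n_users Number of users.
#' @param modules,subsections,pages Content structure: modules are numbered
#'   `0:(modules-1)`; each has one intro label plus
#'   `subsections x pages` page labels.
#' @param period_days Observation period in days.
#' @param archetype_mix Named proportions over the four archetypes; must
#'   sum to 1.
#' @param sessions_per_week Expected session rate for non-burst users.
#' @param session_length Integer range (min, max) of content+app events per
#'   session.
#' @param app_rate Fraction of a session's events that are app events
#'   (0.75 for `app_focused` users regardless).
#' @param unmapped_rate Per-session probability of one stray, unmapped URL.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_users = 20,
                         modules = 8, subsections = 3, pages = 2,
                         period_days = 70,
                         archetype_mix = c(linear_completer = 0.25,
                                           repeater = 0.25,
                                           app_focused = 0.25,
                                           burst_user = 0.25),
                         sessions_per_week = 2,
                         session_length = c(5, 20),
                         app_rate = 0.3,
                         unmapped_rate = 0.02,
                         seed = NULL) {
  stopifnot(n_users >= 0, modules >= 1, subsections >= 1, pages >= 1,
            period_days >= 1, sessions_per_week > 0,
            length(session_length) == 2, session_length[1] >= 1,
            session_length[2] >= session_length[1],
            app_rate >= 0, app_rate <= 1)
  if (!setequal(names(archetype_mix), .archetypes) ||
      any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix must be non-negative proportions over {",
         paste(.archetypes, collapse = ", "), "} summing to 1", call. = FALSE)
  }
  structure(list(n_users = as.integer(n_users), modules = as.integer(modules),
                 subsections = as.integer(subsections), pages = as.integer(pages),
                 period_days = as.integer(period_days),
                 archetype_mix = archetype_mix[.archetypes],
                 sessions_per_week = sessions_per_week,
                 session_length = as.integer(session_length),
                 app_rate = app_rate, unmapped_rate = unmapped_rate,
                 seed = seed),
            class = "synth_config")
}

## Key table for the synthetic platform: one URL per content label plus a
## handful of feature URLs per category.
synth_key_table <- function(config) {
  labels <- character(0)
  patterns <- character(0)
  for (m in 0:(config$modules - 1)) {
    labels <- c(labels, as.character(m))
    patterns <- c(patterns, sprintf("content/m%d/", m))
    for (s in seq_len(config$subsections)) {
      for (p in 0:(config$pages - 1)) {
        labels <- c(labels, sprintf("%d.%d.%d", m, s, p))
        patterns <- c(patterns, sprintf("content/m%d/s%d/p%d/", m, s, p))
      }
    }
  }
  features <- tibble::tibble(
    pattern = c("apps/ex/i", "apps/ex/addItem", "apps/mind/", "journal/",
                "journal/add/", "apps/review/", "bns/main/", "quiz/start/"),
    label = c("Exercise", "Exercise", "Mindfulness", "Journal",
              "Journal", "Review", "Other", "Other")
  )
  dplyr::bind_rows(tibble::tibble(pattern = patterns, label = labels), features)
}

feature_urls <- list(
  Exercise = c("apps/ex/i", "apps/ex/addItem"),
  Mindfulness = "apps/mind/",
  Journal = c("journal/", "journal/add/"),
  Review = "apps/review/",
  Other = c("bns/main/", "quiz/start/")
)

## Session-day schedule per archetype, as day offsets (may repeat: several
## sessions on one day).
schedule_days <- function(archetype, config) {
  if (archetype == "burst_user") {
    days <- integer(0)
    cur <- sample(0:3, 1)
    while (cur < config$period_days) {
      len <- sample(2:4, 1)
      cluster <- cur + seq_len(len) - 1L
      cluster <- cluster[cluster < config$period_days]
      days <- c(days, rep(cluster, times = sample(1:2, length(cluster),
                                                  replace = TRUE)))
      cur <- cur + len + 7L + sample(0:7, 1)
    }
    if (length(days) == 0) days <- 0L
    sort(days)
  } else {
    n <- max(1L, round(config$sessions_per_week * config$period_days / 7))
    sort(sample(0:(config$period_days - 1), n, replace = TRUE))
  }
}

## Content ordinals for one session; state$pos is the linear progress
## pointer. Returns list(ordinals, state).
session_content <- function(archetype, n_content, state, K) {
  if (n_content == 0) return(list(ordinals = integer(0), state = state))
  if (archetype == "app_focused") {
    return(list(ordinals = sample(0:(K - 1), n_content, replace = TRUE),
                state = state))
  }
  take <- min(n_content, K - state$pos)
  fresh <- if (take > 0) state$pos + seq_len(take) - 1L else integer(0)
  state$pos <- state$pos + take
  ords <- fresh
  if (archetype == "repeater" && state$pos > 4 && stats::runif(1) < 0.4) {
    block_start <- sample(0:max(0, state$pos - 4), 1)
    revisit <- block_start + 0:min(3, state$pos - block_start - 1)
    ords <- c(revisit, fresh)
  }
  list(ordinals = ords, state = state)
}

#' Generate a synthetic cohort
#'
#' Emits a raw event stream, the matching key map, and the generator's
#' ground truth: per-user archetypes, true session boundaries and
#' per-session first/last content labels, and true usage days (computed on
#' the generator's own minute clock, independently of the ingestion path).
#' Fixed seeds reproduce streams exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort`: `events` (tibble `user_id`,
#'   `timestamp`, `event_id`), `key` (a [keymap()]), `key_table` (the
#'   pattern/label tibble behind it), `ground_truth` (list of tibbles
#'   `users`, `sessions`, `days`), and `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  key_table <- synth_key_table(config)
  key <- keymap(key_table)
  K <- nrow(key$content)
  ordinal_url <- key$entries$pattern[key$entries$kind == "content"][
    match(key$content$label,
          key$entries$label[key$entries$kind == "content"])]
  origin <- as.POSIXct("2024-01-08 00:00:00", tz = "UTC")

  users <- sessions_gt <- days_gt <- ev <- list()
  for (u in seq_len(config$n_users)) {
    uid <- sprintf("u%03d", u)
    archetype <- sample(.archetypes, 1, prob = config$archetype_mix)
    day_sched <- schedule_days(archetype, config)
    state <- list(pos = 0L)
    prev_end <- -Inf
    u_minutes <- integer(0)
    u_urls <- character(0)
    s_rows <- list()
    for (si in seq_along(day_sched)) {
      start <- day_sched[si] * 1440 + sample(480:1260, 1)
      if (start < prev_end + 90) start <- prev_end + 90 + sample(0:30, 1)
      n <- sample(config$session_length[1]:config$session_length[2], 1)
      share <- if (archetype == "app_focused") 0.75 else config$app_rate
      n_app <- if (archetype == "app_focused") ceiling(share * n) else round(share * n)
      n_content <- n - n_app
      sc <- session_content(archetype, n_content, state, K)
      state <- sc$state
      cats <- sample(names(feature_urls), n_app, replace = TRUE,
                     prob = c(0.3, 0.15, 0.3, 0.1, 0.15))
      app_urls <- vapply(cats, function(cc) sample(feature_urls[[cc]], 1), "")
      n_total <- length(sc$ordinals) + n_app
      if (n_total == 0) { app_urls <- "journal/"; n_total <- 1L; n_app <- 1L }
      slots <- sort(sample(n_total, length(sc$ordinals)))
      urls <- character(n_total)
      urls[slots] <- ordinal_url[sc$ordinals + 1L]
      urls[setdiff(seq_len(n_total), slots)] <- app_urls
      if (stats::runif(1) < 0.5) urls <- c("", urls)          # landing page
      if (stats::runif(1) < config$unmapped_rate) {
        urls <- append(urls, sprintf("stray/%d/", sample.int(10000L, 1)),
                       after = sample(length(urls), 1))
      }
      gaps <- sample(0:8, length(urls) - 1, replace = TRUE,
                     prob = c(0.35, rep(0.65 / 8, 8)))
      minutes <- start + cumsum(c(0L, gaps))
      content_labels <- key$content$label[sc$ordinals + 1L]
      s_rows[[si]] <- tibble::tibble(
        user_id = uid, session_index = si,
        start_minute = minutes[1], end_minute = minutes[length(minutes)],
        n_events = length(urls),
        first_content = if (length(content_labels)) content_labels[1] else NA_character_,
        last_content = if (length(content_labels)) content_labels[length(content_labels)] else NA_character_
      )
      u_minutes <- c(u_minutes, minutes)
      u_urls <- c(u_urls, urls)
      prev_end <- minutes[length(minutes)]
    }
    day0 <- u_minutes[1] %/% 1440
    users[[u]] <- tibble::tibble(user_id = uid, archetype = archetype)
    sessions_gt[[u]] <- dplyr::bind_rows(s_rows)
    days_gt[[u]] <- tibble::tibble(
      user_id = uid,
      day = as.integer(sort(unique(u_minutes %/% 1440 - day0))))
    ev[[u]] <- tibble::tibble(user_id = uid,
                              timestamp = origin + 60 * u_minutes,
                              event_id = u_urls)
  }

  empty_sessions <- tibble::tibble(
    user_id = character(0), session_index = integer(0),
    start_minute = numeric(0), end_minute = numeric(0), n_events = integer(0),
    first_content = character(0), last_content = character(0))
  structure(list(
    events = if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(user_id = character(0),
                     timestamp = as.POSIXct(character(0), tz = "UTC"),
                     event_id = character(0)),
    key = key, key_table = key_table,
    ground_truth = list(
      users = if (length(users)) dplyr::bind_rows(users) else
        tibble::tibble(user_id = character(0), archetype = character(0)),
      sessions = if (length(sessions_gt)) dplyr::bind_rows(sessions_gt) else
        empty_sessions,
      days = if (length(days_gt)) dplyr::bind_rows(days_gt) else
        tibble::tibble(user_id = character(0), day = integer(0))
    ),
    config = config
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", x$config$n_users, " users, ",
      nrow(x$events), " events, ",
      nrow(x$ground_truth$sessions), " sessions\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the raw log, the key file, and the per-session ground truth as
#' three CSVs (`synthetic_log.csv`, `synthetic_key.csv`,
#' `synthetic_ground_truth.csv`) into `dir`.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_df <- tibble::tibble(
    id = cohort$events$user_id,
    datetime = format(cohort$events$timestamp, "%Y-%m-%d %H:%M"),
    url = cohort$events$event_id
  )
  paths <- file.path(dir, c("synthetic_log.csv", "synthetic_key.csv",
                            "synthetic_ground_truth.csv"))
  readr::write_csv(log_df, paths[1], progress = FALSE)
  readr::write_csv(cohort$key_table, paths[2], progress = FALSE)
  gt <- dplyr::left_join(cohort$ground_truth$sessions,
                         cohort$ground_truth$users, by = "user_id")
  readr::write_csv(gt, paths[3], progress = FALSE)
  invisible(paths)
}
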