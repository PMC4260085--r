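# Shared fixtures: a small key map, event builders, and independent oracles.

tiny_key_table <- function() {
  tibble::tibble(
    pattern = c("content/1/", "content/1/s1/p0/", "content/1/s1/p1/",
                "content/1/s2/p0/", "content/2/", "content/2/s1/p0/",
                "journal/", "apps/mind/", "apps/ex/i", "apps/review/",
                "quiz/"),
    label = c("1", "1.1.0", "1.1.1", "1.2.0", "2", "2.1.0",
              "Journal", "Mindfulness", "Exercise", "Review", "Other")
  )
}

tiny_key <- function() keymap(tiny_key_table())

# events at the given minute offsets from a fixed origin
make_events <- function(minutes, ids, user = "u1") {
  tibble::tibble(
    user_id = user,
    timestamp = as.POSIXct("2024-01-08 09:00:00", tz = "UTC") + 60 * minutes,
    event_id = ids,
    .row = seq_along(minutes)
  )
}

# a labeled+sessionized stream straight from urls and minute offsets
make_log <- function(minutes, ids, user = "u1", key = tiny_key(), gap = 60) {
  prepare_log(make_events(minutes, ids, user), key, gap_minutes = gap)
}

# independent O(n) reference sessionizer: explicit loop over gaps
ref_segment <- function(minutes, threshold) {
  if (length(minutes) == 0) return(integer(0))
  idx <- integer(length(minutes))
  idx[1] <- 1L
  for (i in seq_along(minutes)[-1]) {
    idx[i] <- idx[i - 1] + if (minutes[i] - minutes[i - 1] > threshold) 1L else 0L
  }
  idx
}

# brute-force within-session consecutive-pair enumeration
ref_pairs <- function(states, session_idx) {
  out <- list()
  for (s in unique(session_idx)) {
    v <- states[session_idx == s]
    if (length(v) >= 2) out[[as.character(s)]] <-
        data.frame(from = v[-length(v)], to = v[-1])
  }
  do.call(rbind, c(out, list(data.frame(from = character(0), to = character(0)))))
}

table1_expected_assignments <- function() {
  raw <- readr::read_csv(example_log("log"),
                         col_types = readr::cols(.default = "c"),
                         na = character())
  ifelse(is_content_label(raw$sequence_assignment),
         raw$sequence_assignment,
         normalize_category(raw$sequence_assignment))
}
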