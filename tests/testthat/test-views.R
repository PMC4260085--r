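# The four visualization-backing tables.
# tiny_key() content ordinals: 1->0, 1.1.0->1, 1.1.1->2, 1.2.0->3, 2->4, 2.1.0->5;
# app categories occupy indices 6..10 (Exercise, Mindfulness, Journal, Review, Other).

test_that("navigation trace drops Home and unmapped, keeps content/app order", {
  log <- make_log(c(0, 1, 2, 3), c("", "content/1/s1/p0/", "journal/", "who/knows/"))
  nav <- navigation_view(log)
  expect_equal(nrow(nav), 2)
  expect_equal(nav$step, c(0L, 1L))
  expect_equal(nav$ordinal[1], 1L)
  expect_equal(nav$category[2], "Journal")
})

test_that("consecutive duplicate content labels are retained as separate steps", {
  log <- make_log(c(0, 1, 2), rep("content/1/s1/p0/", 3))
  expect_equal(navigation_view(log)$step, 0:2)
})

test_that("transcribed excerpt's content trace follows the printed order", {
  log <- prepare_log(example_log("log"), read_key_file(example_log("key")))
  nav <- navigation_view(log)
  content <- nav$label[nav$kind == "content"]
  expect_equal(content[1:5], c("1", "1.0.1", "1.1.0", "1.1.0", "1.1.1"))
  # counting oracle: trace length = non-Home mapped events
  lab <- tibble::as_tibble(log)
  expect_equal(nrow(nav),
               sum(lab$kind == "content" |
                     (lab$kind == "feature" & lab$category != "Home")))
})

test_that("trace length matches the counting oracle on random synthetic users", {
  cohort <- generate_cohort(synth_config(n_users = 4, seed = 202))
  log <- prepare_log(cohort$events, cohort$key)
  nav <- navigation_view(log)
  lab <- tibble::as_tibble(log)
  for (u in unique(lab$user_id)) {
    expected <- sum((lab$kind == "content" |
                       (lab$kind == "feature" & lab$category != "Home")) &
                      lab$user_id == u)
    expect_equal(sum(nav$user_id == u), expected)
    expect_equal(sort(nav$step[nav$user_id == u]), seq_len(expected) - 1L)
  }
  # order preservation: ordinals equal content_ordinal of the labels
  cc <- nav[nav$kind == "content", ]
  expect_equal(cc$ordinal, content_ordinal(cc$label, cohort$key))
})

test_that("stripe matrix covers the full user x day grid with correct cells", {
  log1 <- make_log(c(0, 10), c("content/1/", "journal/"))
  sv <- stripe_view(log1)
  expect_equal(nrow(sv), 1)
  expect_true(all(sv$used))

  # burst-like usage days {0,1,2,20,21,60}
  mins <- c(0, 1440, 2880, 20 * 1440, 21 * 1440, 60 * 1440)
  sv2 <- stripe_view(make_events(mins, rep("x/", 6)))
  expect_equal(nrow(sv2), 61)
  expect_equal(sv2$day[sv2$used], c(0L, 1L, 2L, 20L, 21L, 60L))
})

test_that("stripe row sums equal each user's usage-day count; users sorted by first event", {
  cohort <- generate_cohort(synth_config(n_users = 6, seed = 303))
  sv <- stripe_view(cohort$events)
  ud <- usage_days(cohort$events)
  per_user <- dplyr::count(dplyr::filter(sv, .data$used), .data$user_id)
  expect_equal(dplyr::arrange(per_user, .data$user_id)$n,
               dplyr::count(ud, .data$user_id)$n)
  first <- dplyr::summarise(dplyr::group_by(cohort$events, .data$user_id),
                            t = min(.data$timestamp))
  expect_equal(attr(sv, "user_order"),
               first$user_id[order(first$t, first$user_id)])
})

test_that("start-finish takes first/last content by time, one row per content session", {
  # content order within session: 1.2.0, 2.1.0, 1.1.0 -> start 1.2.0, end 1.1.0
  log <- make_log(c(0, 1, 2, 3), c("content/1/s2/p0/", "journal/",
                                   "content/2/s1/p0/", "content/1/s1/p0/"))
  sf <- start_finish_view(log)
  expect_equal(nrow(sf), 1)
  expect_equal(sf$start_label, "1.2.0")
  expect_equal(sf$end_label, "1.1.0")
  expect_equal(sf$end_ordinal, 1L)

  # degenerate session: single content event is both start and finish
  sf2 <- start_finish_view(make_log(0, "content/2/s1/p0/"))
  expect_equal(sf2$start_label, sf2$end_label)

  # app-only sessions produce no row
  expect_equal(nrow(start_finish_view(make_log(c(0, 1), c("journal/", "quiz/")))), 0)
})

test_that("start-finish rows sort by finishing module/ordinal with deterministic ties", {
  log <- dplyr::bind_rows(
    make_log(c(0, 1), c("content/2/s1/p0/", "content/2/"), user = "b"),
    make_log(c(0, 1), c("content/1/s1/p0/", "content/1/s1/p1/"), user = "a"),
    make_log(c(0, 1), c("content/2/s1/p0/", "content/1/"), user = "c"))
  sf <- start_finish_view(log)
  expect_equal(sf$user_id, c("c", "a", "b"))
  expect_equal(sf$end_module, c(1L, 1L, 2L))
  expect_true(!is.unsorted(sf$end_module))
})

test_that("removing app events never changes start/finish labels", {
  cohort <- generate_cohort(synth_config(n_users = 5, seed = 404))
  log <- prepare_log(cohort$events, cohort$key)
  with_apps <- start_finish_view(log)
  no_apps <- start_finish_view(dplyr::filter(log, .data$kind == "content"))
  expect_equal(with_apps$start_label, no_apps$start_label)
  expect_equal(with_apps$end_label, no_apps$end_label)
  # row count never exceeds session count
  expect_lte(nrow(with_apps),
             nrow(dplyr::distinct(tibble::as_tibble(log),
                                  .data$user_id, .data$session_index)))
})

test_that("a single within-session pair lands in exactly one transition cell", {
  log <- make_log(c(0, 1), c("content/1/s1/p0/", "content/1/s1/p1/"))
  tm <- next_action_view(log, tiny_key())
  expect_equal(sum(tm$count), 1)
  expect_equal(tm$count[tm$from_index == 1 & tm$to_index == 2], 1)
})

test_that("a strictly linear user puts probability 1 on the one-off diagonal", {
  key <- tiny_key()
  urls <- key$entries$pattern[key$entries$kind == "content"][
    order(key$entries$ordinal[key$entries$kind == "content"])]
  log <- make_log(seq_along(urls) - 1, urls)
  tm <- next_action_view(log, key)
  k <- nrow(key$content)
  for (i in 0:(k - 2)) {
    expect_equal(tm$prob[tm$from_index == i & tm$to_index == i + 1], 1)
  }
  m <- as.matrix(tm, "prob")
  expect_equal(unname(apply(m[1:(k - 1), ], 1, which.max)), 2:k)
})

test_that("transition rows sum to 1 or 0 and totals obey the conservation law", {
  cohort <- generate_cohort(synth_config(n_users = 8, seed = 505))
  log <- prepare_log(cohort$events, cohort$key)
  tm <- next_action_view(log, cohort$key)
  row_sums <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tm), .data$from_index),
                               s = sum(.data$prob))$s
  expect_true(all(abs(row_sums - 1) < 1e-9 | row_sums == 0))
  # conservation: sum of counts = sum over sessions of (included length - 1)
  inc <- dplyr::filter(tibble::as_tibble(log),
                       .data$kind == "content" |
                         (.data$kind == "feature" & .data$category != "Home"))
  lens <- dplyr::count(inc, .data$user_id, .data$session_index)$n
  expect_equal(sum(tm$count), sum(pmax(lens - 1, 0)))
  # brute-force pair enumeration agrees cell by cell
  inc$state <- ifelse(inc$kind == "content", inc$label, inc$category)
  ref <- ref_pairs(inc$state, paste(inc$user_id, inc$session_index))
  ref_n <- dplyr::count(ref, .data$from, .data$to)
  got <- dplyr::filter(tibble::as_tibble(tm), .data$count > 0)
  merged <- dplyr::full_join(got, ref_n,
                             by = c(from_state = "from", to_state = "to"))
  expect_equal(merged$count, merged$n)
})

test_that("no transition crosses a session boundary unless asked to", {
  log <- make_log(c(0, 200), c("content/1/", "content/2/"))
  expect_equal(sum(next_action_view(log, tiny_key())$count), 0)
  across <- next_action_view(log, tiny_key(), across_sessions = TRUE)
  expect_equal(sum(across$count), 1)
  expect_equal(across$count[across$from_index == 0 & across$to_index == 4], 1)
})

test_that("content-only matrix re-forms pairs over content events", {
  log <- make_log(c(0, 1, 2), c("content/1/", "journal/", "content/2/"))
  full <- next_action_view(log, tiny_key())
  expect_equal(sum(full$count), 2)  # 1 -> Journal -> 2
  content_only <- next_action_view(log, tiny_key(), include_apps = FALSE)
  expect_equal(sum(content_only$count), 1)
  expect_equal(content_only$count[content_only$from_index == 0 &
                                    content_only$to_index == 4], 1)
  expect_equal(nrow(content_only), nrow(tiny_key()$content)^2)
})

test_that("collapse_repeats removes the self-transition diagonal", {
  log <- make_log(0:3, c("content/1/", "content/1/", "content/1/s1/p0/",
                         "content/1/s1/p0/"))
  tm <- next_action_view(log, tiny_key())
  expect_equal(tm$count[tm$from_index == 0 & tm$to_index == 0], 1)
  collapsed <- next_action_view(log, tiny_key(), collapse_repeats = TRUE)
  expect_equal(sum(collapsed$count), 1)
  expect_equal(collapsed$count[collapsed$from_index == 0 & collapsed$to_index == 1], 1)
})

test_that("tidy() returns nonzero transitions and glance() summarizes the log", {
  log <- prepare_log(example_log("log"), read_key_file(example_log("key")))
  tm <- next_action_view(log)
  td <- tidy(tm)
  expect_true(all(td$count > 0))
  expect_equal(sum(td$count), sum(tm$count))
  g <- glance(log)
  expect_equal(g$n_events, 63L)
  expect_equal(g$n_users, 1L)
  expect_equal(g$n_unmapped, 0L)
})
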