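# Synthetic cohort generator: reproducibility, archetype contracts, and
# exact pipeline recovery of the generator's ground truth.

test_that("an empty cohort is empty everywhere", {
  cohort <- generate_cohort(synth_config(n_users = 0, seed = 1))
  expect_equal(nrow(cohort$events), 0)
  expect_equal(nrow(cohort$ground_truth$users), 0)
  expect_equal(nrow(cohort$ground_truth$sessions), 0)
})

test_that("a fixed seed reproduces the stream exactly", {
  a <- generate_cohort(synth_config(n_users = 5, seed = 99))
  b <- generate_cohort(synth_config(n_users = 5, seed = 99))
  expect_identical(a$events, b$events)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("invalid archetype proportions are rejected", {
  expect_error(synth_config(archetype_mix = c(linear_completer = 0.5,
                                              repeater = 0.2,
                                              app_focused = 0.2,
                                              burst_user = 0.2)),
               "sum")
})

test_that("linear completers emit content in strictly increasing ordinal order", {
  cohort <- generate_cohort(synth_config(
    n_users = 3, seed = 17,
    archetype_mix = c(linear_completer = 1, repeater = 0,
                      app_focused = 0, burst_user = 0)))
  log <- prepare_log(cohort$events, cohort$key)
  for (u in unique(log$user_id)) {
    ords <- log$ordinal[log$user_id == u & log$kind == "content"]
    expect_true(all(diff(ords) > 0))
  }
  # closed form: probs(i, i+1) = 1 on the visited range, content-only matrix
  tm <- next_action_view(dplyr::filter(log, .data$user_id == log$user_id[1]),
                         cohort$key, include_apps = FALSE)
  active <- unique(tm$from_index[tm$count > 0])
  for (i in active) {
    expect_equal(tm$prob[tm$from_index == i & tm$to_index == i + 1], 1)
  }
})

test_that("app-focused users are at least 70% feature events", {
  cohort <- generate_cohort(synth_config(
    n_users = 4, seed = 23,
    archetype_mix = c(linear_completer = 0, repeater = 0,
                      app_focused = 1, burst_user = 0)))
  log <- label_events(cohort$events, cohort$key)
  for (u in unique(log$user_id)) {
    lu <- log[log$user_id == u & log$kind != "unmapped" &
                !(log$kind == "feature" & log$category == "Home"), ]
    expect_gte(mean(lu$kind == "feature"), 0.7)
  }
})

test_that("burst users cluster sessions with quiet weeks between bursts", {
  cohort <- generate_cohort(synth_config(
    n_users = 3, seed = 31,
    archetype_mix = c(linear_completer = 0, repeater = 0,
                      app_focused = 0, burst_user = 1)))
  for (u in unique(cohort$ground_truth$days$user_id)) {
    d <- cohort$ground_truth$days$day[cohort$ground_truth$days$user_id == u]
    gaps <- diff(sort(unique(d)))
    # every break between clusters is a quiet week or more
    expect_true(all(gaps[gaps > 1] >= 7))
  }
})

test_that("repeaters revisit earlier material", {
  cohort <- generate_cohort(synth_config(
    n_users = 4, seed = 37,
    archetype_mix = c(linear_completer = 0, repeater = 1,
                      app_focused = 0, burst_user = 0)))
  log <- prepare_log(cohort$events, cohort$key)
  revisits <- vapply(unique(log$user_id), function(u) {
    ords <- log$ordinal[log$user_id == u & log$kind == "content"]
    any(diff(ords) < 0)
  }, logical(1))
  expect_true(any(revisits))
})

test_that("the pipeline recovers ground truth exactly: sessions, days, start/finish", {
  cohort <- generate_cohort(synth_config(n_users = 12, seed = 71))
  log <- prepare_log(cohort$events, cohort$key, gap_minutes = 60)

  got_sessions <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(log), .data$user_id, .data$session_index),
    n_events = dplyr::n(), .groups = "drop")
  gt <- cohort$ground_truth$sessions
  expect_equal(got_sessions$user_id, gt$user_id)
  expect_equal(got_sessions$session_index, gt$session_index)
  expect_equal(got_sessions$n_events, gt$n_events)

  expect_equal(usage_days(log), cohort$ground_truth$days)

  sf <- start_finish_view(log)
  want <- dplyr::filter(gt, !is.na(.data$first_content))
  merged <- dplyr::left_join(want, tibble::as_tibble(sf),
                             by = c("user_id", "session_index"))
  expect_equal(merged$start_label, merged$first_content)
  expect_equal(merged$end_label, merged$last_content)
  expect_equal(nrow(sf), nrow(want))
})

test_that("write_cohort emits three readable CSVs that re-enter the pipeline", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(synth_config(n_users = 2, seed = 5))
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  log <- prepare_log(file.path(dir, "synthetic_log.csv"),
                     file.path(dir, "synthetic_key.csv"))
  expect_equal(nrow(log), nrow(cohort$events))
})
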