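#' Run the full engagement pipeline
#'
#' Ingestion -> key mapping -> sessionization -> view tables -> images, in
#' one call: the programmatic equivalent of the `engagement-logviz`
#' command-line tool. One CSV (and, if `render = TRUE`, one image) is
#' written per selected view, plus a `summary.txt` with cohort counts. The
#' pipeline is a pure function of its inputs: re-running it reproduces the
#' CSVs byte for byte.
#'
#' @param log Path to the raw event log (CSV/TSV).
#' @param key Path to the key file, or a [keymap()].
#' @param outdir Output directory (created if needed).
#' @param gap_minutes Session inactivity threshold in minutes (default 60).
#' @param views Which views to compute; any of `"navigation"`, `"stripe"`,
#'   `"startfinish"`, `"heatmap"` (default all four).
#' @param render Write images next to the CSVs.
#' @param format Image format, `"png"` or `"svg"`.
#' @param nav_user User id to render in the navigation graph; `NULL`
#'   renders every user (faceted). The navigation CSV always covers all
#'   users.
#' @param period_end Formal treatment-period marker for the stripe view.
#' @param strict Treat unmapped event identifiers as an error.
#' @param quiet Suppress the processing summary on stderr.
#' @param width,height Image size in pixels.
#' @return Invisibly, a list with the written `paths`, the one-row
#'   `summary` tibble, and the computed `views`.
#' @export
run_pipeline <- function(log, key, outdir,
                         gap_minutes = 60,
                         views = c("navigation", "stripe", "startfinish", "heatmap"),
                         render = TRUE, format = c("png", "svg"),
                         nav_user = NULL, period_end = 56,
                         strict = FALSE, quiet = FALSE,
                         width = 900, height = 600) {
  format <- match.arg(format)
  views <- match.arg(views, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  events <- prepare_log(log, key, gap_minutes = gap_minutes, strict = strict)
  key <- attr(events, "keymap")
  summary <- glance(events)
  if (!quiet) {
    message("processed ", summary$n_events, " events from ", summary$n_users,
            " user(s): ", summary$n_sessions, " sessions, ",
            summary$n_usage_days, " usage days, ",
            summary$n_unmapped, " unmapped event(s)")
  }

  computed <- list()
  if ("navigation" %in% views) computed$navigation <- navigation_view(events, key)
  if ("stripe" %in% views) computed$stripe <- stripe_view(events, period_end)
  if ("startfinish" %in% views) computed$startfinish <- start_finish_view(events)
  if ("heatmap" %in% views) computed$heatmap <- next_action_view(events, key)

  paths <- character(0)
  for (nm in names(computed)) {
    csv <- file.path(outdir, paste0(nm, ".csv"))
    write_view_table(computed[[nm]], csv)
    paths <- c(paths, csv)
    if (render) {
      img <- file.path(outdir, paste0(nm, ".", format))
      view <- computed[[nm]]
      if (nm == "navigation" && !is.null(nav_user)) {
        view <- new_view(dplyr::filter(tibble::as_tibble(view),
                                       .data$user_id == nav_user),
                         "nav_view", n_content = attr(view, "n_content"))
      }
      render_view(view, img, width = width, height = height)
      paths <- c(paths, img)
    }
  }
  summary_path <- file.path(outdir, "summary.txt")
  writeLines(paste(names(summary), unlist(summary), sep = ": "), summary_path)
  paths <- c(paths, summary_path)
  invisible(list(paths = paths, summary = summary, views = computed))
}

#' Bundled worked example: one user's session log
#'
#' Paths to the small log and key fixtures shipped with the package: a
#' transcription of one real user-session excerpt (63 events of user 8 on
#' 8 March 2012) and the key file mapping its 44 distinct URLs to content
#' labels and feature categories.
#'
#' @param which `"log"` or `"key"`.
#' @return A file path.
#' @export
example_log <- function(which = c("log", "key")) {
  which <- match.arg(which)
  system.file("extdata",
              c(log = "table1_log.csv", key = "table1_key.csv")[[which]],
              package = "engagelog", mustWork = TRUE)
}
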