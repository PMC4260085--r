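## ggplot2 renderers. All quantitative content comes straight from the view
## tables; rendering never recomputes or mutates them. Conventions:
## navigation — content line with sessions demarcated by space (horizontal
## gaps) and color (alternating parity hues), five app stripe lanes across
## the top; stripe — one row per user, filled cells on used days, vertical
## marker at the formal period end; start-finish — light start circle, dark
## end circle per session on the content-ordinal axis; heat map — origin at
## the lower left so strictly linear use draws a red one-off diagonal.

session_colors <- c("#1b6ca8", "#e0861a")

empty_plot <- function(title) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = "no data") +
    ggplot2::labs(title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a navigation trace
#'
#' @param object A `nav_view` (see [navigation_view()]). Multi-user views
#'   are faceted by user.
#' @param session_gap Horizontal blank steps inserted between sessions.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nav_view <- function(object, session_gap = 2, ...) {
  if (nrow(object) == 0) return(empty_plot("Navigation graph"))
  n_content <- attr(object, "n_content") %||% (max(object$ordinal, na.rm = TRUE) + 1L)
  lanes <- tibble::tibble(category = .stripe_lanes,
                          lane_y = n_content + seq_along(.stripe_lanes))
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(
      session_rank = match(.data$session_index, unique(.data$session_index)),
      x = .data$step + session_gap * (.data$session_rank - 1),
      parity = factor(.data$session_rank %% 2)
    ) |>
    dplyr::ungroup() |>
    dplyr::left_join(lanes, by = "category")
  content <- df[df$kind == "content", ]
  feats <- df[df$kind == "feature" & !is.na(df$lane_y), ]
  p <- ggplot2::ggplot(content, ggplot2::aes(x = .data$x, y = .data$ordinal)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$user_id, .data$session_rank),
                                    color = .data$parity),
                       linewidth = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$parity), size = 0.8, na.rm = TRUE) +
    ggplot2::geom_point(data = feats,
                        ggplot2::aes(x = .data$x, y = .data$lane_y, color = .data$parity),
                        shape = 15, size = 1.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = n_content + 0.5, linetype = "dotted",
                        color = "grey50") +
    ggplot2::scale_y_continuous(
      breaks = c(pretty(c(0, max(1, n_content - 1))), lanes$lane_y),
      labels = c(format(pretty(c(0, max(1, n_content - 1)))), lanes$category)
    ) +
    ggplot2::scale_color_manual(values = session_colors, guide = "none") +
    ggplot2::labs(x = "event (sequential order; sessions separated)",
                  y = "content ordinal", title = "Navigation graph") +
    ggplot2::theme_minimal()
  if (length(unique(df$user_id)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$user_id), ncol = 1)
  }
  p
}

#' Plot a stripe calendar
#'
#' @param object A `stripe_view` (see [stripe_view()]).
#' @param ... Unused.
#' @return A ggplot; one row per user, filled cells on used days, dashed
#'   vertical line at the formal treatment-period end.
#' @export
autoplot.stripe_view <- function(object, ...) {
  if (nrow(object) == 0) return(empty_plot("Stripe graph"))
  order <- attr(object, "user_order") %||% unique(object$user_id)
  df <- dplyr::filter(tibble::as_tibble(object), .data$used) |>
    dplyr::mutate(user = factor(.data$user_id, levels = rev(order)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$user)) +
    ggplot2::geom_tile(fill = "#1b6ca8", width = 0.9, height = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "period_end") %||% 56,
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "day of treatment period", y = "user",
                  title = "Stripe graph") +
    ggplot2::theme_minimal()
}

#' Plot start-finish rows
#'
#' @param object A `start_finish_view` (see [start_finish_view()]).
#' @param ... Unused.
#' @return A ggplot; per session a light circle at the starting content
#'   page and a dark circle at the finishing page, rows in view order
#'   (sorted by finishing module).
#' @export
autoplot.start_finish_view <- function(object, ...) {
  if (nrow(object) == 0) return(empty_plot("Start-finish graph"))
  df <- tibble::as_tibble(object)
  df$row <- seq_len(nrow(df))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_ordinal, xend = .data$end_ordinal,
                                       y = .data$row, yend = .data$row),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$start_ordinal, y = .data$row),
                        shape = 21, fill = "white", color = "#1b6ca8", size = 1.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$end_ordinal, y = .data$row),
                        color = "#0b3c5d", size = 1.6) +
    ggplot2::labs(x = "content ordinal", y = "session (sorted by finishing module)",
                  title = "Start-finish graph") +
    ggplot2::theme_minimal()
}

#' Plot a next-action heat map
#'
#' @param object A `next_action_view` (see [next_action_view()]).
#' @param ... Unused.
#' @return A ggplot; warmer cells are higher likelihoods, the origin is at
#'   the lower left so strictly linear navigation appears as a red one-off
#'   diagonal.
#' @export
autoplot.next_action_view <- function(object, ...) {
  if (nrow(object) == 0) return(empty_plot("Next action heat map"))
  df <- dplyr::filter(tibble::as_tibble(object), .data$count > 0)
  states <- attr(object, "states")
  content_max <- if (!is.null(states)) max(states$index[states$kind == "content"]) else
    max(object$from_index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from_index, y = .data$to_index,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = content_max + 0.5, linetype = "dotted",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = content_max + 0.5, linetype = "dotted",
                        color = "grey50") +
    ggplot2::scale_fill_gradient(low = "#c6dbef", high = "#b2182b",
                                 name = "likelihood") +
    ggplot2::coord_cartesian(xlim = c(-0.5, max(object$from_index) + 0.5),
                             ylim = c(-0.5, max(object$to_index) + 0.5),
                             expand = FALSE) +
    ggplot2::labs(x = "content page (ordinal; apps at right)",
                  y = "next page viewed (apps at top)",
                  title = "Next action heat map") +
    ggplot2::theme_minimal()
}

#' Render a view to an image file
#'
#' Writes a PNG or SVG (chosen by the file extension) of the view's
#' standard plot. An empty view still yields a valid image with a "no
#' data" annotation. Rendering is deterministic: the same view and spec
#' produce identical output.
#'
#' @param view Any of the four view tables.
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Image size in pixels.
#' @param dpi Resolution used to convert pixels to plot inches.
#' @param ... Passed on to the view's `autoplot()` method.
#' @return `path`, invisibly.
#' @export
render_view <- function(view, path, width = 900, height = 600, dpi = 100, ...) {
  p <- ggplot2::autoplot(view, ...)
  ext <- tolower(tools::file_ext(path))
  w_in <- width / dpi
  h_in <- height / dpi
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, res = dpi,
                   type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(path, width = w_in, height = h_in)
  } else {
    stop("unsupported image format '", ext, "' (use .png or .svg)", call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
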