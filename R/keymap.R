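#' Build a key map from a pattern/label table
#'
#' The key file is the curated table that gives raw event identifiers their
#' meaning: each row maps a URL pattern either to a dotted content label
#' (`"2.1.0"`) or to a feature category (`Journal`, `Mindfulness`, ...).
#' Distinct patterns may map to the same content label (several URLs can
#' reach one piece of content). The intended reading order of the content is
#' derived from the labels themselves: module-major, bare module before its
#' subsections, bare subsection before its pages; the resulting rank (the
#' *content ordinal*) runs 0..K-1 over the K distinct content labels.
#'
#' @param entries A data frame with character columns `pattern` and `label`.
#' @param match_mode How patterns are matched against event identifiers:
#'   `"suffix"` (default; an identifier matches if, after stripping a leading
#'   `/`, it equals the pattern or ends with `/<pattern>`; the longest
#'   matching pattern wins), or `"exact"`.
#' @return A `keymap` object: a list with `entries` (one row per pattern,
#'   with its parsed assignment and, for content, its ordinal), `content`
#'   (one row per distinct content label with its ordinal), and `match_mode`.
#' @seealso [read_key_file()], [map_event()], [label_events()]
#' @examples
#' key <- keymap(data.frame(
#'   pattern = c("content/1/", "content/2/", "journal/"),
#'   label   = c("1", "2", "Journal")
#' ))
#' key$content
#' @export
keymap <- function(entries, match_mode = c("suffix", "exact")) {
  match_mode <- match.arg(match_mode)
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("pattern", "label") %in% names(entries)))
  entries <- dplyr::mutate(
    entries,
    pattern = sub("^/", "", as.character(.data$pattern)),
    label = stringr::str_trim(as.character(.data$label))
  )

  is_content <- is_content_label(entries$label)
  category <- normalize_category(entries$label)
  bad <- !is_content & is.na(category)
  if (any(bad)) {
    stop("key file row(s) ", paste(which(bad), collapse = ", "),
         ": label is neither a dotted content label nor a known category: ",
         paste(unique(entries$label[bad]), collapse = ", "), call. = FALSE)
  }

  entries <- dplyr::bind_cols(
    entries["pattern"],
    tibble::tibble(
      kind = ifelse(is_content, "content", "feature"),
      label = ifelse(is_content, entries$label, NA_character_),
      category = ifelse(is_content, NA_character_, category)
    ),
    parse_content_label(ifelse(is_content, entries$label, NA_character_))
  )

  # duplicate patterns: identical assignments collapse, conflicts are errors
  entries <- dplyr::distinct(entries)
  dup <- duplicated(entries$pattern)
  if (any(dup)) {
    stop("conflicting assignments for pattern(s): ",
         paste(unique(entries$pattern[dup]), collapse = ", "), call. = FALSE)
  }

  content <- dplyr::distinct(entries[entries$kind == "content",
                                     c("label", "module", "subsection", "page")])
  content <- content[order_content_labels(content$label), ]
  content$ordinal <- seq_len(nrow(content)) - 1L
  entries <- dplyr::left_join(entries, content[, c("label", "ordinal")], by = "label")

  structure(list(entries = entries, content = tibble::as_tibble(content),
                 match_mode = match_mode),
            class = "keymap")
}

#' @export
print.keymap <- function(x, ...) {
  cat("<keymap> ", nrow(x$entries), " patterns, ",
      nrow(x$content), " content labels, match mode '", x$match_mode, "'\n",
      sep = "")
  invisible(x)
}

#' Read a key file
#'
#' Reads a delimited key file (comma or tab, auto-detected) with columns
#' `pattern` and `label` and builds a [keymap()]. The aliases `Supporter`
#' (-> Review) and `Feature` (-> Other) are normalized.
#'
#' @param path Path to the key file.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @inheritParams keymap
#' @return A `keymap` object.
#' @export
read_key_file <- function(path, delim = NULL, match_mode = c("suffix", "exact")) {
  if (!file.exists(path)) stop("key file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("pattern", "label")) {
    if (!col %in% names(df)) {
      stop("key file ", path, " is missing required column '", col, "'", call. = FALSE)
    }
  }
  keymap(df[, c("pattern", "label")], match_mode = match_mode)
}

## Vectorized pattern matching: returns integer index into key$entries
## (NA = no match). Longest pattern wins under suffix mode.
match_patterns <- function(event_ids, key) {
  ids <- sub("^/", "", event_ids)
  idx <- match(ids, key$entries$pattern)
  if (key$match_mode == "suffix") {
    pats <- key$entries$pattern[order(-nchar(key$entries$pattern))]
    pat_idx <- match(pats, key$entries$pattern)
    for (i in seq_along(pats)) {
      todo <- is.na(idx) & endsWith(ids, paste0("/", pats[i]))
      if (any(todo)) idx[todo] <- pat_idx[i]
    }
  }
  idx
}

#' Map one event identifier to its sequence assignment
#'
#' A total function: an empty identifier is the platform landing page
#' (feature `Home`); an identifier matching no key pattern is `unmapped`,
#' never an error.
#'
#' @param event_id Character vector of raw event identifiers (URL paths).
#' @param key A [keymap()].
#' @return A tibble with one row per identifier and columns `kind`
#'   (`content`/`feature`/`unmapped`), `label`, `module`, `subsection`,
#'   `page`, `ordinal` (content only) and `category` (feature only).
#' @examples
#' key <- keymap(data.frame(pattern = "content/9/54/93/", label = "2.1.0"))
#' map_event("content/9/54/93/", key)
#' map_event("", key)        # Home
#' map_event("unknown/", key) # unmapped
#' @export
map_event <- function(event_id, key) {
  stopifnot(inherits(key, "keymap"))
  n <- length(event_id)
  out <- tibble::tibble(
    kind = rep("unmapped", n),
    label = NA_character_, module = NA_integer_, subsection = NA_integer_,
    page = NA_integer_, ordinal = NA_integer_, category = NA_character_
  )
  empty <- is.na(event_id) | event_id == ""
  out$kind[empty] <- "feature"
  out$category[empty] <- "Home"
  idx <- match_patterns(event_id[!empty], key)
  hit <- !is.na(idx)
  cols <- c("kind", "label", "module", "subsection", "page", "ordinal", "category")
  out[which(!empty)[hit], cols] <- key$entries[idx[hit], cols]
  out
}

#' Label an event stream using a key map
#'
#' Joins the sequence assignment of every event onto the log. Unmapped
#' identifiers are kept (kind `"unmapped"`) so that callers can count and
#' report them; all view constructors exclude them.
#'
#' @param events A data frame of raw events (see [read_event_log()]).
#' @param key A [keymap()].
#' @param strict If `TRUE`, any unmapped non-empty identifier is an error.
#' @return The input tibble with assignment columns appended (`kind`,
#'   `label`, `module`, `subsection`, `page`, `ordinal`, `category`).
#' @export
label_events <- function(events, key, strict = FALSE) {
  events <- tibble::as_tibble(events)
  assign <- map_event(events$event_id, key)
  if (strict && any(assign$kind == "unmapped")) {
    stop(sum(assign$kind == "unmapped"), " event identifier(s) not in key; ",
         "first: ", events$event_id[which(assign$kind == "unmapped")[1]],
         call. = FALSE)
  }
  dplyr::bind_cols(events, assign)
}

#' Content ordinal of a label
#'
#' The linear rank (0-based) of a content label in the author's intended
#' sequence, as declared by the key map. This is the vertical axis of the
#' navigation graph and both axes of the next-action heat map.
#'
#' @param label Character vector of dotted content labels.
#' @param key A [keymap()].
#' @return Integer vector of ordinals.
#' @export
content_ordinal <- function(label, key) {
  stopifnot(inherits(key, "keymap"))
  ord <- key$content$ordinal[match(label, key$content$label)]
  if (anyNA(ord)) {
    stop("content label(s) not in key: ",
         paste(unique(label[is.na(ord)]), collapse = ", "), call. = FALSE)
  }
  ord
}

#' @importFrom generics glance
#' @export
generics::glance

#' Glance at a key map
#'
#' @param x A [keymap()].
#' @param ... Unused.
#' @return A one-row tibble: number of patterns, content labels, feature
#'   patterns, and modules covered.
#' @export
glance.keymap <- function(x, ...) {
  tibble::tibble(
    n_patterns = nrow(x$entries),
    n_content_labels = nrow(x$content),
    n_feature_patterns = sum(x$entries$kind == "feature"),
    n_modules = length(unique(x$content$module))
  )
}
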