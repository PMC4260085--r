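## Canonical feature categories. The first five are the app stripe lanes of
## the navigation graph; Home is the platform landing page and is shown in
## no stripe. Key files may use the aliases "Supporter" (-> Review) and
## "Feature" (-> Other).
.categories <- c("Exercise", "Mindfulness", "Journal", "Review", "Other", "Home")
.category_aliases <- c(supporter = "Review", feature = "Other")
.stripe_lanes <- c("Exercise", "Mindfulness", "Journal", "Review", "Other")

#' Normalize a feature-category name
#'
#' Matches case-insensitively against the six canonical categories
#' (Exercise, Mindfulness, Journal, Review, Other, Home) and the aliases
#' "Supporter" (a review written by the assigned supporter) and "Feature".
#'
#' @param x Character vector of category names or aliases.
#' @return Character vector of canonical category names; `NA` where `x` is
#'   not a recognized category.
#' @examples
#' normalize_category(c("supporter", "Journal", "Feature", "nonsense"))
#' @export
normalize_category <- function(x) {
  lx <- tolower(x)
  out <- .categories[match(lx, tolower(.categories))]
  alias <- .category_aliases[lx]
  ifelse(is.na(out) & !is.na(alias), unname(alias), out)
}

#' Parse dotted content labels
#'
#' Content pages are labelled `module[.subsection[.page]]`, e.g. `"2"`,
#' `"1.0.1"`, `"2.1.0"`. Module 0 is legal (interventions commonly have an
#' introduction module 0).
#'
#' @param x Character vector.
#' @return A tibble with integer columns `module`, `subsection`, `page`
#'   (`NA` where the component is absent) and one row per element of `x`;
#'   all-`NA` rows where `x` is not a dotted numeric label.
#' @examples
#' parse_content_label(c("2", "1.0.1", "2.1.0", "Journal"))
#' @export
parse_content_label <- function(x) {
  ok <- is_content_label(x)
  parts <- stringr::str_split(ifelse(ok, x, NA_character_), stringr::fixed("."))
  comp <- function(i) {
    vapply(parts, function(p) {
      if (length(p) >= i && !is.na(p[i])) as.integer(p[i]) else NA_integer_
    }, integer(1))
  }
  tibble::tibble(module = comp(1), subsection = comp(2), page = comp(3))
}

#' @rdname parse_content_label
#' @return For `is_content_label`, a logical vector.
#' @export
is_content_label <- function(x) {
  !is.na(x) & stringr::str_detect(x, "^[0-9]+(\\.[0-9]+(\\.[0-9]+)?)?$")
}

#' Format a content label as a dotted string
#'
#' @param module,subsection,page Integer vectors; `subsection`/`page` may be
#'   `NA` (absent components are dropped from the right).
#' @param drop_page If `TRUE`, truncate to `module.subsection` for display
#'   (the coarser form used in running text, e.g. "2.1" for "2.1.0").
#' @return Character vector of dotted labels.
#' @examples
#' format_content_label(2L, 1L, 0L)
#' format_content_label(2L, 1L, 0L, drop_page = TRUE)
#' @export
format_content_label <- function(module, subsection, page, drop_page = FALSE) {
  out <- as.character(module)
  has_sub <- !is.na(subsection)
  if (drop_page) {
    out[has_sub] <- paste0(out[has_sub], ".", subsection[has_sub])
  } else {
    has_page <- has_sub & !is.na(page)
    out[has_page] <- paste0(out[has_page], ".", subsection[has_page], ".", page[has_page])
    only_sub <- has_sub & is.na(page)
    out[only_sub] <- paste0(out[only_sub], ".", subsection[only_sub])
  }
  out[is.na(module)] <- NA_character_
  out
}

## Order content labels the way the author intends the material to be read:
## module-major, with the bare module label (absent subsection) preceding its
## subsections, and a bare subsection preceding its pages.
order_content_labels <- function(labels) {
  tr <- parse_content_label(labels)
  order(tr$module,
        !is.na(tr$subsection), tr$subsection,
        !is.na(tr$page), tr$page)
}
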