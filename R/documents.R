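#' Document sets
#'
#' A document set is a tibble with one row per text unit (passage): columns
#' `doc_id`, `provider`, `section_id`, `offset`, `text`. The package's fixed
#' offset convention is that a document's full text is the concatenation of
#' its units in offset order, joined by a single newline, and every offset is
#' a 0-based character (not byte) position into that concatenation. For the
#' usual title/abstract layout the title unit (`section_id = "T"`) sits at
#' offset 0 and the abstract unit (`"A"`) at `nchar(title) + 1`.
#'
#' @param doc_id document identifier (non-empty).
#' @param title,abstract character scalars; the two text units.
#' @param provider one of `"patent"`, `"abstract"`, `"pubmed"` (or any label).
#' @return a `anno_documents` tibble with one row per unit.
#' @examples
#' d <- document("D1", "A title", "An abstract about hydrocodone.")
#' document_text(d)
#' @export
document <- function(doc_id, title, abstract, provider = "abstract") {
  stopifnot(is.character(doc_id), nzchar(doc_id), length(doc_id) == 1L)
  as_documents(tibble(
    doc_id = doc_id,
    provider = provider,
    section_id = c("T", "A"),
    offset = c(0L, nchar(title) + 1L),
    text = c(title, abstract)
  ))
}

#' Coerce a data frame to a document set
#'
#' @param x a data frame with columns `doc_id`, `section_id`, `offset`,
#'   `text` (and optionally `provider`).
#' @param check validate the offset convention (offsets strictly increasing
#'   within a document and equal to the cumulative length of preceding units
#'   plus one separator character each).
#' @export
as_documents <- function(x, check = TRUE) {
  x <- as_tibble(x)
  need <- c("doc_id", "section_id", "offset", "text")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_bench(paste0("document set is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (!"provider" %in% names(x)) x$provider <- NA_character_
  x$offset <- as.integer(x$offset)
  x <- x[, c("doc_id", "provider", "section_id", "offset", "text")]
  if (check && nrow(x)) {
    bad <- x |>
      dplyr::arrange(.data$doc_id, .data$offset) |>
      dplyr::group_by(.data$doc_id) |>
      dplyr::summarise(ok = all(.data$offset ==
        c(0L, utils::head(cumsum(nchar(.data$text) + 1L), -1L)))) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad)) {
      abort_bench(paste0("unit offsets are inconsistent with the newline-",
                         "concatenation convention for document(s): ",
                         paste(bad$doc_id, collapse = ", ")))
    }
    if (any(x$offset < 0L)) abort_bench("unit offsets must be non-negative")
    if (any(!nzchar(x$section_id))) abort_bench("section_id must be non-empty")
  }
  class(x) <- c("anno_documents", class(tibble()))
  x
}

#' Reassemble full document texts from a document set
#'
#' @param docs a document set (see [as_documents()]).
#' @return a tibble with one row per document: `doc_id`, `provider`, `text`,
#'   `length` (characters).
#' @export
document_text <- function(docs) {
  docs <- as_documents(docs, check = FALSE)
  docs |>
    dplyr::arrange(.data$doc_id, .data$offset) |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::summarise(
      provider = .data$provider[1],
      text = paste(.data$text, collapse = "\n"),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = nchar(.data$text))
}
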