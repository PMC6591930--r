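#' Validate predictions against their source documents
#'
#' Checks every annotation against the document set and the entity-type
#' vocabulary. Nothing errors here: all problems are reported as rows of the
#' returned violation table, so an empty table means the payload is valid.
#' Flagged kinds are:
#'
#' * `offset_out_of_bounds` — `init + length` runs past the document text
#'   (or `init` is negative);
#' * `text_mismatch` — the document substring at `[init, init + length)`
#'   differs from the annotation text, compared case-insensitively but
#'   whitespace-exactly;
#' * `unknown_type` — `entity_type` is not in the supplied vocabulary
#'   (skipped when `type_vocabulary` is `NULL`, the open-vocabulary default);
#' * `malformed_record` — the annotation's `doc_id` does not resolve in the
#'   document set.
#'
#' @param preds an `anno_predictions` tibble.
#' @param docs a document set ([as_documents()]).
#' @param type_vocabulary character vector of admissible entity-type labels,
#'   e.g. [reference_entity_types()]; `NULL` disables the type check.
#' @return a tibble with columns `annotation` (row index into `preds`),
#'   `doc_id`, `kind`, `message`; zero rows iff the payload is valid.
#' @export
validate_against_documents <- function(preds, docs, type_vocabulary = NULL) {
  preds <- as_predictions(preds)
  dt <- document_text(docs)
  viol <- list()
  flag <- function(i, kind, message) {
    viol[[length(viol) + 1L]] <<- tibble(
      annotation = i, doc_id = preds$doc_id[i], kind = kind,
      message = message)
  }
  doc_row <- match(preds$doc_id, dt$doc_id)
  for (i in seq_len(nrow(preds))) {
    r <- doc_row[i]
    if (is.na(r)) {
      flag(i, "malformed_record",
           sprintf("doc_id '%s' not found in the document set",
                   preds$doc_id[i]))
      next
    }
    len <- dt$length[r]
    if (preds$init[i] < 0L || preds$end[i] > len) {
      flag(i, "offset_out_of_bounds",
           sprintf("span [%d, %d) exceeds document length %d",
                   preds$init[i], preds$end[i], len))
    } else {
      span <- substr(dt$text[r], preds$init[i] + 1L, preds$end[i])
      if (tolower(span) != tolower(preds$text[i])) {
        flag(i, "text_mismatch",
             sprintf("document substring '%s' != annotation text '%s'",
                     span, preds$text[i]))
      }
    }
    if (!is.null(type_vocabulary) &&
        !(normalize_entity_type(preds$entity_type[i]) %in%
          normalize_entity_type(type_vocabulary))) {
      flag(i, "unknown_type",
           sprintf("entity_type '%s' is not in the vocabulary",
                   preds$entity_type[i]))
    }
  }
  out <- if (length(viol)) dplyr::bind_rows(viol) else {
    tibble(annotation = integer(), doc_id = character(),
           kind = character(), message = character())
  }
  class(out) <- c("anno_violations", class(tibble()))
  out
}
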