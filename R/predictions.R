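#' Stand-off entity predictions
#'
#' Predictions are held as a tibble with one row per entity mention, in the
#' eight-field stand-off model shared by all three interchange formats:
#' `doc_id`, `section_id`, `init` (0-based character start), `length`
#' (characters, >= 1), `end` (`init + length`, half-open), `score`
#' (confidence in \[0, 1\]), `text` (surface string), `entity_type`, `db_id`
#' (normalization identifier, `""` when absent).
#'
#' @param doc_id,section_id,init,length,score,text,entity_type,db_id field
#'   vectors, recycled tibble-style.
#' @return an `anno_predictions` tibble.
#' @examples
#' predictions("D1", "A", init = 103, length = 11,
#'             text = "hydrocodone", entity_type = "chemical")
#' @export
predictions <- function(doc_id, section_id = "A", init, length, score = 1,
                        text, entity_type, db_id = "") {
  out <- tibble(
    doc_id = as.character(doc_id),
    section_id = as.character(section_id),
    init = as.integer(init),
    length = as.integer(length),
    score = as.double(score),
    text = as.character(text),
    entity_type = as.character(entity_type),
    db_id = as.character(db_id)
  )
  out$end <- out$init + out$length
  out <- out[, prediction_cols()]
  validate_predictions(new_predictions(out))
}

prediction_cols <- function() {
  c("doc_id", "section_id", "init", "length", "end", "score",
    "text", "entity_type", "db_id")
}

new_predictions <- function(x, source_format = NA_character_) {
  x <- as_tibble(x)
  class(x) <- c("anno_predictions", class(tibble()))
  attr(x, "source_format") <- source_format
  x
}

#' @rdname predictions
#' @export
empty_predictions <- function() {
  new_predictions(tibble(
    doc_id = character(), section_id = character(), init = integer(),
    length = integer(), end = integer(), score = double(),
    text = character(), entity_type = character(), db_id = character()
  ))
}

#' @rdname predictions
#' @param x a data frame carrying the prediction columns.
#' @param source_format optional format id the predictions were parsed from.
#' @export
as_predictions <- function(x, source_format = NA_character_) {
  x <- as_tibble(x)
  if (!"end" %in% names(x)) x$end <- as.integer(x$init) + as.integer(x$length)
  if (!"db_id" %in% names(x)) x$db_id <- ""
  if (!"score" %in% names(x)) x$score <- 1
  miss <- setdiff(prediction_cols(), names(x))
  if (length(miss)) {
    abort_bench(paste0("predictions are missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  x <- x[, prediction_cols()]
  x$init <- as.integer(x$init)
  x$length <- as.integer(x$length)
  x$end <- as.integer(x$end)
  x$score <- as.double(x$score)
  x$db_id[is.na(x$db_id)] <- ""
  validate_predictions(new_predictions(x, source_format))
}

#' Validate prediction invariants
#'
#' Checks the type invariants (offsets non-negative, length >= 1,
#' `end == init + length`, score in \[0, 1\], non-empty identifiers) and
#' errors on the first batch of violations found.
#'
#' @param x an `anno_predictions` tibble.
#' @return `x`, invisibly unchanged, on success.
#' @export
validate_predictions <- function(x) {
  probs <- character()
  add <- function(cond, msg) if (any(cond, na.rm = TRUE) || anyNA(cond)) {
    probs <<- c(probs, msg)
  }
  add(!nzchar(x$doc_id) | is.na(x$doc_id), "doc_id must be non-empty")
  add(is.na(x$init) | x$init < 0L, "init must be a non-negative integer")
  add(is.na(x$length) | x$length < 1L, "length must be >= 1")
  add(x$end != x$init + x$length, "end must equal init + length")
  add(is.na(x$score) | x$score < 0 | x$score > 1, "score must be in [0, 1]")
  add(!nzchar(x$entity_type) | is.na(x$entity_type),
      "entity_type must be non-empty")
  if (length(probs)) {
    abort_bench(paste0("invalid predictions: ", paste(probs, collapse = "; ")),
                class = "annobench_invalid_predictions")
  }
  x
}

# canonical ordering used for multiset comparisons in tests and conversion
arrange_predictions <- function(x) {
  dplyr::arrange(as_tibble(x), .data$doc_id, .data$section_id, .data$init,
                 .data$length, .data$entity_type, .data$text, .data$db_id,
                 .data$score)
}
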