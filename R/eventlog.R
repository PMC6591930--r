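#' Persist and reload event logs
#'
#' Event logs are written as line-delimited JSON: a meta record (evaluation
#' window, deadline) followed by one record per event, payload annotations
#' nested as arrays of objects. Numbers are written at full precision so a
#' reload reproduces the log exactly.
#'
#' @param log an `anno_eventlog`.
#' @param path output file.
#' @export
write_event_log <- function(log, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- jsonlite::toJSON(list(record = "meta",
                                window = attr(log, "window"),
                                deadline = attr(log, "deadline")),
                           auto_unbox = TRUE, digits = NA)
  writeLines(meta, con, useBytes = TRUE)
  for (k in seq_len(nrow(log))) {
    rec <- list(
      record = "event",
      server_id = log$server_id[k], request_id = log$request_id[k],
      provider = log$provider[k], issue_time = log$issue_time[k],
      receive_time = log$receive_time[k], status = log$status[k],
      response_time = log$response_time[k],
      document_bytes = log$document_bytes[k],
      annotation_count = log$annotation_count[k],
      doc_ids = as.list(log$doc_ids[[k]]),
      doc_versions = as.list(log$doc_versions[[k]]))
    pay <- log$payload[[k]]
    if (!is.null(pay)) {
      rec$payload <- purrr::map(seq_len(nrow(pay)), function(j) {
        as.list(pay[j, prediction_cols()])
      })
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  meta <- recs[[1]]
  stopifnot(identical(meta$record, "meta"))
  events <- recs[-1]
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.double(x)
  out <- tibble(
    server_id = purrr::map_int(events, ~ as.integer(.x$server_id)),
    request_id = purrr::map_chr(events, "request_id"),
    provider = purrr::map_chr(events, "provider"),
    issue_time = purrr::map_dbl(events, ~ as.double(.x$issue_time)),
    receive_time = purrr::map_dbl(events, ~ num_or_na(.x$receive_time)),
    status = purrr::map_chr(events, "status"),
    response_time = purrr::map_dbl(events, ~ num_or_na(.x$response_time)),
    document_bytes = purrr::map_dbl(events, ~ as.double(.x$document_bytes)),
    annotation_count = purrr::map_int(events,
                                      ~ as.integer(.x$annotation_count)),
    doc_ids = purrr::map(events, ~ as.character(unlist(.x$doc_ids))),
    doc_versions = purrr::map(events, ~ as.integer(unlist(.x$doc_versions))),
    payload = purrr::map(events, function(e) {
      if (is.null(e$payload)) return(NULL)
      if (!length(e$payload)) return(empty_predictions())
      as_predictions(dplyr::bind_rows(
        purrr::map(e$payload, ~ as_tibble(.x))))
    })
  )
  class(out) <- c("anno_eventlog", class(tibble()))
  attr(out, "window") <- as.double(unlist(meta$window))
  attr(out, "deadline") <- as.double(meta$deadline)
  out
}
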