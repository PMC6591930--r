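failure_statuses <- function() c("timeout", "error", "malformed")

log_window <- function(log) {
  w <- attr(log, "window")
  if (is.null(w)) {
    if (!nrow(log)) return(c(0, 0))
    c(min(log$issue_time),
      max(log$issue_time, log$receive_time, na.rm = TRUE))
  } else w
}

server_events <- function(log, server_id) {
  if (!server_id %in% log$server_id) {
    abort_bench(sprintf("no events for server %s in the log", server_id),
                class = "annobench_not_found")
  }
  dplyr::arrange(log[log$server_id == server_id, ], .data$issue_time)
}

#' Derive downtime intervals from an event log
#'
#' A downtime interval is one maximal run of consecutive failed requests
#' (timeout, transport error or malformed payload — any request without a
#' complete parseable response before the deadline). The interval starts at
#' the issue time of the first failed request of the run and ends at the
#' issue time of the first subsequent ok response, or at the evaluation
#' window end if the server never recovers. The number of failures used in
#' the MTBF/MTTR denominators is the number of such intervals.
#'
#' @param log an `anno_eventlog`.
#' @param server_id server to analyse.
#' @return a tibble with `start`, `end` columns, disjoint and ordered.
#' @export
derive_downtime <- function(log, server_id) {
  ev <- server_events(log, server_id)
  fail <- ev$status %in% failure_statuses()
  if (!any(fail)) return(tibble(start = double(), end = double()))
  runs <- rle(fail)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  wend <- log_window(log)[2]
  down <- which(runs$values)
  tibble(
    start = ev$issue_time[idx_start[down]],
    end = vapply(down, function(r) {
      if (r == length(runs$values)) wend else ev$issue_time[idx_end[r] + 1L]
    }, 1)
  )
}

#' Compute the six evaluation metrics for a server
#'
#' From the event log of one server (or all servers when `server_id` is
#' `NULL`), computes requests, ok responses, total predictions and the six
#' reliability/performance metrics. Sums run over ok responses only —
#' timeouts, errors and malformed payloads enter the reliability metrics,
#' not the performance means:
#'
#' * `ART` = (sum of response times) / (number of responses), seconds;
#' * `MAD` = (total annotations) / (number of responses);
#' * `MTSA` = (sum of response times) / (total annotations), seconds per
#'   annotation — `NA` (an undefined sentinel, never 0 or infinity) when the
#'   server produced no predictions;
#' * `MTDV` = (sum of response times) / (sum of requested document bytes),
#'   seconds per byte;
#' * `MTTR` = (total downtime) / (number of failures), seconds — 0 when the
#'   server never failed;
#' * `MTBF` = (total uptime) / (number of failures), seconds, where uptime
#'   resumes at the end of each downtime interval and the first uptime span
#'   starts at the window start — the full window length when the server
#'   never failed.
#'
#' @param log an `anno_eventlog`.
#' @param server_id one server id, or `NULL` for every server in the log.
#' @return an `anno_metrics` tibble, one row per server.
#' @seealso [derive_downtime()], [median_summary()], [metrics_report()]
#' @export
compute_metrics <- function(log, server_id = NULL) {
  ids <- server_id %||% sort(unique(log$server_id))
  win <- log_window(log)
  rows <- purrr::map(ids, function(sid) {
    ev <- server_events(log, sid)
    ok <- ev[ev$status == "ok", ]
    responses <- nrow(ok)
    predictions <- sum(ok$annotation_count)
    sum_rt <- sum(ok$response_time)
    sum_bytes <- sum(ok$document_bytes)
    down <- derive_downtime(log, sid)
    failures <- nrow(down)
    total_down <- sum(down$end - down$start)
    span <- win[2] - win[1]
    tibble(
      server_id = sid,
      requests = nrow(ev),
      responses = responses,
      predictions = predictions,
      failures = failures,
      ART = if (responses) sum_rt / responses else NA_real_,
      MAD = if (responses) predictions / responses else 0,
      MTSA = if (predictions > 0) sum_rt / predictions else NA_real_,
      MTDV = if (sum_bytes > 0) sum_rt / sum_bytes else NA_real_,
      MTBF = if (failures) (span - total_down) / failures else span,
      MTTR = if (failures) total_down / failures else 0
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anno_metrics", class(tibble()))
  attr(out, "window") <- win
  out
}

#' Median summaries across servers
#'
#' Standard middle-of-sorted medians (mean of the two middle values for
#' even counts) of ART and MAD across servers; undefined (`NA`) values are
#' excluded. The MAD median is also reported rounded to the nearest whole
#' annotations/document. When the metrics carry a `provider` column,
#' per-provider medians are nested in the `per_provider` list-column.
#'
#' @param metrics an `anno_metrics` tibble (or any data frame with `ART`
#'   and `MAD` columns, e.g. the published results fixture).
#' @return a one-row tibble: `median_ART`, `median_MAD`,
#'   `median_MAD_rounded`, `per_provider`.
#' @export
median_summary <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  per_provider <- if ("provider" %in% names(metrics)) {
    metrics |>
      dplyr::group_by(.data$provider) |>
      dplyr::summarise(median_ART = stats::median(.data$ART, na.rm = TRUE),
                       median_MAD = stats::median(.data$MAD, na.rm = TRUE),
                       .groups = "drop")
  } else NULL
  med_mad <- stats::median(metrics$MAD, na.rm = TRUE)
  tibble(
    median_ART = stats::median(metrics$ART, na.rm = TRUE),
    median_MAD = med_mad,
    median_MAD_rounded = as.integer(round(med_mad)),
    per_provider = list(per_provider)
  )
}

# annotation set fingerprint used by the cache detector: position, extent,
# type and surface string of every annotation, order-independent
annotation_set_key <- function(pred) {
  if (is.null(pred) || !nrow(pred)) return("")
  paste(sort(paste(pred$entity_type, pred$init, pred$length, pred$text,
                   sep = "\r")), collapse = "\n")
}

#' Detect prediction caching from compliance documents
#'
#' Compliance documents are perturbed between serves, so an honest server's
#' annotation sets must differ across served versions. For every compliance
#' document with at least two ok responses at different served versions the
#' detector compares the returned annotation sets (type, init, length,
#' text): if every such comparison, over every usable document, finds
#' identical sets, the server is `flagged` as caching; any difference clears
#' it; with fewer than two usable responses for every compliance document
#' the verdict is `insufficient_evidence`. Payloads must have been recorded
#' in the log (see `record_payloads` in [run_benchmark()]).
#'
#' @param log an `anno_eventlog` with recorded payloads.
#' @param compliance_doc_ids character vector of compliance document ids.
#' @param server_id one server id, or `NULL` for all servers.
#' @return a tibble with `server_id` and `verdict` in
#'   `c("flagged", "clear", "insufficient_evidence")`.
#' @export
detect_caching <- function(log, compliance_doc_ids, server_id = NULL) {
  ids <- server_id %||% sort(unique(log$server_id))
  rows <- purrr::map(ids, function(sid) {
    ev <- server_events(log, sid)
    ev <- ev[ev$status == "ok" & !purrr::map_lgl(ev$payload, is.null), ]
    per_doc <- list()
    for (k in seq_len(nrow(ev))) {
      docs <- ev$doc_ids[[k]]
      vers <- ev$doc_versions[[k]]
      pay <- ev$payload[[k]]
      for (d in intersect(docs, compliance_doc_ids)) {
        sub <- pay[pay$doc_id == d, ]
        per_doc[[d]] <- dplyr::bind_rows(
          per_doc[[d]],
          tibble(version = vers[match(d, docs)],
                 key = annotation_set_key(sub)))
      }
    }
    usable <- purrr::keep(per_doc, ~ dplyr::n_distinct(.x$version) >= 2L)
    if (!length(usable)) {
      return(tibble(server_id = sid, verdict = "insufficient_evidence"))
    }
    all_identical <- all(purrr::map_lgl(usable, function(x) {
      dplyr::n_distinct(x$key) == 1L
    }))
    tibble(server_id = sid,
           verdict = if (all_identical) "flagged" else "clear")
  })
  dplyr::bind_rows(rows)
}

#' Leaderboard over a metrics report
#'
#' Stable sort by the declared ranking keys (default: ART ascending, ties
#' broken by MAD descending, then server id). The best value of each metric
#' column is marked in the `leaders` attribute (minimum for the time-like
#' metrics MTSA/MTDV/ART/MTTR, maximum for requests, predictions, MAD and
#' MTBF), mirroring the highlighting of published evaluation tables.
#'
#' @param x an `anno_metrics` tibble or an `anno_report`.
#' @param keys character vector of ranking keys; prefix with `-` for
#'   descending order.
#' @return the ranked tibble with a `rank` column and a `leaders` attribute
#'   (named vector metric -> server_id).
#' @export
leaderboard <- function(x, keys = c("ART", "-MAD", "server_id")) {
  m <- if (inherits(x, "anno_report")) x$per_server else x
  ord <- purrr::map(keys, function(k) {
    desc <- startsWith(k, "-")
    col <- m[[sub("^-", "", k)]]
    if (desc) -xtfrm(col) else xtfrm(col)
  })
  out <- m[do.call(order, ord), ]
  out$rank <- seq_len(nrow(out))
  best <- c(requests = "max", predictions = "max", MTSA = "min",
            MTDV = "min", MAD = "max", ART = "min", MTBF = "max",
            MTTR = "min")
  leaders <- purrr::imap_int(best[names(best) %in% names(out)],
    function(how, col) {
      v <- out[[col]]
      if (all(is.na(v))) return(NA_integer_)
      i <- if (how == "min") which.min(v) else which.max(v)
      as.integer(out$server_id[i])
    })
  attr(out, "leaders") <- leaders
  out
}

#' Full metrics report for an event log
#'
#' Assembles the per-server metrics, per-provider performance breakdowns,
#' median summaries and (when compliance documents and payloads are
#' available) cache-compliance verdicts into one report object with
#' [generics::tidy()] / [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @param log an `anno_eventlog`.
#' @param compliance_doc_ids optional compliance document ids for the cache
#'   detector.
#' @return an `anno_report` object.
#' @export
metrics_report <- function(log, compliance_doc_ids = NULL) {
  per_server <- compute_metrics(log)
  per_provider <- log |>
    as_tibble() |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$server_id, .data$provider) |>
    dplyr::summarise(
      responses = dplyr::n(),
      predictions = sum(.data$annotation_count),
      ART = mean(.data$response_time),
      MAD = sum(.data$annotation_count) / dplyr::n(),
      MTSA = ifelse(sum(.data$annotation_count) > 0,
                    sum(.data$response_time) / sum(.data$annotation_count),
                    NA_real_),
      MTDV = sum(.data$response_time) / sum(.data$document_bytes),
      .groups = "drop")
  medians <- median_summary(per_server)
  provider_medians <- per_provider |>
    dplyr::group_by(.data$provider) |>
    dplyr::summarise(median_ART = stats::median(.data$ART, na.rm = TRUE),
                     median_MAD = stats::median(.data$MAD, na.rm = TRUE),
                     .groups = "drop")
  medians$per_provider <- list(provider_medians)
  caching <- if (!is.null(compliance_doc_ids)) {
    detect_caching(log, compliance_doc_ids)
  } else NULL
  structure(list(per_server = per_server, per_provider = per_provider,
                 medians = medians, caching = caching,
                 window = log_window(log),
                 n_requests = dplyr::n_distinct(log$request_id),
                 n_events = nrow(log)),
            class = "anno_report")
}

#' @export
print.anno_report <- function(x, ...) {
  cat(sprintf("Benchmark report: %d server(s), %d request(s), %d event(s)\n",
              nrow(x$per_server), x$n_requests, x$n_events))
  cat(sprintf("  evaluation window: [%g, %g] s\n", x$window[1], x$window[2]))
  cat(sprintf("  median ART %.3g s; median MAD %.3g (~%d annotations/doc)\n",
              x$medians$median_ART, x$medians$median_MAD,
              x$medians$median_MAD_rounded))
  print(leaderboard(x), n = Inf)
  if (!is.null(x$caching)) {
    cat("  caching verdicts:\n")
    print(x$caching, n = Inf)
  }
  invisible(x)
}

#' Export a report as JSON and a TSV leaderboard
#'
#' The TSV reproduces the published results-table column order (requests,
#' predictions, MTSA, MTDV, MAD, ART, MTBF, MTTR) with values printed in
#' 3-significant-figure scientific notation.
#'
#' @param report an `anno_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lb <- leaderboard(report)
  out <- tibble(
    server_id = lb$server_id, rank = lb$rank,
    requests = format_sci3(lb$requests),
    predictions = format_sci3(lb$predictions),
    MTSA = format_sci3(lb$MTSA), MTDV = format_sci3(lb$MTDV),
    MAD = format_sci3(lb$MAD), ART = format_sci3(lb$ART),
    MTBF = format_sci3(lb$MTBF), MTTR = format_sci3(lb$MTTR))
  utils::write.table(out, file.path(dir, "leaderboard.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json <- list(
    window = report$window, n_requests = report$n_requests,
    n_events = report$n_events,
    medians = list(median_ART = report$medians$median_ART,
                   median_MAD = report$medians$median_MAD,
                   median_MAD_rounded = report$medians$median_MAD_rounded),
    per_server = report$per_server,
    per_provider = report$per_provider,
    provider_medians = report$medians$per_provider[[1]],
    caching = report$caching)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(dir)
}
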