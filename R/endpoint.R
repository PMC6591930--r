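#' Real HTTP annotation-server endpoints
#'
#' The transport is a contract — send a request, await a response or the
#' deadline — and simulated profiles and HTTP endpoints are interchangeable
#' behind it. An endpoint answers a JSON request body (versioned schema
#' `annobench/1`: `request_id`, `documents` as `doc_id`/`provider` pairs
#' with raw text, `requested_types`, `response_format`, `deadline`) with a
#' payload in any of the three formats. Endpoints need the `curl` package
#' and a reachable network, so they are exercised only in live deployments;
#' benchmarks and tests use simulated profiles.
#'
#' @param server_id integer id.
#' @param url annotation endpoint URL.
#' @param status_url optional status endpoint URL.
#' @param format format id the server responds in.
#' @return an `anno_endpoint` object accepted by [run_benchmark()]'s server
#'   list in place of a behaviour profile.
#' @export
http_endpoint <- function(server_id, url, status_url = NULL,
                          format = "bioc_json") {
  check_format_id(format)
  structure(list(server_id = as.integer(server_id), url = url,
                 status_url = status_url, format = format),
            class = "anno_endpoint")
}

request_body <- function(request, documents, format, deadline) {
  jsonlite::toJSON(list(
    schema = "annobench/1",
    request_id = request$request_id,
    documents = purrr::map(documents, function(d) {
      list(doc_id = d$doc_id, provider = d$provider, text = d$text)
    }),
    requested_types = as.list(reference_entity_types()),
    response_format = format,
    deadline = deadline
  ), auto_unbox = TRUE)
}

call_endpoint <- function(endpoint, request, documents, deadline) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    abort_bench("the 'curl' package is required for HTTP endpoints")
  }
  h <- curl::new_handle(timeout = ceiling(deadline))
  curl::handle_setopt(h, post = TRUE,
                      postfields = request_body(request, documents,
                                                endpoint$format, deadline))
  curl::handle_setheaders(h, "Content-Type" = "application/json")
  t0 <- Sys.time()
  res <- tryCatch(curl::curl_fetch_memory(endpoint$url, handle = h),
                  error = function(e) NULL)
  delay <- as.double(difftime(Sys.time(), t0, units = "secs"))
  if (is.null(res)) return(list(delay = delay, status = "timeout"))
  if (res$status_code >= 400) return(list(delay = delay, status = "error"))
  ann <- tryCatch(parse_predictions(rawToChar(res$content), endpoint$format),
                  error = function(e) NULL)
  if (is.null(ann)) return(list(delay = delay, status = "malformed"))
  list(delay = delay, status = "ok", annotations = ann)
}

probe_endpoint <- function(endpoint) {
  if (is.null(endpoint$status_url) ||
      !requireNamespace("curl", quietly = TRUE)) {
    return("up")
  }
  res <- tryCatch(curl::curl_fetch_memory(endpoint$status_url),
                  error = function(e) NULL)
  if (is.null(res)) "down" else if (res$status_code >= 400) "degraded"
  else "up"
}
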