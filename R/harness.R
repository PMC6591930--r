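#' Simulated annotation-server behaviour profiles
#'
#' A behaviour profile fully describes one simulated annotation server: its
#' latency model, scripted failure windows, caching behaviour and the entity
#' types it recognises. The tagging strategy is an honest dictionary tagger:
#' it annotates exactly the mentions embedded in the served document version
#' whose type it supports (so its output is always valid against the served
#' text). Setting `caches_predictions = TRUE` models the forbidden
#' behaviour: the server replays the payload from the first time it saw each
#' document id, ignoring later perturbed versions.
#'
#' @param server_id integer id.
#' @param latency latency model: `list(family = "constant", value = )`,
#'   `list(family = "exponential", mean = )`,
#'   `list(family = "lognormal", meanlog = , sdlog = )` or
#'   `list(family = "gamma", shape = , rate = )`; seconds.
#' @param per_doc_latency extra seconds per document in a batch.
#' @param failure_windows data frame with `start`, `end` columns (seconds of
#'   benchmark time); requests issued inside produce no response. Windows
#'   must be disjoint and ordered.
#' @param caches_documents,caches_predictions compliance flags; only
#'   prediction caching changes simulated behaviour.
#' @param malformed_rate probability that an otherwise-ok response is an
#'   unparseable payload.
#' @param error_rate probability of a transport error (no usable response).
#' @param supported_types entity types the server annotates (normalized).
#' @param format output format id the server responds in.
#' @param name optional display name.
#' @return an `anno_behavior` profile.
#' @export
behavior_profile <- function(server_id,
                             latency = list(family = "exponential", mean = 1),
                             per_doc_latency = 0,
                             failure_windows = NULL,
                             caches_documents = FALSE,
                             caches_predictions = FALSE,
                             malformed_rate = 0, error_rate = 0,
                             supported_types = reference_entity_types(),
                             format = "bioc_json", name = NULL) {
  pars <- unlist(latency[setdiff(names(latency), "family")])
  if (!length(pars) || any(pars <= 0 & names(pars) != "meanlog")) {
    abort_bench("latency parameters must be positive",
                class = "annobench_config_error")
  }
  if (!latency$family %in% c("constant", "exponential", "lognormal", "gamma")) {
    abort_bench(sprintf("unknown latency family '%s'", latency$family),
                class = "annobench_config_error")
  }
  fw <- if (is.null(failure_windows)) {
    tibble(start = double(), end = double())
  } else as_tibble(failure_windows)
  if (nrow(fw)) {
    fw <- dplyr::arrange(fw, .data$start)
    if (any(fw$end < fw$start) ||
        any(utils::head(fw$end, -1) > utils::tail(fw$start, -1))) {
      abort_bench("failure windows must be disjoint and ordered",
                  class = "annobench_config_error")
    }
  }
  check_format_id(format)
  structure(list(
    server_id = as.integer(server_id),
    name = name %||% paste0("server-", server_id),
    latency = latency, per_doc_latency = per_doc_latency,
    failure_windows = fw,
    caches_documents = isTRUE(caches_documents),
    caches_predictions = isTRUE(caches_predictions),
    malformed_rate = malformed_rate, error_rate = error_rate,
    supported_types = normalize_entity_type(supported_types),
    format = format,
    .cache = new.env(parent = emptyenv())
  ), class = "anno_behavior")
}

draw_latency <- function(model, n = 1L) {
  switch(model$family,
    constant = rep(model$value, n),
    exponential = stats::rexp(n, 1 / model$mean),
    lognormal = stats::rlnorm(n, model$meanlog, model$sdlog),
    gamma = stats::rgamma(n, shape = model$shape, rate = model$rate))
}

in_failure_window <- function(profile, t) {
  fw <- profile$failure_windows
  nrow(fw) > 0L && any(fw$start <= t & t < fw$end)
}

#' Probe a server's status
#'
#' Reflects the profile's scripted failure windows at the probe time:
#' `"down"` inside a failure window, `"up"` outside. A profile may carry
#' optional `degraded_windows` (same shape) reported as `"degraded"`.
#' For HTTP endpoints the status endpoint is queried instead.
#'
#' @param server an `anno_behavior` profile (or `anno_endpoint`).
#' @param time probe time, seconds of benchmark time.
#' @export
status_probe <- function(server, time = 0) {
  if (inherits(server, "anno_endpoint")) return(probe_endpoint(server))
  if (in_failure_window(server, time)) return("down")
  dw <- server$degraded_windows
  if (!is.null(dw) && any(dw$start <= time & time < dw$end)) {
    return("degraded")
  }
  "up"
}

honest_annotations <- function(profile, doc) {
  gt <- doc$ground_truth
  gt[normalize_entity_type(gt$entity_type) %in% profile$supported_types, ]
}

#' Simulate one server response
#'
#' The honest dictionary tagger annotates the exact served document
#' versions: one annotation per embedded mention of a supported type. With
#' `caches_predictions = TRUE` the payload recorded at the first sight of
#' each `doc_id` is replayed regardless of the served version. The delay is
#' one draw from the latency model plus the per-document increment times the
#' batch size; scripted failure windows and the malformed/error rates are
#' applied by [run_benchmark()], which owns the request timeline.
#'
#' @param profile an `anno_behavior` profile.
#' @param request a list with at least `request_id` and `issue_time`.
#' @param documents list of served documents as returned by [get_document()].
#' @return list with `delay` (seconds) and `annotations`
#'   (an `anno_predictions` tibble over the batch).
#' @export
simulate_server_response <- function(profile, request, documents) {
  delay <- draw_latency(profile$latency) +
    profile$per_doc_latency * length(documents)
  ann <- purrr::map(documents, function(doc) {
    if (profile$caches_predictions) {
      hit <- profile$.cache[[doc$doc_id]]
      if (!is.null(hit)) return(hit)
      fresh <- honest_annotations(profile, doc)
      assign(doc$doc_id, fresh, envir = profile$.cache)
      fresh
    } else {
      honest_annotations(profile, doc)
    }
  })
  # served ground truth is already validated; avoid re-validating per event
  ann <- if (length(ann) == 1L) ann[[1]] else if (length(ann)) {
    new_predictions(dplyr::bind_rows(ann))
  } else empty_predictions()
  list(delay = delay, annotations = ann)
}

#' Run a benchmark
#'
#' Dispatches every request of the plan to every server and records exactly
#' one response event per (request, server) pair, so the event log always
#' holds `nrow(plan) * length(servers)` events. Simulated servers run
#' against an event-driven virtual clock (issue times come from the plan;
#' latencies are model draws), so full campaigns replay in seconds of wall
#' time; `anno_endpoint` servers would be driven by the wall clock instead.
#'
#' Event statuses: `ok` (complete parseable response within the deadline),
#' `timeout` (no response before the deadline, including scripted failure
#' windows), `error` (transport error) and `malformed` (response arrived but
#' does not parse). Everything except `ok` counts as a failure for the
#' reliability metrics.
#'
#' For each request the harness serves the batch documents once from the
#' provider corpus (advancing compliance-document versions) and hands the
#' same served versions to every server.
#'
#' @param plan an `anno_plan` from [build_plan()].
#' @param servers a list of [behavior_profile()] objects (or a single one).
#' @param corpora a named list of `anno_corpus` objects keyed by provider
#'   (`patent`, `abstract`, `pubmed`), or a single corpus.
#' @param record_payloads which events keep the returned annotation payload
#'   in the log: `"compliance"` (default; batches touching a compliance
#'   document — all the cache detector needs), `"all"`, or `"none"`.
#' @param seed overrides the plan seed for the response randomness.
#' @return an `anno_eventlog` tibble with attributes `window` and
#'   `deadline`.
#' @export
run_benchmark <- function(plan, servers, corpora,
                          record_payloads = c("compliance", "all", "none"),
                          seed = NULL) {
  record_payloads <- match.arg(record_payloads)
  if (inherits(servers, "anno_behavior")) servers <- list(servers)
  if (inherits(corpora, "anno_corpus")) {
    corpora <- stats::setNames(list(corpora),
                               attr(corpora, "profile")$provider)
  }
  need <- unique(plan$provider)
  miss <- setdiff(need, names(corpora))
  if (length(miss)) {
    abort_bench(paste0("no corpus supplied for provider(s): ",
                       paste(miss, collapse = ", ")),
                class = "annobench_config_error")
  }
  seed <- seed %||% attr(plan, "seed") %||% 1L
  deadline <- attr(plan, "deadline") %||% 60
  nreq <- nrow(plan)
  nsrv <- length(servers)
  for (s in servers) {
    if (inherits(s, "anno_behavior")) rm(list = ls(s$.cache), envir = s$.cache)
  }
  n <- nreq * nsrv
  ev <- list(
    server_id = integer(n), request_id = character(n), provider = character(n),
    issue_time = double(n), receive_time = rep(NA_real_, n),
    status = character(n), response_time = rep(NA_real_, n),
    document_bytes = double(n), annotation_count = integer(n),
    doc_ids = vector("list", n), doc_versions = vector("list", n),
    payload = vector("list", n))
  srv_ids <- purrr::map_int(servers, "server_id")
  withr::with_seed(derive_seed(seed, 23L), {
    k <- 0L
    for (i in seq_len(nreq)) {
      prov <- plan$provider[i]
      t0 <- plan$issue_time[i]
      corpus <- corpora[[prov]]
      ids <- sample(corpus$doc_id, plan$batch_size[i],
                    replace = plan$batch_size[i] > nrow(corpus))
      served <- lapply(ids, function(d) get_document(corpus, d, t0))
      bytes <- sum(vapply(served, function(d) nchar(d$text, type = "bytes"),
                          1L))
      versions <- vapply(served, function(d) d$version, 1L)
      keep_payload <- record_payloads == "all" ||
        (record_payloads == "compliance" &&
           any(corpus$compliance[match(ids, corpus$doc_id)]))
      for (j in seq_len(nsrv)) {
        k <- k + 1L
        p <- servers[[j]]
        ev$server_id[k] <- srv_ids[j]
        ev$request_id[k] <- plan$request_id[i]
        ev$provider[k] <- prov
        ev$issue_time[k] <- t0
        ev$document_bytes[k] <- bytes
        ev$doc_ids[[k]] <- ids
        ev$doc_versions[[k]] <- versions
        if (inherits(p, "anno_endpoint")) {
          res <- call_endpoint(p, list(request_id = plan$request_id[i]),
                               served, deadline)
          ev$status[k] <- res$status
          if (res$status %in% c("ok", "malformed")) {
            ev$receive_time[k] <- t0 + res$delay
            ev$response_time[k] <- res$delay
          }
          if (res$status == "ok") {
            ev$annotation_count[k] <- nrow(res$annotations)
            if (keep_payload) ev$payload[[k]] <- res$annotations
          }
          next
        }
        if (in_failure_window(p, t0)) {
          ev$status[k] <- "timeout"
          next
        }
        resp <- simulate_server_response(p, list(request_id = plan$request_id[i],
                                                 issue_time = t0), served)
        if (resp$delay > deadline) {
          ev$status[k] <- "timeout"
          next
        }
        u <- stats::runif(1)
        if (u < p$error_rate) {
          ev$status[k] <- "error"
          next
        }
        if (u < p$error_rate + p$malformed_rate) {
          ev$status[k] <- "malformed"
          ev$receive_time[k] <- t0 + resp$delay
          ev$response_time[k] <- resp$delay
          next
        }
        ev$status[k] <- "ok"
        ev$receive_time[k] <- t0 + resp$delay
        ev$response_time[k] <- resp$delay
        ev$annotation_count[k] <- nrow(resp$annotations)
        if (keep_payload) ev$payload[[k]] <- resp$annotations
      }
    }
  })
  out <- tibble(!!!ev)
  out <- dplyr::arrange(out, .data$issue_time, .data$server_id)
  class(out) <- c("anno_eventlog", class(tibble()))
  attr(out, "window") <- attr(plan, "window") %||%
    (if (nreq) c(min(plan$issue_time), max(plan$issue_time)) else c(0, 0))
  attr(out, "deadline") <- deadline
  out
}

#' Default simulated server fleet from a registry
#'
#' Builds one honest behaviour profile per registry record: the server's
#' supported types come from its registration, its latency is an
#' exponential model with a seeded mean between 0.5 and 4 s, no failure
#' windows, no caching. Useful as the stock fleet for scaled campaign
#' replays.
#'
#' @param reg an `anno_registry`.
#' @param seed integer seed for the latency means.
#' @return a list of [behavior_profile()] objects.
#' @export
profiles_from_registry <- function(reg, seed = 1L) {
  means <- withr::with_seed(derive_seed(seed, 31L),
                            stats::runif(nrow(reg), 0.5, 4))
  purrr::map(seq_len(nrow(reg)), function(i) {
    behavior_profile(reg$server_id[i], name = reg$name[i],
                     latency = list(family = "exponential", mean = means[i]),
                     supported_types = reg$supported_types[[i]],
                     format = reg$supported_formats[[i]][1])
  })
}
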