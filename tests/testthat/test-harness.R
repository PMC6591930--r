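const_server <- function(id, value = 1, ...) {
  behavior_profile(id, latency = list(family = "constant", value = value), ...)
}

test_that("constant-latency servers answer every request at the scripted delay", {
  co <- tiny_corpus(10, seed = 1, compliance_fraction = 0)
  plan <- build_plan(plan_window(0, 1000, "regular", "patent", 100),
                     seed = 2, deadline = 5)
  log <- run_benchmark(plan, const_server(1, 1.0), co)
  expect_equal(nrow(log), 100L)
  expect_true(all(log$status == "ok"))
  expect_true(all(log$response_time == 1.0))
  expect_true(all(log$receive_time == log$issue_time + 1.0))
})

test_that("the event log conserves (requests x servers) exactly", {
  co <- tiny_corpus(8, seed = 3, compliance_fraction = 0.25)
  plan <- build_plan(plan_window(0, 500, "irregular", "patent", 37), seed = 9)
  servers <- list(const_server(1), const_server(2), const_server(3))
  log <- run_benchmark(plan, servers, co)
  expect_equal(nrow(log), 37L * 3L)
  expect_equal(anyDuplicated(paste(log$server_id, log$request_id)), 0L)
  # no event precedes its request; ok events respect the deadline
  expect_true(all(is.na(log$receive_time) |
                    log$receive_time >= log$issue_time))
  expect_true(all(log$response_time[log$status == "ok"] <=
                    attr(plan, "deadline")))
})

test_that("identical plans, profiles and corpora reproduce identical logs", {
  make_log <- function() {
    co <- tiny_corpus(10, seed = 4, compliance_fraction = 0.5)
    plan <- build_plan(plan_window(0, 300, "irregular", "patent", 30), seed = 6)
    srv <- list(behavior_profile(1, latency = list(family = "exponential",
                                                   mean = 0.8)),
                const_server(2, 0.3))
    run_benchmark(plan, srv, co)
  }
  a <- make_log()
  b <- make_log()
  expect_equal(as.data.frame(a[, 1:9]), as.data.frame(b[, 1:9]))
})

test_that("scripted failure windows produce timeouts for covered requests only", {
  co <- tiny_corpus(6, seed = 5, compliance_fraction = 0)
  plan <- build_plan(plan_window(0, 1000, "regular", "patent", 100),
                     seed = 2, deadline = 5)
  srv <- const_server(1, 0.5,
                      failure_windows = data.frame(start = 95, end = 195))
  log <- run_benchmark(plan, srv, co)
  expect_equal(sum(log$status == "timeout"), 10L)
  expect_equal(sum(log$status == "ok"), 90L)
  expect_true(all(log$issue_time[log$status == "timeout"] >= 95 &
                    log$issue_time[log$status == "timeout"] < 195))
})

test_that("latency draws beyond the deadline become timeouts", {
  co <- tiny_corpus(5, seed = 6, compliance_fraction = 0)
  plan <- build_plan(plan_window(0, 100, "regular", "patent", 50),
                     seed = 3, deadline = 1)
  srv <- behavior_profile(1, latency = list(family = "exponential", mean = 1))
  log <- run_benchmark(plan, srv, co)
  expect_true(all(log$status %in% c("ok", "timeout")))
  expect_true(any(log$status == "timeout"))
  expect_true(all(log$response_time[log$status == "ok"] <= 1))
})

test_that("the honest tagger annotates exactly the supported embedded mentions", {
  co <- tiny_corpus(20, seed = 7, compliance_fraction = 0)
  i <- which(purrr::map_int(co$ground_truth, nrow) >= 2)[1]
  doc <- get_document(co, co$doc_id[i])
  types <- unique(doc$ground_truth$entity_type)
  srv <- const_server(1, supported_types = types[1])
  resp <- simulate_server_response(srv, list(request_id = "r1",
                                             issue_time = 0), list(doc))
  expect_equal(nrow(resp$annotations),
               sum(doc$ground_truth$entity_type == types[1]))
  # payload validates against the served text (honest-by-construction)
  d <- document(doc$doc_id, doc$title, doc$abstract, "patent")
  expect_equal(nrow(validate_against_documents(resp$annotations, d)), 0L)
  # disjoint supported types: ok response with zero annotations
  srv0 <- const_server(2, supported_types = "martian_anatomy")
  resp0 <- simulate_server_response(srv0, list(request_id = "r1",
                                               issue_time = 0), list(doc))
  expect_equal(nrow(resp0$annotations), 0L)
})

test_that("a caching profile replays its first payload across document versions", {
  co <- tiny_corpus(4, seed = 8, compliance_fraction = 1)
  srv <- const_server(1, caches_predictions = TRUE)
  d <- co$doc_id[1]
  v1 <- get_document(co, d)
  v2 <- get_document(co, d)
  expect_equal(v2$version, 2L)
  r1 <- simulate_server_response(srv, list(request_id = "a", issue_time = 0),
                                 list(v1))
  r2 <- simulate_server_response(srv, list(request_id = "b", issue_time = 1),
                                 list(v2))
  expect_equal(as.data.frame(r1$annotations), as.data.frame(r2$annotations))
  # an honest profile re-annotates the new version instead
  honest <- const_server(2)
  h2 <- simulate_server_response(honest, list(request_id = "b",
                                              issue_time = 1), list(v2))
  expect_equal(as.data.frame(h2$annotations), as.data.frame(v2$ground_truth))
})

test_that("status probes reflect failure windows with transitions at boundaries", {
  srv <- const_server(1, failure_windows = data.frame(start = 10, end = 20))
  expect_equal(status_probe(srv, 5), "up")
  expect_equal(status_probe(srv, 10), "down")
  expect_equal(status_probe(srv, 19.9), "down")
  expect_equal(status_probe(srv, 20), "up")
})

test_that("zero servers yield an empty event log", {
  log <- bench_run(scale = 0.0001, seed = 1, servers = list(), corpus_n = 5)
  expect_equal(nrow(log), 0L)
})

test_that("event logs reload exactly from line-delimited records", {
  co <- tiny_corpus(6, seed = 9, compliance_fraction = 0.5)
  plan <- build_plan(plan_window(0, 60, "regular", "patent", 20), seed = 5)
  log <- run_benchmark(plan, const_server(1), co, record_payloads = "all")
  tf <- withr::local_tempfile(fileext = ".ndjson")
  write_event_log(log, tf)
  back <- read_event_log(tf)
  expect_equal(as.data.frame(back[, 1:9]), as.data.frame(log[, 1:9]))
  expect_identical(attr(back, "window"), attr(log, "window"))
  expect_identical(attr(back, "deadline"), attr(log, "deadline"))
  expect_identical(back$doc_ids, log$doc_ids)
  has_pay <- !purrr::map_lgl(log$payload, is.null)
  for (k in which(has_pay)) {
    expect_same_annotations(back$payload[[k]], log$payload[[k]])
  }
})

test_that("malformed and error rates surface as failure statuses", {
  co <- tiny_corpus(5, seed = 10, compliance_fraction = 0)
  plan <- build_plan(plan_window(0, 400, "regular", "patent", 400),
                     seed = 2, deadline = 10)
  srv <- const_server(1, 0.1, malformed_rate = 0.2, error_rate = 0.1)
  log <- run_benchmark(plan, srv, co)
  tab <- table(log$status)
  expect_gt(tab[["malformed"]], 0)
  expect_gt(tab[["error"]], 0)
  # malformed responses arrived (receive_time set) but count as failures
  expect_true(all(!is.na(log$receive_time[log$status == "malformed"])))
  expect_true(all(is.na(log$receive_time[log$status == "error"])))
})
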