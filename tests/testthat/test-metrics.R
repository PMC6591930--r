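test_that("an all-ok log has no downtime intervals", {
  log <- make_eventlog(tibble::tibble(
    server_id = 1L, issue_time = 1:10 * 10, status = "ok",
    response_time = 1, document_bytes = 100, annotation_count = 1L),
    window = c(0, 100))
  expect_equal(nrow(derive_downtime(log, 1L)), 0L)
  expect_error(derive_downtime(log, 99L), class = "annobench_not_found")
})

test_that("a failure run spans first failed issue to first subsequent ok issue", {
  issue <- seq(10, 300, by = 10)
  status <- rep("ok", length(issue))
  status[issue >= 100 & issue <= 190] <- "timeout"
  log <- make_eventlog(tibble::tibble(
    server_id = 1L, issue_time = issue, status = status,
    response_time = ifelse(status == "ok", 1, NA_real_),
    document_bytes = 100, annotation_count = 1L), window = c(0, 300))
  dt <- derive_downtime(log, 1L)
  expect_equal(nrow(dt), 1L)
  expect_equal(dt$start, 100)
  expect_equal(dt$end, 200)
})

test_that("downtime runs match a brute-force run-length scan on random logs", {
  for (seed in 1:10) {
    log <- random_event_log(seed)
    dt <- derive_downtime(log, 1L)
    # oracle: walk the ordered events and count failure runs
    ev <- log[order(log$issue_time), ]
    fail <- ev$status != "ok"
    runs <- 0L
    starts <- c()
    ends <- c()
    k <- 1L
    while (k <= length(fail)) {
      if (fail[k]) {
        runs <- runs + 1L
        starts <- c(starts, ev$issue_time[k])
        while (k <= length(fail) && fail[k]) k <- k + 1L
        ends <- c(ends, if (k <= length(fail)) ev$issue_time[k] else
          attr(log, "window")[2])
      } else k <- k + 1L
    }
    expect_equal(nrow(dt), runs)
    expect_equal(dt$start, starts)
    expect_equal(dt$end, ends)
  }
})

test_that("a never-failing server over the 53-day window has MTBF = window, MTTR = 0", {
  window <- c(0, 4579200) # 53 days
  log <- make_eventlog(tibble::tibble(
    server_id = 103L, issue_time = seq(60, 4579140, length.out = 500),
    status = "ok", response_time = 1.5, document_bytes = 1300,
    annotation_count = 2L), window = window)
  m <- compute_metrics(log, 103L)
  expect_equal(m$failures, 0L)
  expect_equal(m$MTBF, 4579200)
  expect_equal(m$MTTR, 0)
})

test_that("the six metrics match hand computation on a scripted log", {
  log <- make_eventlog(tibble::tibble(
    server_id = 7L, issue_time = c(10, 20, 30, 40), status = "ok",
    response_time = c(1, 2, 3, 4), document_bytes = c(100, 100, 200, 200),
    annotation_count = c(2L, 2L, 3L, 3L)), window = c(0, 100))
  m <- compute_metrics(log, 7L)
  expect_equal(m$ART, 2.5)
  expect_equal(m$MAD, 2.5)
  expect_equal(m$MTSA, 1.0)
  expect_equal(m$MTDV, 10 / 600)
  expect_equal(m$responses, 4L)
  expect_equal(m$predictions, 10L)
})

test_that("a server with only empty predictions has MAD 0 and undefined MTSA", {
  log <- make_eventlog(tibble::tibble(
    server_id = 108L, issue_time = 1:20 * 5, status = "ok",
    response_time = 36.3, document_bytes = 1200, annotation_count = 0L),
    window = c(0, 120))
  m <- compute_metrics(log, 108L)
  expect_equal(m$MAD, 0)
  expect_true(is.na(m$MTSA))
  expect_false(is.na(m$ART))
})

test_that("failed responses never enter the performance sums", {
  log <- make_eventlog(tibble::tibble(
    server_id = 1L, issue_time = 1:4 * 10,
    status = c("ok", "timeout", "malformed", "ok"),
    response_time = c(1, NA, 50, 3), document_bytes = 100,
    annotation_count = c(5L, 0L, 9L, 5L)), window = c(0, 50))
  m <- compute_metrics(log, 1L)
  expect_equal(m$responses, 2L)
  expect_equal(m$ART, 2)
  expect_equal(m$predictions, 10L)
})

test_that("the published results fixture reproduces the abstract's medians", {
  res <- load_fixture("results")
  ms <- median_summary(res)
  expect_equal(ms$median_ART, 3.74)
  expect_equal(ms$median_MAD_rounded, 10L)
})

test_that("median_summary equals a sort-based oracle and handles single servers", {
  for (seed in 1:6) {
    vals <- withr::with_seed(seed, tibble::tibble(
      server_id = 1:9, ART = stats::runif(9, 0.5, 100),
      MAD = stats::runif(9, 0, 40)))
    ms <- median_summary(vals)
    expect_equal(ms$median_ART, sort(vals$ART)[5])
    expect_equal(ms$median_MAD, sort(vals$MAD)[5])
  }
  one <- tibble::tibble(server_id = 1L, ART = 2.2, MAD = 7.7)
  ms1 <- median_summary(one)
  expect_equal(ms1$median_ART, 2.2)
  expect_equal(ms1$median_MAD, 7.7)
})

test_that("the leaderboard ranks the fastest responder first on the results fixture", {
  res <- load_fixture("results")
  lb <- leaderboard(res)
  expect_equal(lb$server_id[1], 122L)
  expect_equal(lb$ART[1], 1.07)
  leaders <- attr(lb, "leaders")
  expect_equal(unname(leaders[["ART"]]), 122L)
  expect_equal(unname(leaders[["predictions"]]), 120L)
  expect_equal(unname(leaders[["MAD"]]), 120L)
})

test_that("leaderboard order equals an independent sort oracle on random reports", {
  for (seed in 20:24) {
    m <- withr::with_seed(seed, tibble::tibble(
      server_id = sample(1:50, 12), ART = round(stats::runif(12, 1, 10), 2),
      MAD = round(stats::runif(12, 0, 30), 1)))
    lb <- leaderboard(m)
    oracle <- m[order(m$ART, -m$MAD, m$server_id), ]
    expect_equal(lb$server_id, oracle$server_id)
  }
  single <- tibble::tibble(server_id = 5L, ART = 1, MAD = 2)
  expect_equal(leaderboard(single)$rank, 1L)
})

test_that("caching verdicts: flagged cheats, cleared honest servers, insufficient evidence", {
  co <- tiny_corpus(6, seed = 15, compliance_fraction = 1)
  plan <- build_plan(plan_window(0, 120, "regular", "patent", 24,
                                 batch_size = 1L), seed = 3, deadline = 30)
  honest <- behavior_profile(1, latency = list(family = "constant",
                                               value = 0.2))
  cheat <- behavior_profile(2, latency = list(family = "constant",
                                              value = 0.2),
                            caches_predictions = TRUE)
  log <- run_benchmark(plan, list(honest, cheat), co)
  verdict <- detect_caching(log, co$doc_id[co$compliance])
  expect_equal(verdict$verdict[verdict$server_id == 1], "clear")
  expect_equal(verdict$verdict[verdict$server_id == 2], "flagged")
  # a single request: every compliance doc is served at most once
  plan1 <- build_plan(plan_window(0, 6, "regular", "patent", 1,
                                  batch_size = 1L), seed = 8, deadline = 30)
  co2 <- tiny_corpus(50, seed = 16, compliance_fraction = 1)
  log1 <- run_benchmark(plan1, honest, co2)
  v1 <- detect_caching(log1, co2$doc_id)
  expect_equal(v1$verdict, "insufficient_evidence")
})

test_that("reports assemble medians, provider breakdowns and tidy/glance views", {
  co <- tiny_corpus(10, seed = 17, compliance_fraction = 0.3)
  plan <- build_plan(plan_window(0, 200, "regular", "patent", 40), seed = 2)
  log <- run_benchmark(plan, list(
    behavior_profile(1, latency = list(family = "constant", value = 0.5)),
    behavior_profile(2, latency = list(family = "constant", value = 1.5))), co)
  rep <- metrics_report(log, co$doc_id[co$compliance])
  expect_s3_class(rep, "anno_report")
  expect_equal(nrow(rep$per_server), 2L)
  expect_equal(rep$medians$median_ART, 1.0)
  td <- tidy(rep)
  expect_equal(td$server_id, c(1L, 2L))
  gl <- glance(rep)
  expect_equal(gl$n_events, 80L)
  expect_equal(gl$n_flagged, 0L)
  # report writing produces the two export files
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "leaderboard.tsv")))
})
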