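# Seeded generators and constructors shared across the suite.

random_prediction_set <- function(n, seed) {
  withr::with_seed(seed, {
    len <- sample(1:15, n, replace = TRUE)
    predictions(
      doc_id = sprintf("DOC-%03d", sample(1:20, n, replace = TRUE)),
      section_id = sample(c("T", "A"), n, replace = TRUE),
      init = sample(0:500, n, replace = TRUE),
      length = len,
      score = round(stats::runif(n), 4),
      text = vapply(len, function(l) {
        paste(sample(letters, l, replace = TRUE), collapse = "")
      }, ""),
      entity_type = sample(reference_entity_types(), n, replace = TRUE),
      db_id = ifelse(stats::runif(n) < 0.5, "",
                     sprintf("DB:%04d", sample(9999, n, replace = TRUE)))
    )
  })
}

# order-independent comparison of two prediction sets as multisets
expect_same_annotations <- function(a, b) {
  key <- function(x) {
    x <- as.data.frame(x)[, c("doc_id", "section_id", "init", "length",
                              "score", "text", "entity_type", "db_id")]
    x[do.call(order, x), ]
  }
  ka <- key(a); kb <- key(b)
  rownames(ka) <- rownames(kb) <- NULL
  expect_equal(ka, kb)
}

# assemble an event log tibble directly (bypassing the harness) so metric
# formulas can be exercised on hand-scripted and random logs
make_eventlog <- function(df, window, deadline = 60) {
  df <- tibble::as_tibble(df)
  if (!"provider" %in% names(df)) df$provider <- "patent"
  if (!"request_id" %in% names(df)) {
    df$request_id <- sprintf("r%05d", seq_len(nrow(df)))
  }
  if (!"receive_time" %in% names(df)) {
    df$receive_time <- ifelse(df$status == "ok",
                              df$issue_time + df$response_time, NA_real_)
  }
  class(df) <- c("anno_eventlog", class(tibble::tibble()))
  attr(df, "window") <- window
  attr(df, "deadline") <- deadline
  df
}

random_event_log <- function(seed, nreq = 60, window = c(0, 1000)) {
  withr::with_seed(seed, {
    issue <- sort(stats::runif(nreq, window[1], window[2] - 10))
    status <- sample(c("ok", "timeout"), nreq, replace = TRUE,
                     prob = c(0.85, 0.15))
    make_eventlog(tibble::tibble(
      server_id = 1L,
      issue_time = issue,
      status = status,
      response_time = ifelse(status == "ok",
                             round(stats::runif(nreq, 0.1, 5), 3), NA_real_),
      document_bytes = sample(200:2000, nreq, replace = TRUE),
      annotation_count = ifelse(status == "ok",
                                sample(0:20, nreq, replace = TRUE), 0L)
    ), window = window)
  })
}

tiny_corpus <- function(n = 12, seed = 5, provider = "patent",
                        compliance_fraction = 0.5) {
  generate_corpus(
    provider_profile(provider, mean_length = 300, mention_density = 4,
                     compliance_fraction = compliance_fraction),
    n, seed)
}
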