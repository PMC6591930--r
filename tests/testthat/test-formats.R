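test_that("the worked BioC example parses to the published annotation", {
  p <- parse_predictions(load_fixture("example"), "bioc_xml")
  expect_equal(nrow(p), 1L)
  expect_equal(p$init, 103L)
  expect_equal(p$length, 13L)
  expect_equal(p$end, 116L)
  expect_equal(p$entity_type, "chemical")
  expect_equal(p$text, "hydrocodone")
  expect_equal(p$section_id, "A")
})

test_that("a collection with documents but no annotations parses to zero rows", {
  docs <- dplyr::bind_rows(document("D1", "t one", "a one"),
                           document("D2", "t two", "a two"))
  xml <- write_predictions(empty_predictions(), "bioc_xml",
                           documents = as_documents(docs))
  p <- parse_predictions(xml, "bioc_xml")
  expect_equal(nrow(p), 0L)
  expect_true(validate_bioc_xml(xml))
})

test_that("round-trip identity holds for every format", {
  for (seed in 1:8) {
    s <- random_prediction_set(50, seed)
    for (f in annobench_formats()) {
      expect_same_annotations(parse_predictions(write_predictions(s, f), f), s)
    }
  }
})

test_that("the TSV dialect has 8 tab-separated fields, end = init + length, no header", {
  p <- predictions("CA2073500C", "A", init = 103, length = 13,
                   text = "hydrocodone c", entity_type = "chemical",
                   score = 0.99, db_id = "CHEBI:5779")
  out <- write_predictions(p, "tsv")
  line <- strsplit(sub("\n$", "", out), "\t")[[1]]
  expect_length(line, 8L)
  expect_equal(line[3], "103")
  expect_equal(line[4], "116")
  expect_equal(write_predictions(empty_predictions(), "tsv"), "")
})

test_that("TSV readers accept CRLF and empty trailing db_id", {
  p <- predictions("D1", "A", 5, 3, text = "abc", entity_type = "gene")
  crlf <- gsub("\n", "\r\n", write_predictions(p, "tsv"))
  expect_same_annotations(parse_predictions(crlf, "tsv"), p)
})

test_that("serialized BioC XML validates against the declared schema", {
  for (seed in 1:5) {
    s <- random_prediction_set(20, seed)
    expect_true(validate_bioc_xml(write_predictions(s, "bioc_xml")))
  }
})

test_that("conversion preserves the annotation multiset across all ordered format pairs", {
  s <- random_prediction_set(100, seed = 99)
  pairs <- expand.grid(from = annobench_formats(), to = annobench_formats(),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    raw <- write_predictions(s, pairs$from[k])
    conv <- convert_format(raw, pairs$from[k], pairs$to[k])
    expect_same_annotations(parse_predictions(conv, pairs$to[k]), s)
  }
})

test_that("malformed payloads raise parse errors naming the problem site", {
  expect_error(parse_predictions("a\tb\tc\n", "tsv"),
               class = "annobench_parse_error")
  expect_error(parse_predictions("D1\tA\tx\t9\t1\tt\tgene\t\n", "tsv"),
               class = "annobench_parse_error")
  expect_error(parse_predictions("D1\tA\t9\t5\t1\tt\tgene\t\n", "tsv"),
               class = "annobench_parse_error")
  expect_error(parse_predictions("<collection><document></document></collection>",
                                 "bioc_xml"),
               class = "annobench_parse_error")
  no_loc <- paste0("<collection><document><id>D</id><passage>",
                   "<infon key=\"section\">A</infon><offset>0</offset>",
                   "<annotation><infon key=\"type\">gene</infon>",
                   "<text>t</text></annotation></passage></document>",
                   "</collection>")
  expect_error(parse_predictions(no_loc, "bioc_xml"),
               class = "annobench_parse_error")
  expect_error(parse_predictions("{not json", "bioc_json"),
               class = "annobench_parse_error")
  expect_error(parse_predictions("x", "becalm"),
               class = "annobench_unsupported_format")
})

test_that("invariant-violating predictions are refused at serialization", {
  bad <- predictions("D1", "A", 0, 3, text = "abc", entity_type = "gene")
  bad$score <- 2
  expect_error(write_predictions(bad, "tsv"),
               class = "annobench_invalid_predictions")
  bad2 <- predictions("D1", "A", 0, 3, text = "abc", entity_type = "gene")
  bad2$length <- 0L
  expect_error(write_predictions(bad2, "bioc_json"),
               class = "annobench_invalid_predictions")
})

test_that("validation flags out-of-bounds offsets, text mismatches and unknown types", {
  d <- document("D1", "Short title", "mentions of glucose appear here")
  txt <- document_text(d)
  ok <- predictions("D1", "A", init = 24, length = 7, text = "glucose",
                    entity_type = "chemical")
  expect_equal(nrow(validate_against_documents(ok, d)), 0L)
  # case-insensitive match is accepted
  ok$text <- "GLUCOSE"
  expect_equal(nrow(validate_against_documents(ok, d)), 0L)
  # init at exactly the document length is out of bounds
  oob <- predictions("D1", "A", init = txt$length, length = 1, text = "x",
                     entity_type = "chemical")
  v <- validate_against_documents(oob, d)
  expect_equal(v$kind, "offset_out_of_bounds")
  mism <- predictions("D1", "A", init = 0, length = 5, text = "wrong",
                      entity_type = "chemical")
  expect_equal(validate_against_documents(mism, d)$kind, "text_mismatch")
  unk <- predictions("D1", "A", init = 24, length = 7, text = "glucose",
                     entity_type = "martian")
  expect_equal(
    validate_against_documents(unk, d, reference_entity_types())$kind,
    "unknown_type")
  lost <- predictions("NOPE", "A", init = 0, length = 3, text = "abc",
                      entity_type = "gene")
  expect_equal(validate_against_documents(lost, d)$kind, "malformed_record")
})

test_that("a known number of corrupted annotations yields exactly that many violations", {
  co <- tiny_corpus(8, seed = 21, compliance_fraction = 0)
  docs <- as_documents(dplyr::bind_rows(purrr::map(seq_len(nrow(co)), ~
    document(co$doc_id[.x], co$title[.x], co$abstract[.x], "patent"))))
  gt <- as_predictions(dplyr::bind_rows(co$ground_truth))
  gt <- gt[seq_len(min(20L, nrow(gt))), ]
  expect_equal(nrow(validate_against_documents(gt, docs)), 0L)
  corrupt <- gt[1:5, ]
  corrupt$init <- corrupt$init + 3L
  corrupt$end <- corrupt$init + corrupt$length
  v <- validate_against_documents(dplyr::bind_rows(gt[-(1:5), ], corrupt),
                                  docs)
  expect_equal(nrow(v), 5L)
})
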