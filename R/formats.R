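#' Annotation interchange formats
#'
#' Three stand-off payload formats are supported over the shared prediction
#' model: `"bioc_xml"` (a BioC subset: collection > document > passage >
#' annotation, with section carried as a passage infon and positions as a
#' `location offset/length` pair), `"bioc_json"` (a field-for-field JSON
#' mirror of that subset) and `"tsv"` (eight tab-separated columns, no
#' header: document id, section, init, end, score, text, type, database id).
#' All offsets are 0-based characters over the newline-concatenated document
#' text; `end = init + length` (half-open). Readers accept LF and CRLF;
#' writers emit LF and UTF-8.
#'
#' @name formats
#' @return `annobench_formats()` returns the three format identifiers.
#' @export
annobench_formats <- function() c("bioc_xml", "bioc_json", "tsv")

check_format_id <- function(format_id) {
  if (!(is.character(format_id) && length(format_id) == 1L &&
        format_id %in% annobench_formats())) {
    abort_bench(paste0("unsupported format id: ",
                       paste(format_id, collapse = ", "),
                       " (expected one of ",
                       paste(annobench_formats(), collapse = ", "), ")"),
                class = "annobench_unsupported_format")
  }
  format_id
}

payload_text <- function(raw) {
  if (is.raw(raw)) raw <- rawToChar(raw)
  if (!is.character(raw) || length(raw) != 1L) {
    abort_bench("payload must be a single character string or a raw vector")
  }
  Encoding(raw) <- "UTF-8"
  if (!validUTF8(raw)) {
    abort_bench("payload is not valid UTF-8",
                class = "annobench_parse_error")
  }
  raw
}

#' Parse an annotation payload
#'
#' Parsing is total: every annotation record in the payload is returned, and
#' a malformed record raises a parse error naming the offending line or
#' element instead of being silently dropped.
#'
#' @param raw payload as a UTF-8 character scalar or raw vector.
#' @param format_id one of [annobench_formats()].
#' @return an `anno_predictions` tibble with attribute `source_format`.
#' @seealso [write_predictions()], [convert_format()], [read_predictions()]
#' @export
parse_predictions <- function(raw, format_id) {
  check_format_id(format_id)
  txt <- payload_text(raw)
  out <- switch(format_id,
    tsv = parse_tsv(txt),
    bioc_xml = parse_bioc_xml(txt),
    bioc_json = parse_bioc_json(txt)
  )
  new_predictions(validate_predictions(out), source_format = format_id)
}

#' Serialize predictions to a payload
#'
#' Refuses to serialize predictions that violate the type invariants.
#' For the BioC formats the passage skeleton is taken from `documents` when
#' supplied (so passage text and offsets are embedded); otherwise minimal
#' passages are synthesized per (document, section) pair.
#'
#' @param preds an `anno_predictions` tibble (see [predictions()]).
#' @param format_id one of [annobench_formats()].
#' @param documents optional document set ([as_documents()]) to embed.
#' @return the payload as a UTF-8 character scalar.
#' @export
write_predictions <- function(preds, format_id, documents = NULL) {
  check_format_id(format_id)
  preds <- as_predictions(preds)
  switch(format_id,
    tsv = write_tsv_payload(preds),
    bioc_xml = write_bioc_xml(preds, documents),
    bioc_json = write_bioc_json(preds, documents)
  )
}

#' Convert a payload between formats
#'
#' The annotation multiset (document, section, init, length, score, text,
#' type, database id) is preserved exactly; parse errors propagate.
#'
#' @inheritParams parse_predictions
#' @param from_id,to_id source and target format ids (identity permitted).
#' @export
convert_format <- function(raw, from_id, to_id) {
  write_predictions(parse_predictions(raw, from_id), to_id)
}

#' Read / write predictions from a file
#'
#' Thin file wrappers; the format is guessed from the extension
#' (`.xml`, `.json`, `.tsv`) unless given.
#'
#' @param path file path.
#' @param format_id format id; `NULL` to guess from the extension.
#' @inheritParams write_predictions
#' @export
read_predictions <- function(path, format_id = NULL) {
  format_id <- format_id %||% guess_format(path)
  parse_predictions(read_file_utf8(path), format_id)
}

#' @rdname read_predictions
#' @export
write_predictions_file <- function(preds, path, format_id = NULL,
                                   documents = NULL) {
  format_id <- format_id %||% guess_format(path)
  writeLines(write_predictions(preds, format_id, documents), path,
             sep = "", useBytes = TRUE)
  invisible(path)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    xml = "bioc_xml", json = "bioc_json", tsv = "tsv", txt = "tsv",
    abort_bench(paste0("cannot guess format from extension of ", path))
  )
}

read_file_utf8 <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}

## ---- TSV dialect -----------------------------------------------------------

split_lines <- function(txt) {
  lines <- strsplit(txt, "\r\n|\n", perl = TRUE)[[1]]
  lines[seq_len(max(which(nzchar(lines)), 0L))]
}

parse_tsv <- function(txt) {
  lines <- split_lines(txt)
  if (!length(lines)) return(empty_predictions())
  # keep trailing empty fields (db_id is often empty): append a sentinel
  fields <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  nfield <- lengths(fields)
  bad <- which(nfield != 8L)
  if (length(bad)) {
    abort_bench(sprintf(
      "TSV parse error: line %d has %d field(s), expected 8",
      bad[1], nfield[bad[1]]), class = "annobench_parse_error")
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  init <- suppressWarnings(as.integer(m[, 3]))
  end <- suppressWarnings(as.integer(m[, 4]))
  score <- suppressWarnings(as.double(m[, 5]))
  bad <- which(is.na(init) | is.na(end) | is.na(score))
  if (length(bad)) {
    abort_bench(sprintf("TSV parse error: line %d has non-numeric init/end/score",
                        bad[1]), class = "annobench_parse_error")
  }
  bad <- which(end <= init)
  if (length(bad)) {
    abort_bench(sprintf("TSV parse error: line %d has end <= init", bad[1]),
                class = "annobench_parse_error")
  }
  new_predictions(tibble(
    doc_id = m[, 1], section_id = m[, 2], init = init,
    length = end - init, end = end, score = score,
    text = m[, 6], entity_type = m[, 7], db_id = m[, 8]
  ))
}

write_tsv_payload <- function(preds) {
  if (!nrow(preds)) return("")
  if (any(grepl("[\t\n\r]", preds$text))) {
    abort_bench("annotation text containing tab or newline cannot be written as TSV",
                class = "annobench_invalid_predictions")
  }
  lines <- paste(preds$doc_id, preds$section_id, preds$init, preds$end,
                 formatC(preds$score, digits = 6, format = "g"),
                 preds$text, preds$entity_type, preds$db_id, sep = "\t")
  paste0(paste(lines, collapse = "\n"), "\n")
}

## ---- BioC XML subset -------------------------------------------------------

# passage skeleton used by both BioC writers: one row per (doc, section)
# with offset/text from `documents` when available
passage_skeleton <- function(preds, documents) {
  if (!is.null(documents)) {
    docs <- as_documents(documents, check = FALSE)
    skel <- docs[, c("doc_id", "section_id", "offset", "text")]
    extra <- dplyr::anti_join(
      dplyr::distinct(preds[, c("doc_id", "section_id")]),
      skel[, c("doc_id", "section_id")],
      by = c("doc_id", "section_id"))
    if (nrow(extra)) {
      extra$offset <- 0L
      extra$text <- ""
      skel <- dplyr::bind_rows(skel, extra)
    }
  } else {
    skel <- dplyr::distinct(preds[, c("doc_id", "section_id")])
    skel$offset <- 0L
    skel$text <- ""
  }
  # title before abstract, then lexicographic for any other labels
  skel$._rank <- match(skel$section_id, c("T", "A"), nomatch = 3L)
  skel <- dplyr::arrange(skel, .data$doc_id, .data$._rank, .data$section_id,
                         .data$offset)
  skel$._rank <- NULL
  skel
}

write_bioc_xml <- function(preds, documents = NULL) {
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "annobench")
  skel <- passage_skeleton(preds, documents)
  aid <- 0L
  for (d in unique(skel$doc_id)) {
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", d)
    dsk <- skel[skel$doc_id == d, ]
    for (i in seq_len(nrow(dsk))) {
      pnode <- xml2::xml_add_child(dnode, "passage")
      inf <- xml2::xml_add_child(pnode, "infon", dsk$section_id[i])
      xml2::xml_set_attr(inf, "key", "section")
      xml2::xml_add_child(pnode, "offset", as.character(dsk$offset[i]))
      xml2::xml_add_child(pnode, "text", dsk$text[i])
      ann <- preds[preds$doc_id == d & preds$section_id == dsk$section_id[i], ]
      for (j in seq_len(nrow(ann))) {
        aid <- aid + 1L
        anode <- xml2::xml_add_child(pnode, "annotation")
        xml2::xml_set_attr(anode, "id", as.character(aid))
        it <- xml2::xml_add_child(anode, "infon", ann$entity_type[j])
        xml2::xml_set_attr(it, "key", "type")
        isc <- xml2::xml_add_child(anode, "infon",
                                   formatC(ann$score[j], digits = 15,
                                           format = "g"))
        xml2::xml_set_attr(isc, "key", "score")
        if (nzchar(ann$db_id[j])) {
          idb <- xml2::xml_add_child(anode, "infon", ann$db_id[j])
          xml2::xml_set_attr(idb, "key", "db_id")
        }
        loc <- xml2::xml_add_child(anode, "location")
        xml2::xml_set_attr(loc, "offset", as.character(ann$init[j]))
        xml2::xml_set_attr(loc, "length", as.character(ann$length[j]))
        xml2::xml_add_child(anode, "text", ann$text[j])
      }
    }
  }
  as.character(root)
}

xml_text_first <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

parse_bioc_xml <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt),
    error = function(e) abort_bench(
      paste0("BioC XML parse error: ", conditionMessage(e)),
      class = "annobench_parse_error"))
  if (xml2::xml_name(doc) != "collection") {
    abort_bench("BioC XML parse error: root element must be <collection>",
                class = "annobench_parse_error")
  }
  rows <- list()
  for (dnode in xml2::xml_find_all(doc, "./document")) {
    did <- xml_text_first(dnode, "./id")
    if (is.na(did) || !nzchar(did)) {
      abort_bench("BioC XML parse error: <document> without an <id> element",
                  class = "annobench_parse_error")
    }
    for (pnode in xml2::xml_find_all(dnode, "./passage")) {
      section <- xml_text_first(pnode, './infon[@key="section"]')
      if (is.na(section)) section <- "A"
      for (anode in xml2::xml_find_all(pnode, "./annotation")) {
        type <- xml_text_first(anode, './infon[@key="type"]')
        if (is.na(type)) {
          abort_bench(sprintf(
            "BioC XML parse error: annotation in document %s lacks a type infon",
            did), class = "annobench_parse_error")
        }
        loc <- xml2::xml_find_first(anode, "./location")
        if (inherits(loc, "xml_missing")) {
          abort_bench(sprintf(
            "BioC XML parse error: annotation in document %s lacks a <location>",
            did), class = "annobench_parse_error")
        }
        init <- suppressWarnings(as.integer(xml2::xml_attr(loc, "offset")))
        len <- suppressWarnings(as.integer(xml2::xml_attr(loc, "length")))
        if (is.na(init) || is.na(len)) {
          abort_bench(sprintf(
            "BioC XML parse error: non-numeric location in document %s", did),
            class = "annobench_parse_error")
        }
        score <- xml_text_first(anode, './infon[@key="score"]')
        dbid <- xml_text_first(anode, './infon[@key="db_id"]')
        rows[[length(rows) + 1L]] <- tibble(
          doc_id = did, section_id = section, init = init, length = len,
          end = init + len,
          score = if (is.na(score)) 1 else as.double(score),
          text = xml_text_first(anode, "./text") %|NA|% "",
          entity_type = type, db_id = dbid %|NA|% "")
      }
    }
  }
  if (!length(rows)) return(empty_predictions())
  new_predictions(dplyr::bind_rows(rows))
}

`%|NA|%` <- function(x, y) if (length(x) != 1L || is.na(x)) y else x

#' Validate a BioC XML payload against the shipped schema
#'
#' The package declares its BioC subset as an XSD (shipped under
#' `extdata/bioc_subset.xsd`); this checks a payload against it.
#'
#' @param raw payload text or raw vector.
#' @return `TRUE`/`FALSE`, with validator messages in attribute `errors`.
#' @export
validate_bioc_xml <- function(raw) {
  schema <- xml2::read_xml(bioc_schema_path())
  xml2::xml_validate(xml2::read_xml(payload_text(raw)), schema)
}

#' @rdname validate_bioc_xml
#' @export
bioc_schema_path <- function() {
  system.file("extdata", "bioc_subset.xsd", package = "annobench",
              mustWork = TRUE)
}

## ---- BioC JSON mirror ------------------------------------------------------

write_bioc_json <- function(preds, documents = NULL) {
  skel <- passage_skeleton(preds, documents)
  aid <- 0L
  docs <- lapply(unique(skel$doc_id), function(d) {
    dsk <- skel[skel$doc_id == d, ]
    passages <- lapply(seq_len(nrow(dsk)), function(i) {
      ann <- preds[preds$doc_id == d & preds$section_id == dsk$section_id[i], ]
      annotations <- lapply(seq_len(nrow(ann)), function(j) {
        aid <<- aid + 1L
        infons <- list(type = ann$entity_type[j], score = ann$score[j])
        if (nzchar(ann$db_id[j])) infons$db_id <- ann$db_id[j]
        list(id = as.character(aid), infons = infons,
             locations = list(list(offset = ann$init[j],
                                   length = ann$length[j])),
             text = ann$text[j])
      })
      list(infons = list(section = dsk$section_id[i]),
           offset = dsk$offset[i], text = dsk$text[i],
           annotations = annotations)
    })
    list(id = d, passages = passages)
  })
  jsonlite::toJSON(list(source = "annobench", documents = docs),
                   auto_unbox = TRUE, digits = NA)
}

json_field <- function(x, name, where) {
  if (is.null(x[[name]])) {
    abort_bench(sprintf("BioC JSON parse error: %s lacks field '%s'",
                        where, name), class = "annobench_parse_error")
  }
  x[[name]]
}

parse_bioc_json <- function(txt) {
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) abort_bench(
      paste0("BioC JSON parse error: ", conditionMessage(e)),
      class = "annobench_parse_error"))
  rows <- list()
  for (d in obj$documents %||% list()) {
    did <- as.character(json_field(d, "id", "document"))
    for (p in d$passages %||% list()) {
      section <- as.character(p$infons$section %||% "A")
      for (a in p$annotations %||% list()) {
        where <- sprintf("annotation in document %s", did)
        type <- as.character(json_field(json_field(a, "infons", where),
                                        "type", where))
        loc <- (a$locations %||% list())[[1]] %||% NULL
        if (is.null(loc)) {
          abort_bench(paste0("BioC JSON parse error: ", where,
                             " lacks locations"),
                      class = "annobench_parse_error")
        }
        init <- as.integer(json_field(loc, "offset", where))
        len <- as.integer(json_field(loc, "length", where))
        rows[[length(rows) + 1L]] <- tibble(
          doc_id = did, section_id = section, init = init, length = len,
          end = init + len,
          score = as.double(a$infons$score %||% 1),
          text = as.character(a$text %||% ""),
          entity_type = type,
          db_id = as.character(a$infons$db_id %||% ""))
      }
    }
  }
  if (!length(rows)) return(empty_predictions())
  new_predictions(dplyr::bind_rows(rows))
}
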