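#' Built-in entity mention lexicon
#'
#' A small per-type lexicon (shipped under `extdata/entity_lexicon.tsv`)
#' from which the corpus generator draws the entity mentions it embeds. Each
#' of the twelve reference types carries at least six surface forms, so
#' perturbed document variants can always substitute a mention.
#'
#' @return a tibble with columns `entity_type`, `term`.
#' @export
entity_lexicon <- function() {
  path <- system.file("extdata", "entity_lexicon.tsv", package = "annobench",
                      mustWork = TRUE)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  as_tibble(x)
}

#' Document provider profiles
#'
#' A provider profile fixes the document model of one synthetic content
#' source. Defaults emulate the three providers of the first continuous
#' evaluation campaign: patents average 582 characters, abstract and
#' PubMed-style documents average 1326 characters. Lengths are drawn from a
#' normal distribution truncated at 50 characters; the dispersion defaults
#' to 30% of the mean. `mention_density` is the expected number of embedded
#' entity mentions per document (Poisson), and `type_mix` the distribution
#' over entity types (uniform over the reference vocabulary by default).
#' A `compliance_fraction` of the documents is flagged for per-request
#' perturbation so that prediction caching becomes detectable.
#'
#' @param provider `"patent"`, `"abstract"` or `"pubmed"`.
#' @param mean_length,length_dispersion document length model, characters.
#' @param mention_density expected mentions per document (>= 0).
#' @param type_mix named numeric vector of entity-type weights (normalized
#'   to sum to 1); names must be lexicon types.
#' @param compliance_fraction fraction of documents flagged as compliance
#'   (perturbed-on-request) documents.
#' @return a `provider_profile` list.
#' @export
provider_profile <- function(provider = c("patent", "abstract", "pubmed"),
                             mean_length = NULL, length_dispersion = NULL,
                             mention_density = NULL, type_mix = NULL,
                             compliance_fraction = 0.1) {
  provider <- match.arg(provider)
  mean_length <- mean_length %||% switch(provider, patent = 582, 1326)
  if (!is_scalar_number(mean_length) || mean_length <= 0) {
    abort_bench("mean_length must be a positive number",
                class = "annobench_config_error")
  }
  length_dispersion <- length_dispersion %||% (0.3 * mean_length)
  mention_density <- mention_density %||% switch(provider, patent = 4, 9)
  if (mention_density < 0) {
    abort_bench("mention_density must be >= 0",
                class = "annobench_config_error")
  }
  if (is.null(type_mix)) {
    type_mix <- stats::setNames(rep(1, 12), reference_entity_types())
  }
  if (is.null(names(type_mix)) || any(type_mix < 0) || sum(type_mix) <= 0) {
    abort_bench("type_mix must be a named non-negative vector",
                class = "annobench_config_error")
  }
  type_mix <- type_mix / sum(type_mix)
  structure(list(provider = provider, mean_length = mean_length,
                 length_dispersion = length_dispersion,
                 mention_density = mention_density, type_mix = type_mix,
                 compliance_fraction = compliance_fraction),
            class = "provider_profile")
}

make_word_pool <- function(n) {
  lens <- sample(2:9, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(letters, l, replace = TRUE),
                                 collapse = ""), "")
}

random_chars <- function(n) paste(sample(letters, n, replace = TRUE),
                                  collapse = "")

# Compose an abstract of exactly `a` characters (spaces included) from
# filler tokens plus the given mention strings. Mentions that do not fit the
# budget are dropped. Returns token offsets so ground truth can be located.
assemble_abstract <- function(a, mentions, pool) {
  chunks <- list()
  n_tok <- 0L
  len <- -1L # running length of paste(tokens, collapse = " ")
  mention_at <- integer(0)
  kept <- integer(0)
  push <- function(v) {
    chunks[[length(chunks) + 1L]] <<- v
    n_tok <<- n_tok + length(v)
    len <<- len + sum(nchar(v)) + length(v)
  }
  for (k in seq_along(mentions)) {
    nf <- sample.int(3L, 1L)
    fills <- sample(pool, nf, replace = TRUE)
    need <- sum(nchar(fills)) + nf + nchar(mentions[[k]]) + 1L
    if (len + need > a - 2L) next
    push(fills)
    push(mentions[[k]])
    mention_at <- c(mention_at, n_tok)
    kept <- c(kept, k)
  }
  if (n_tok == 0L) push(sample(pool, 1L))
  repeat {
    r <- a - len
    if (r < 15L) break
    ws <- sample(pool, max(4L, ceiling(r / 5)), replace = TRUE)
    cs <- cumsum(nchar(ws) + 1L)
    ws <- ws[cs <= r - 14L]
    if (length(ws)) push(ws) else push(sample(pool, 1L))
  }
  r <- a - len
  tokens <- unlist(chunks, use.names = FALSE)
  if (r == 1L) {
    tokens[1L] <- paste0(tokens[1L], random_chars(1L))
  } else if (r >= 2L) {
    tokens <- c(tokens, random_chars(r - 1L))
  }
  stopifnot(sum(nchar(tokens)) + length(tokens) - 1L == a)
  offsets <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  list(text = paste(tokens, collapse = " "),
       mention_offset = offsets[mention_at], kept = kept)
}

# Build one document version deterministically from (doc_seed, version).
# prev_key forces at least one mention substitution relative to version 1.
build_document <- function(doc_id, doc_seed, version, L, m_target, pool,
                           lex, type_mix, prev_key = NULL) {
  withr::with_seed(derive_seed(doc_seed, version), {
    nt <- sample(4:6, 1L)
    title_words <- sample(pool, nt, replace = TRUE)
    title <- paste(title_words, collapse = " ")
    while (nchar(title) > L - 31L && nt > 1L) {
      nt <- nt - 1L
      title <- paste(title_words[seq_len(nt)], collapse = " ")
    }
    if (nchar(title) > L - 31L) title <- substr(title, 1L, max(3L, L - 31L))
    a <- L - nchar(title) - 1L
    types <- if (m_target > 0L) {
      sample(names(type_mix), m_target, replace = TRUE, prob = type_mix)
    } else character(0)
    terms <- vapply(types, function(tp) sample(lex[[tp]], 1L), "",
                    USE.NAMES = FALSE)
    if (!is.null(prev_key) && length(terms) &&
        identical(sort(paste(types, terms)), sort(prev_key))) {
      alt <- setdiff(lex[[types[1L]]], terms[1L])
      if (length(alt)) terms[1L] <- sample(alt, 1L)
    }
    asm <- assemble_abstract(a, terms, pool)
    gt <- if (length(asm$kept)) {
      predictions(
        doc_id = doc_id, section_id = "A",
        init = nchar(title) + 1L + asm$mention_offset,
        length = nchar(terms[asm$kept]),
        score = 1, text = terms[asm$kept],
        entity_type = types[asm$kept], db_id = "")
    } else empty_predictions()
    list(title = title, abstract = asm$text,
         text = paste(title, asm$text, sep = "\n"), ground_truth = gt)
  })
}

#' Generate a synthetic document corpus
#'
#' Draws `n` documents from a provider profile, fully reproducible under
#' `seed` (the same profile and seed give byte-identical corpora). Documents
#' are pseudo-natural filler text (word-shaped random tokens) with real
#' entity mentions injected from the shipped lexicon at known offsets; the
#' embedded mentions form the ground truth that honest simulated taggers
#' return. Documents flagged as compliance documents always carry at least
#' one mention, so perturbed variants are distinguishable through an honest
#' tagger's output.
#'
#' @param profile a [provider_profile()].
#' @param n number of documents (>= 0).
#' @param seed integer seed.
#' @return an `anno_corpus` tibble with one row per document: `doc_id`,
#'   `provider`, `title`, `abstract`, `text`, `length`, `compliance`, and a
#'   `ground_truth` list-column of `anno_predictions`. Carries the serving
#'   state used by [get_document()].
#' @seealso [get_document()], [corpus_stats()], [export_corpus()]
#' @export
generate_corpus <- function(profile, n, seed) {
  stopifnot(inherits(profile, "provider_profile"), n >= 0)
  lex_tbl <- entity_lexicon()
  lex <- split(lex_tbl$term, lex_tbl$entity_type)
  missing_types <- setdiff(names(profile$type_mix), names(lex))
  if (length(missing_types)) {
    abort_bench(paste0("type_mix names absent from the lexicon: ",
                       paste(missing_types, collapse = ", ")),
                class = "annobench_config_error")
  }
  prefix <- toupper(substr(profile$provider, 1L, 3L))
  rows <- withr::with_seed(derive_seed(seed, 11L), {
    pool <- make_word_pool(3000L)
    L <- pmax(50L, as.integer(round(stats::rnorm(
      n, profile$mean_length, profile$length_dispersion))))
    m <- stats::rpois(n, profile$mention_density)
    compliance <- stats::runif(n) < profile$compliance_fraction
    m[compliance] <- pmax(1L, m[compliance])
    list(pool = pool, L = L, m = as.integer(m), compliance = compliance)
  })
  doc_id <- sprintf("%s-%06d", prefix, seq_len(n))
  doc_seed <- vapply(seq_len(n), function(i) derive_seed(seed, 100L + i), 1L)
  built <- purrr::map(seq_len(n), function(i) {
    build_document(doc_id[i], doc_seed[i], 1L, rows$L[i], rows$m[i],
                   rows$pool, lex, profile$type_mix)
  })
  out <- tibble(
    doc_id = doc_id,
    provider = profile$provider,
    title = purrr::map_chr(built, "title", .default = ""),
    abstract = purrr::map_chr(built, "abstract", .default = ""),
    text = purrr::map_chr(built, "text", .default = ""),
    length = nchar(purrr::map_chr(built, "text", .default = "")),
    compliance = rows$compliance,
    doc_seed = doc_seed,
    target_length = rows$L,
    target_mentions = rows$m,
    ground_truth = purrr::map(built, "ground_truth")
  )
  class(out) <- c("anno_corpus", class(tibble()))
  attr(out, "profile") <- profile
  attr(out, "seed") <- seed
  attr(out, "pool") <- rows$pool
  attr(out, "lexicon") <- lex
  attr(out, "state") <- new.env(parent = emptyenv())
  out
}

#' Serve a document from a corpus
#'
#' Emulates a document provider answering one request. Non-compliance
#' documents are version-stable: every request returns the same text at
#' version 1. Compliance documents return a freshly perturbed variant whose
#' version increments per serve (the first serve is the original). A
#' perturbation regenerates the filler text entirely and forces at least one
#' embedded mention substitution relative to the original, with the ground
#' truth recomputed consistently, so an honest tagger's output necessarily
#' differs between versions. The perturbation stream is deterministic given
#' the document seed and version.
#'
#' @param corpus an `anno_corpus`.
#' @param doc_id document identifier.
#' @param request_time optional request timestamp (recorded only).
#' @return a list with `doc_id`, `provider`, `title`, `abstract`, `text`,
#'   `version` and `ground_truth`.
#' @export
get_document <- function(corpus, doc_id, request_time = NULL) {
  i <- match(doc_id, corpus$doc_id)
  if (is.na(i)) {
    abort_bench(sprintf("document '%s' not found in corpus", doc_id),
                class = "annobench_not_found")
  }
  base <- list(doc_id = corpus$doc_id[i], provider = corpus$provider[i],
               title = corpus$title[i], abstract = corpus$abstract[i],
               text = corpus$text[i], version = 1L,
               ground_truth = corpus$ground_truth[[i]])
  if (!corpus$compliance[i]) return(base)
  st <- attr(corpus, "state")
  v <- (st[[doc_id]] %||% 0L) + 1L
  assign(doc_id, v, envir = st)
  if (v == 1L) return(base)
  prev <- corpus$ground_truth[[i]]
  built <- build_document(
    doc_id, corpus$doc_seed[i], v, corpus$target_length[i],
    corpus$target_mentions[i], attr(corpus, "pool"), attr(corpus, "lexicon"),
    attr(corpus, "profile")$type_mix,
    prev_key = paste(prev$entity_type, prev$text))
  list(doc_id = doc_id, provider = corpus$provider[i], title = built$title,
       abstract = built$abstract, text = built$text, version = v,
       ground_truth = built$ground_truth)
}

#' Reset the serving state of a corpus
#'
#' Clears the per-document version counters so a fresh benchmark run starts
#' from version 1 again.
#' @param corpus an `anno_corpus`.
#' @export
reset_corpus <- function(corpus) {
  st <- attr(corpus, "state")
  rm(list = ls(st), envir = st)
  invisible(corpus)
}

#' Corpus summary statistics
#'
#' @param corpus an `anno_corpus`.
#' @return a one-row tibble: `n`, `mean_length`, `median_length`,
#'   `n_mentions`, plus a `mentions_per_type` list-column.
#' @export
corpus_stats <- function(corpus) {
  types <- unlist(purrr::map(corpus$ground_truth,
                             ~ .x$entity_type), use.names = FALSE)
  per_type <- if (length(types)) {
    tb <- table(types)
    tibble(entity_type = names(tb), n_mentions = as.integer(tb))
  } else {
    tibble(entity_type = character(), n_mentions = integer())
  }
  tibble(
    n = nrow(corpus),
    mean_length = if (nrow(corpus)) mean(corpus$length) else 0,
    median_length = if (nrow(corpus)) stats::median(corpus$length) else 0,
    n_mentions = length(types),
    mentions_per_type = list(per_type)
  )
}

#' Export / import a corpus as plain text
#'
#' Writes one `<doc_id>.txt` per document under `<dir>/<provider>/`,
#' a `ground_truth.tsv` in the eight-column offset format, and a
#' `manifest.yaml` holding the profile, seed and per-document metadata
#' needed to re-serve (and re-perturb) the corpus after import.
#'
#' @param corpus an `anno_corpus`.
#' @param dir output directory (created if needed).
#' @export
export_corpus <- function(corpus, dir) {
  prov <- attr(corpus, "profile")$provider
  pdir <- file.path(dir, prov)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$text[i], file.path(pdir, paste0(corpus$doc_id[i], ".txt")),
               sep = "", useBytes = TRUE)
  }
  gt <- dplyr::bind_rows(corpus$ground_truth)
  writeLines(write_tsv_payload(as_predictions(gt)),
             file.path(pdir, "ground_truth.tsv"), sep = "", useBytes = TRUE)
  prof <- attr(corpus, "profile")
  yaml::write_yaml(list(
    profile = list(provider = prof$provider, mean_length = prof$mean_length,
                   length_dispersion = prof$length_dispersion,
                   mention_density = prof$mention_density,
                   type_mix = as.list(prof$type_mix),
                   compliance_fraction = prof$compliance_fraction),
    seed = attr(corpus, "seed"),
    documents = purrr::map(seq_len(nrow(corpus)), function(i) list(
      doc_id = corpus$doc_id[i], compliance = corpus$compliance[i],
      doc_seed = corpus$doc_seed[i],
      target_length = corpus$target_length[i],
      target_mentions = corpus$target_mentions[i]))
  ), file.path(pdir, "manifest.yaml"))
  invisible(pdir)
}

#' @rdname export_corpus
#' @param path a provider directory previously written by [export_corpus()].
#' @export
import_corpus <- function(path) {
  man <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  p <- man$profile
  profile <- provider_profile(p$provider, p$mean_length, p$length_dispersion,
                              p$mention_density, unlist(p$type_mix),
                              p$compliance_fraction)
  gt <- parse_tsv(read_file_utf8(file.path(path, "ground_truth.tsv")))
  rows <- purrr::map(man$documents, function(d) {
    txt <- read_file_utf8(file.path(path, paste0(d$doc_id, ".txt")))
    nl <- regexpr("\n", txt, fixed = TRUE)
    tibble(doc_id = d$doc_id, provider = p$provider,
           title = substr(txt, 1L, nl - 1L),
           abstract = substr(txt, nl + 1L, nchar(txt)),
           text = txt, length = nchar(txt),
           compliance = isTRUE(d$compliance),
           doc_seed = as.integer(d$doc_seed),
           target_length = as.integer(d$target_length),
           target_mentions = as.integer(d$target_mentions))
  })
  out <- dplyr::bind_rows(rows)
  out$ground_truth <- purrr::map(out$doc_id, function(d) {
    as_predictions(gt[gt$doc_id == d, ])
  })
  class(out) <- c("anno_corpus", class(tibble()))
  attr(out, "profile") <- profile
  attr(out, "seed") <- as.integer(man$seed)
  attr(out, "pool") <- withr::with_seed(derive_seed(man$seed, 11L),
                                        make_word_pool(3000L))
  lex_tbl <- entity_lexicon()
  attr(out, "lexicon") <- split(lex_tbl$term, lex_tbl$entity_type)
  attr(out, "state") <- new.env(parent = emptyenv())
  out
}
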