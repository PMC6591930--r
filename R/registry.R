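#' Reference entity-type vocabulary
#'
#' The twelve canonical biomedical entity types used across the harness:
#' chemical, protein, disease, organism, anatomical component, cell
#' line/type, mutation, gene, subcellular structure, tissue/organ, miRNA and
#' GO (Gene Ontology term). Labels are stored in snake_case; see
#' [normalize_entity_type()] for the accepted spellings.
#'
#' @return character vector of the twelve canonical labels.
#' @export
reference_entity_types <- function() {
  c("chemical", "protein", "disease", "organism", "anatomical_component",
    "cell_line_type", "mutation", "gene", "subcellular_structure",
    "tissue_organ", "mirna", "go")
}

#' Normalize entity-type labels
#'
#' Case-insensitive mapping of common spellings onto the canonical
#' vocabulary (e.g. "Chemical compound" -> "chemical", "Cell line/type" ->
#' "cell_line_type"). Unrecognized labels are lower-cased and
#' underscore-joined but otherwise kept — the vocabulary is open.
#'
#' @param x character vector of labels.
#' @export
normalize_entity_type <- function(x) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  key <- gsub("^_|_$", "", key)
  syn <- c(
    chemical = "chemical", chemical_compound = "chemical",
    chemical_entity = "chemical", chemicals = "chemical",
    protein = "protein", proteins = "protein",
    disease = "disease", diseases = "disease",
    organism = "organism", organisms = "organism", species = "organism",
    anatomical_component = "anatomical_component",
    anatomical_structure = "anatomical_component",
    anatomy = "anatomical_component",
    cell_line_type = "cell_line_type", cell_line = "cell_line_type",
    cell_type = "cell_line_type", cell = "cell_line_type",
    mutation = "mutation", mutations = "mutation", variant = "mutation",
    gene = "gene", genes = "gene",
    subcellular_structure = "subcellular_structure",
    subcellular = "subcellular_structure",
    tissue_organ = "tissue_organ", tissue = "tissue_organ",
    organ = "tissue_organ",
    mirna = "mirna", mi_rna = "mirna",
    go = "go", go_term = "go", gene_ontology = "go"
  )
  out <- unname(syn[key])
  out[is.na(out)] <- key[is.na(out)]
  out
}

registry_mandatory_fields <- function() {
  c("name", "institution", "admin_contact", "programming_language",
    "supported_types", "supported_formats", "version")
}

registry_recommended_fields <- function() {
  c("license", "third_party_components", "dedicated_server", "references")
}

registry_optional_fields <- function() c("os", "hardware", "distributed")

#' Load an annotation-server registry
#'
#' Registries are human-editable YAML files with a top-level `servers` list.
#' Metadata falls into three tiers: the mandatory tier (name, institution,
#' admin contact, main programming language, non-empty supported entity
#' types, non-empty supported formats, software version) is validated on
#' load and a missing field is a registration error naming the server and
#' field; recommended (license, third-party components, dedicated server,
#' references) and optional (OS, hardware, distributed processing) fields
#' are reported through the per-record `completeness` tier. Unknown keys are
#' preserved in the `extra` list-column, not rejected.
#'
#' @param x path to a YAML registry file, or an already-parsed list with a
#'   `servers` element.
#' @return an `anno_registry` tibble, one row per server, with
#'   `completeness` in `"mandatory" < "recommended" < "complete"`.
#' @seealso [coverage_summary()], [write_registry()], [load_fixture()]
#' @export
load_registry <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  recs <- x$servers %||% x
  if (!length(recs)) {
    out <- empty_registry()
    return(out)
  }
  known <- c("server_id", registry_mandatory_fields(),
             registry_recommended_fields(), registry_optional_fields())
  rows <- purrr::map(recs, function(r) {
    sid <- r$server_id
    if (is.null(sid)) abort_bench("registry record lacks a server_id",
                                  class = "annobench_registration_error")
    for (f in registry_mandatory_fields()) {
      v <- r[[f]]
      if (is.null(v) || !length(v) || all(!nzchar(as.character(v)))) {
        abort_bench(sprintf(
          "registration error: server %s is missing mandatory field '%s'",
          sid, f), class = "annobench_registration_error")
      }
    }
    fmts <- as.character(r$supported_formats)
    bad <- setdiff(fmts, annobench_formats())
    if (length(bad)) {
      abort_bench(sprintf(
        "registration error: server %s declares unsupported format(s): %s",
        sid, paste(bad, collapse = ", ")),
        class = "annobench_registration_error")
    }
    has_rec <- all(purrr::map_lgl(registry_recommended_fields(),
                                  ~ !is.null(r[[.x]])))
    has_opt <- all(purrr::map_lgl(registry_optional_fields(),
                                  ~ !is.null(r[[.x]])))
    tibble(
      server_id = as.integer(sid),
      name = as.character(r$name),
      institution = as.character(r$institution),
      admin_contact = as.character(r$admin_contact),
      programming_language = as.character(r$programming_language),
      version = as.character(r$version),
      supported_types = list(normalize_entity_type(
        as.character(r$supported_types))),
      supported_formats = list(fmts),
      license = as.character(r$license %||% NA_character_),
      third_party_components = list(r$third_party_components),
      dedicated_server = as.logical(r$dedicated_server %||% NA),
      references = list(r$references),
      os = as.character(r$os %||% NA_character_),
      hardware = as.character(r$hardware %||% NA_character_),
      distributed = as.character(r$distributed %||% NA_character_),
      completeness = if (has_rec && has_opt) "complete"
                     else if (has_rec) "recommended" else "mandatory",
      extra = list(r[setdiff(names(r), known)])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$server_id)) {
    abort_bench("registration error: duplicated server_id",
                class = "annobench_registration_error")
  }
  class(out) <- c("anno_registry", class(tibble()))
  out
}

empty_registry <- function() {
  out <- tibble(
    server_id = integer(), name = character(), institution = character(),
    admin_contact = character(), programming_language = character(),
    version = character(), supported_types = list(),
    supported_formats = list(), license = character(),
    third_party_components = list(), dedicated_server = logical(),
    references = list(), os = character(), hardware = character(),
    distributed = character(), completeness = character(), extra = list())
  class(out) <- c("anno_registry", class(tibble()))
  out
}

#' Write a registry back to YAML
#'
#' Round-trips with [load_registry()]: loading the written file reproduces
#' the registry (unknown keys included).
#'
#' @param reg an `anno_registry` tibble.
#' @param path output file.
#' @export
write_registry <- function(reg, path) {
  recs <- purrr::map(seq_len(nrow(reg)), function(i) {
    r <- list(
      server_id = reg$server_id[i],
      name = reg$name[i],
      institution = reg$institution[i],
      admin_contact = reg$admin_contact[i],
      programming_language = reg$programming_language[i],
      version = reg$version[i],
      supported_types = as.list(reg$supported_types[[i]]),
      supported_formats = as.list(reg$supported_formats[[i]])
    )
    if (!is.na(reg$license[i])) r$license <- reg$license[i]
    if (!is.null(reg$third_party_components[[i]])) {
      r$third_party_components <- reg$third_party_components[[i]]
    }
    if (!is.na(reg$dedicated_server[i])) {
      r$dedicated_server <- reg$dedicated_server[i]
    }
    if (!is.null(reg$references[[i]])) r$references <- reg$references[[i]]
    for (f in registry_optional_fields()) {
      if (!is.na(reg[[f]][i])) r[[f]] <- reg[[f]][i]
    }
    c(r, reg$extra[[i]])
  })
  yaml::write_yaml(list(servers = recs), path)
  invisible(path)
}

#' Entity-type coverage statistics over a registry
#'
#' Counts computed exactly over the server-by-type support matrix: the
#' number of distinct supported types, servers per type, types per server,
#' the maximum number of types on a single server, and the number of
#' theoretically extractable pairwise co-occurrence relation types,
#' `k * (k - 1) / 2` for `k` distinct types.
#'
#' @param reg an `anno_registry` tibble (empty gives an all-zero summary).
#' @return an `anno_coverage` list; see also [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
coverage_summary <- function(reg) {
  types <- unlist(reg$supported_types)
  support <- if (length(types)) {
    tibble(entity_type = names(sort(-table(types))),
           n_servers = as.integer(sort(-table(types)) * -1))
  } else {
    tibble(entity_type = character(), n_servers = integer())
  }
  per_server <- tibble(server_id = reg$server_id,
                       n_types = lengths(reg$supported_types))
  k <- dplyr::n_distinct(types)
  out <- list(
    distinct_types = k,
    support_per_type = support,
    types_per_server = per_server,
    max_types_single_server = if (nrow(per_server)) max(per_server$n_types)
                              else 0L,
    pairwise_relation_types = pairwise_relation_type_count(k)
  )
  class(out) <- "anno_coverage"
  out
}

#' Number of pairwise co-occurrence relation types
#'
#' For `k` distinct entity types, the number of unordered distinct type
#' pairs, `k * (k - 1) / 2`.
#'
#' @param k non-negative integer count of distinct entity types.
#' @export
pairwise_relation_type_count <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0))
  as.integer(k * (k - 1) / 2)
}

#' @export
print.anno_coverage <- function(x, ...) {
  cat("Entity-type coverage\n")
  cat("  distinct types:           ", x$distinct_types, "\n")
  cat("  max types, single server: ", x$max_types_single_server, "\n")
  cat("  pairwise relation types:  ", x$pairwise_relation_types, "\n")
  cat("  support per type:\n")
  print(x$support_per_type, n = Inf)
  invisible(x)
}
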