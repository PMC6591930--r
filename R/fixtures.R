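#' Load the shipped campaign fixtures
#'
#' Three fixtures transcribed from the published first-campaign tables ship
#' with the package and are validated on load:
#'
#' * `"registry"` — the 15 annotation servers with metadata and supported
#'   entity types (12 distinct types overall). The per-server type
#'   assignments are a reconstruction consistent with the published
#'   marginal counts; see the fixture file header.
#' * `"schedule"` — the 14 (provider, kind, month) request-count cells of
#'   the two-month campaign (318,629 requests in total).
#' * `"results"` — the published per-server evaluation results (8 metric
#'   columns; the MTSA of the server that returned only empty prediction
#'   files is the undefined sentinel `NA`).
#' * `"example"` — the worked single-annotation BioC payload (returned as
#'   the raw payload text; parse with [parse_predictions()]).
#'
#' @param name one of `"registry"`, `"schedule"`, `"results"`, `"example"`.
#' @export
load_fixture <- function(name) {
  if (!(is.character(name) && length(name) == 1L &&
        name %in% c("registry", "schedule", "results", "example"))) {
    abort_bench(paste0("unknown fixture '", paste(name, collapse = ","),
                       "'; expected registry, schedule, results or example"),
                class = "annobench_not_found")
  }
  ext <- function(f) system.file("extdata", f, package = "annobench",
                                 mustWork = TRUE)
  switch(name,
    registry = {
      reg <- load_registry(ext("registry_tips2017_synthetic.yaml"))
      stopifnot(nrow(reg) == 15L,
                dplyr::n_distinct(unlist(reg$supported_types)) == 12L)
      reg
    },
    schedule = {
      sched <- as_tibble(utils::read.delim(ext("schedule_tips2017.tsv"),
                                           sep = "\t"))
      stopifnot(nrow(sched) == 14L,
                identical(names(sched), c("provider", "kind", "month", "n")))
      sched
    },
    results = {
      res <- as_tibble(utils::read.delim(ext("results_tips2017.tsv"),
                                         sep = "\t"))
      stopifnot(nrow(res) == 15L, ncol(res) == 9L,
                identical(names(res),
                          c("server_id", "requests", "predictions", "MTSA",
                            "MTDV", "MAD", "ART", "MTBF", "MTTR")))
      res
    },
    example = read_file_utf8(ext("example_prediction_synthetic.xml"))
  )
}
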