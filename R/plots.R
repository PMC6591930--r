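#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_tile
#'   labs scale_y_log10 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods and `plot_*()` helpers for the main result types:
#' per-server response-time bars for reports and metrics, request-schedule
#' timelines for plans, response-time histograms for event logs, and a
#' support heatmap for registries.
#'
#' @param object,x the object to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @name annobench-plots
NULL

#' @rdname annobench-plots
#' @method autoplot anno_metrics
#' @export
autoplot.anno_metrics <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$server_id), y = .data$ART)) +
    geom_col() +
    scale_y_log10() +
    labs(x = "server", y = "average response time (s, log scale)",
         title = "Average response time per server") +
    theme_minimal()
}

#' @rdname annobench-plots
#' @method autoplot anno_report
#' @export
autoplot.anno_report <- function(object, ...) {
  autoplot.anno_metrics(object$per_server, ...)
}

#' @rdname annobench-plots
#' @method autoplot anno_coverage
#' @export
autoplot.anno_coverage <- function(object, ...) {
  ggplot(object$support_per_type,
         aes(x = stats::reorder(.data$entity_type, .data$n_servers),
             y = .data$n_servers)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "supporting servers",
         title = "Server support per entity type") +
    theme_minimal()
}

#' @rdname annobench-plots
#' @param bin_width histogram/timeline bin width in seconds (defaults to a
#'   week for plans).
#' @export
plot_request_schedule <- function(x, bin_width = 7 * 86400) {
  ggplot(as_tibble(x),
         aes(x = .data$issue_time / 86400, fill = .data$provider)) +
    geom_histogram(binwidth = bin_width / 86400, position = "stack") +
    labs(x = "benchmark time (days)", y = "requests",
         title = "Issued requests over the evaluation period") +
    theme_minimal()
}

#' @rdname annobench-plots
#' @export
plot_response_times <- function(x) {
  ok <- dplyr::filter(as_tibble(x), .data$status == "ok")
  ggplot(ok, aes(x = .data$response_time)) +
    geom_histogram(bins = 40) +
    facet_wrap(~server_id, scales = "free_y") +
    labs(x = "response time (s)", y = "responses",
         title = "Response-time distribution per server") +
    theme_minimal()
}

#' @rdname annobench-plots
#' @export
plot_type_support <- function(x) {
  m <- tidyr::unnest(
    tibble(server_id = x$server_id, entity_type = x$supported_types),
    "entity_type")
  ggplot(m, aes(x = factor(.data$server_id), y = .data$entity_type)) +
    geom_tile() +
    labs(x = "server", y = NULL,
         title = "Entity-type support matrix") +
    theme_minimal()
}
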