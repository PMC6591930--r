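#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` returns the row-wise content of a result object as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x an `anno_report`, `anno_metrics` or `anno_coverage` object.
#' @param ... unused.
#' @name annobench-tidiers
NULL

#' @rdname annobench-tidiers
#' @method tidy anno_report
#' @export
tidy.anno_report <- function(x, ...) as_tibble(x$per_server)

#' @rdname annobench-tidiers
#' @method glance anno_report
#' @export
glance.anno_report <- function(x, ...) {
  tibble(
    n_servers = nrow(x$per_server),
    n_requests = x$n_requests,
    n_events = x$n_events,
    window_length = x$window[2] - x$window[1],
    median_ART = x$medians$median_ART,
    median_MAD = x$medians$median_MAD,
    median_MAD_rounded = x$medians$median_MAD_rounded,
    n_flagged = if (is.null(x$caching)) NA_integer_ else
      sum(x$caching$verdict == "flagged")
  )
}

#' @rdname annobench-tidiers
#' @method tidy anno_metrics
#' @export
tidy.anno_metrics <- function(x, ...) as_tibble(x)

#' @rdname annobench-tidiers
#' @method glance anno_metrics
#' @export
glance.anno_metrics <- function(x, ...) median_summary(x)[, 1:3]

#' @rdname annobench-tidiers
#' @method tidy anno_coverage
#' @export
tidy.anno_coverage <- function(x, ...) as_tibble(x$support_per_type)

#' @rdname annobench-tidiers
#' @method glance anno_coverage
#' @export
glance.anno_coverage <- function(x, ...) {
  tibble(distinct_types = x$distinct_types,
         max_types_single_server = x$max_types_single_server,
         pairwise_relation_types = x$pairwise_relation_types)
}
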