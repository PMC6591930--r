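#' Request-plan window definitions
#'
#' A plan is built from windows. Each window issues `n` requests of one
#' `kind` within `[start, start + duration)` seconds of benchmark time:
#' `"regular"` windows place requests at the end of each of `n` equal
#' subintervals (so a 100 s window with 10 requests issues at 10, 20, ...,
#' 100 s); `"irregular"` windows draw the `n` issue times uniformly within
#' the window from the plan seed, emulating bursty load. The provider is
#' one of `"patent"`, `"abstract"`, `"pubmed"`, or `"mix"` (each request
#' samples one of the three).
#'
#' @param start window start, seconds of benchmark time.
#' @param duration window length in seconds (> 0).
#' @param kind `"regular"` or `"irregular"`.
#' @param provider `"patent"`, `"abstract"`, `"pubmed"` or `"mix"`.
#' @param n number of requests in the window at scale 1.
#' @param batch_size documents per request: a single count or a vector to
#'   sample from uniformly.
#' @return a one-row window tibble, ready to bind into a window table.
#' @export
plan_window <- function(start, duration, kind = c("regular", "irregular"),
                        provider = c("patent", "abstract", "pubmed", "mix"),
                        n, batch_size = 1L) {
  kind <- match.arg(kind)
  provider <- match.arg(provider)
  stopifnot(duration > 0, n >= 0)
  tibble(start = as.double(start), duration = as.double(duration),
         kind = kind, provider = provider, n = as.double(n),
         batch_size = list(as.integer(batch_size)))
}

#' Shipped plan templates
#'
#' `"tips2017"` reproduces the published two-month request schedule: 14
#' (provider, kind, month) cells over a 53-day evaluation window (early
#' February through late March, 4,579,200 s), totalling 318,629 requests at
#' scale 1. The first month spans days 0-23, the second days 24-52.
#'
#' @param name template name (currently `"tips2017"`).
#' @return a window table for [build_plan()].
#' @export
plan_template <- function(name = "tips2017") {
  if (!identical(name, "tips2017")) {
    abort_bench(sprintf("unknown plan template '%s'", name),
                class = "annobench_config_error")
  }
  sched <- load_fixture("schedule")
  day <- 86400
  feb <- c(start = 0, duration = 24 * day)
  mar <- c(start = 24 * day, duration = 29 * day)
  dplyr::bind_rows(purrr::pmap(sched, function(provider, kind, month, n) {
    w <- if (month == 1) feb else mar
    plan_window(w[["start"]], w[["duration"]], kind, provider, n)
  }))
}

#' Expand windows into a request plan
#'
#' Deterministic under `seed`. Windows of the same provider and kind may
#' not overlap. `scale` multiplies every window's request count (rounded),
#' so desk-scale replays of a full campaign are a matter of `scale = 0.01`.
#'
#' @param windows a window table ([plan_window()], [plan_template()]).
#' @param seed integer seed driving irregular issue times, provider mixes
#'   and batch-size draws.
#' @param deadline seconds allowed per response (default 60).
#' @param scale multiplier on window request counts (> 0).
#' @return an `anno_plan` tibble, one row per request, ordered by
#'   `issue_time`, with attributes `seed`, `deadline` and `window` (the
#'   evaluation start/end).
#' @export
build_plan <- function(windows, seed = 1L, deadline = 60, scale = 1) {
  stopifnot(scale > 0, deadline > 0)
  if (!nrow(windows)) {
    out <- tibble(request_id = character(), window_id = integer(),
                  issue_time = double(), kind = character(),
                  window_provider = character(), provider = character(),
                  batch_size = integer())
    class(out) <- c("anno_plan", class(tibble()))
    attr(out, "seed") <- as.integer(seed)
    attr(out, "deadline") <- deadline
    attr(out, "window") <- c(0, 0)
    return(out)
  }
  windows <- dplyr::arrange(windows, .data$start)
  # overlap check within (provider, kind)
  conf <- windows |>
    dplyr::group_by(.data$provider, .data$kind) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(overlap = any(utils::head(.data$start + .data$duration, -1) >
                                     utils::tail(.data$start, -1) + 1e-9),
                     .groups = "drop") |>
    dplyr::filter(.data$overlap)
  if (nrow(conf)) {
    abort_bench(paste0("overlapping windows with conflicting provider/kind: ",
                       paste(conf$provider, conf$kind, collapse = "; ")),
                class = "annobench_config_error")
  }
  reqs <- withr::with_seed(derive_seed(seed, 17L), {
    purrr::map(seq_len(nrow(windows)), function(i) {
      w <- windows[i, ]
      n <- as.integer(round(w$n * scale))
      if (n == 0L) return(NULL)
      times <- if (w$kind == "regular") {
        w$start + seq_len(n) * (w$duration / n)
      } else {
        sort(stats::runif(n, w$start, w$start + w$duration))
      }
      provider <- if (w$provider == "mix") {
        sample(c("patent", "abstract", "pubmed"), n, replace = TRUE)
      } else rep(w$provider, n)
      bs <- w$batch_size[[1]]
      batch <- if (length(bs) == 1L) rep(bs, n) else sample(bs, n, replace = TRUE)
      tibble(window_id = i, issue_time = times, kind = w$kind,
             window_provider = w$provider, provider = provider,
             batch_size = batch)
    })
  })
  out <- dplyr::bind_rows(reqs) |> dplyr::arrange(.data$issue_time)
  out$request_id <- sprintf("r%07d", seq_len(nrow(out)))
  out <- out[, c("request_id", "window_id", "issue_time", "kind",
                 "window_provider", "provider", "batch_size")]
  class(out) <- c("anno_plan", class(tibble()))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "deadline") <- deadline
  attr(out, "window") <- c(min(windows$start),
                           max(windows$start + windows$duration))
  out
}
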