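#' Early-window specification
#'
#' An early window is a prefix of a clickstream defined either by a fixed
#' number of actions (`mode = "actions"`, width w^a) or by a fixed amount of
#' elapsed time in seconds (`mode = "time"`, width w^t).
#'
#' @param mode `"actions"` or `"time"`.
#' @param w Positive window width: an integer action count, or seconds.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec("actions", 4)
#' window_spec("time", 30)
#' @export
window_spec <- function(mode = c("actions", "time"), w) {
  mode <- match.arg(mode)
  if (!is.numeric(w) || length(w) != 1 || !is.finite(w) || w <= 0) {
    stop("`w` must be a positive number", call. = FALSE)
  }
  if (mode == "actions" && w != round(w)) {
    stop("`w` must be an integer in actions mode", call. = FALSE)
  }
  structure(list(mode = mode, w = if (mode == "actions") as.integer(w)
                 else as.numeric(w)),
            class = "window_spec")
}

format_spec <- function(spec) {
  if (spec$mode == "full") "full sequences"
  else sprintf("%s window w = %s", spec$mode, spec$w)
}

#' Per-stream Earliness metrics
#'
#' Earliness measures the relative distance between the point at which a
#' prediction is made and the end of the sequence; higher values mean earlier
#' predictions. For an included stream with untrimmed length `a_i` and time on
#' task `t_i`:
#' \describe{
#'   \item{actions mode (width w^a)}{action metric `1 - w^a / a_i`; time
#'     metric `1 - t_i^{w^a} / t_i`, where `t_i^{w^a}` is the time required to
#'     perform the first w^a actions (the w^a-th timestamp).}
#'   \item{time mode (width w^t)}{action metric `1 - a_i^{w^t} / a_i`, where
#'     `a_i^{w^t}` is the number of actions performed up to time w^t; time
#'     metric `1 - w^t / t_i`.}
#' }
#'
#' @param stream An (untrimmed) `clickstream` satisfying the inclusion rule
#'   for `spec` (`a_i > w^a`, respectively `t_i > w^t`).
#' @param spec A [window_spec()].
#' @return Named numeric vector `c(actions = ..., time = ...)`.
#' @examples
#' s <- clickstream("x", letters[1:4], 1:4, outcome = 0, total_time = 10)
#' earliness(s, window_spec("actions", 3))[["actions"]]  # 0.25
#' @export
earliness <- function(stream, spec) {
  a_i <- cs_length(stream)
  t_i <- stream$total_time
  if (spec$mode == "actions") {
    if (a_i <= spec$w) stop("stream does not satisfy a_i > w^a", call. = FALSE)
    c(actions = 1 - spec$w / a_i,
      time = 1 - stream$events$t[spec$w] / t_i)
  } else {
    if (t_i <= spec$w) stop("stream does not satisfy t_i > w^t", call. = FALSE)
    c(actions = 1 - sum(stream$events$t <= spec$w) / a_i,
      time = 1 - spec$w / t_i)
  }
}

#' Create one early-window data set
#'
#' Applies the inclusion rule (strict: `a_i > w^a` in actions mode, `t_i >
#' w^t` in time mode), trims each included stream to the window (first w^a
#' events, respectively all events with timestamp at most w^t), and computes
#' the monitored descriptives: per-stream Earliness (from the untrimmed
#' sequence), subset Utility, and the base rate. In time mode a trimmed stream
#' may legitimately have zero events (the examinee had not yet acted); such
#' streams are retained and downstream features default or go missing.
#'
#' Utility is the fraction of all failing streams in `streams` that satisfy
#' the inclusion rule, i.e., the proportion of examinees who failed that could
#' still be flagged as at risk inside this window.
#'
#' @param streams A preprocessed [clickstream_set()] with binary outcomes and
#'   at least one failure.
#' @param spec A [window_spec()].
#' @return An object of class `early_window_dataset`: list with fields
#'   `spec`, `streams` (trimmed), `earliness` (data.frame `id`, `actions`,
#'   `time`), `utility`, `base_rate` (proportion correct in the subset), `n`.
#' @export
subset_and_trim <- function(streams, spec) {
  stopifnot(inherits(spec, "window_spec"))
  y <- outcomes(streams)
  if (anyNA(y)) stop("streams must carry binary outcomes", call. = FALSE)
  n_fail_full <- sum(y == 1)
  if (n_fail_full == 0) stop("no failing stream in the full collection",
                             call. = FALSE)
  include <- if (spec$mode == "actions") {
    vapply(streams, cs_length, numeric(1)) > spec$w
  } else {
    vapply(streams, `[[`, numeric(1), "total_time") > spec$w
  }
  if (!any(include)) {
    stop("empty early-window subset for ", format_spec(spec), call. = FALSE)
  }
  kept <- which(include)
  earl <- t(vapply(streams[kept], earliness, numeric(2), spec = spec))
  trimmed <- lapply(streams[kept], function(s) {
    keep <- if (spec$mode == "actions") seq_len(spec$w)
            else which(s$events$t <= spec$w)
    s$events <- s$events[keep, , drop = FALSE]
    rownames(s$events) <- NULL
    s
  })
  y_sub <- y[kept]
  structure(
    list(spec = spec,
         streams = structure(trimmed, class = "clickstream_set"),
         earliness = data.frame(id = stream_ids(streams[kept]),
                                actions = earl[, "actions"],
                                time = earl[, "time"],
                                stringsAsFactors = FALSE, row.names = NULL),
         utility = sum(y_sub == 1) / n_fail_full,
         base_rate = mean(y_sub == 0),
         n = length(kept)),
    class = "early_window_dataset")
}

#' Wrap full, untrimmed sequences as a dataset
#'
#' Convenience for baseline runs on complete clickstreams: the result flows
#' through the same feature/model path as a genuine early window. Utility is
#' 1 by construction and Earliness is undefined (no prediction point precedes
#' the end of the sequence).
#'
#' @param streams A preprocessed [clickstream_set()] with binary outcomes.
#' @return An `early_window_dataset` with `spec$mode = "full"`.
#' @export
full_dataset <- function(streams) {
  y <- outcomes(streams)
  if (anyNA(y)) stop("streams must carry binary outcomes", call. = FALSE)
  structure(
    list(spec = structure(list(mode = "full", w = Inf), class = "window_spec"),
         streams = streams,
         earliness = data.frame(id = stream_ids(streams),
                                actions = NA_real_, time = NA_real_,
                                stringsAsFactors = FALSE),
         utility = 1,
         base_rate = mean(y == 0),
         n = length(streams)),
    class = "early_window_dataset")
}

#' @export
print.early_window_dataset <- function(x, ...) {
  cat(sprintf("<early_window_dataset: %s, n = %d, utility %.3f, base rate %.3f>\n",
              format_spec(x$spec), x$n, x$utility, x$base_rate))
  invisible(x)
}

#' Apply a grid of window specifications
#'
#' One early-window data set per specification, in the given order. The
#' customary design crosses several action-count widths with several
#' elapsed-time widths per task (e.g., grids of 7 + 4 and 9 + 6 windows across
#' two tasks, 26 data sets in total).
#'
#' @param streams A preprocessed [clickstream_set()].
#' @param specs List of [window_spec()] objects (duplicates allowed, with a
#'   warning).
#' @return List of `early_window_dataset` objects.
#' @export
window_grid <- function(streams, specs) {
  if (!length(specs)) stop("`specs` must be non-empty", call. = FALSE)
  keys <- vapply(specs, function(s) paste(s$mode, s$w), character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate window specification(s): ",
            paste(unique(keys[duplicated(keys)]), collapse = "; "),
            call. = FALSE)
  }
  lapply(specs, function(s) subset_and_trim(streams, s))
}

#' Build a window-spec list from per-mode width vectors
#'
#' @param actions Integer vector of action-count widths (w^a), or `NULL`.
#' @param time Numeric vector of elapsed-time widths in seconds (w^t), or
#'   `NULL`.
#' @return List of [window_spec()] objects, actions widths first.
#' @examples
#' length(window_specs(actions = 1:7, time = c(20, 30, 40, 50)))  # 11
#' @export
window_specs <- function(actions = NULL, time = NULL) {
  c(lapply(actions, function(w) window_spec("actions", w)),
    lapply(time, function(w) window_spec("time", w)))
}

#' Monitored descriptives of an early-window data set
#'
#' @param dataset An `early_window_dataset`.
#' @return Named list: `utility`, `base_rate`, `n`, and median plus
#'   middle-50% range of both Earliness metrics (quantile type 7).
#' @export
window_descriptives <- function(dataset) {
  q <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(v, c(.25, .5, .75), names = FALSE)
  }
  ea <- q(dataset$earliness$actions)
  et <- q(dataset$earliness$time)
  list(mode = dataset$spec$mode, w = dataset$spec$w,
       n = dataset$n, utility = dataset$utility,
       base_rate = dataset$base_rate,
       earliness_actions = c(q25 = ea[1], median = ea[2], q75 = ea[3]),
       earliness_time = c(q25 = et[1], median = et[2], q75 = et[3]))
}
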