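#' Construct a single clickstream
#'
#' A clickstream is one examinee's ordered, time-stamped action sequence on an
#' interactive task, together with the binary behavioral outcome. Timestamps
#' are seconds since task onset (task onset is t = 0) and must be
#' non-decreasing; ties keep their input order, since action order matters for
#' n-gram features.
#'
#' @param id Opaque examinee/task identifier (coerced to character).
#' @param actions Character vector of action labels, in execution order.
#' @param t Numeric vector of non-negative timestamps (seconds), same length
#'   as `actions`.
#' @param outcome Binary outcome: 1 = failure, 0 = (at least partial) success.
#'   May be `NA` if a raw `score` is supplied instead and outcomes are to be
#'   binarized later by [preprocess()].
#' @param total_time Total time on task in seconds. If `NULL`, defaults to the
#'   last event's timestamp with a warning (real logs usually carry a final
#'   proceed-to-next event, so the last timestamp is a reasonable floor).
#' @param score Optional raw (possibly polytomous) score label, mapped to a
#'   binary outcome by a [scoring_rule()] during preprocessing.
#'
#' @return An object of class `clickstream`: a list with fields `id`,
#'   `events` (data.frame with columns `action`, `t`), `outcome`,
#'   `total_time`, and optionally `score`.
#' @examples
#' clickstream("p1", c("open", "search", "submit"), c(4.2, 10.0, 31.5),
#'             outcome = 0, total_time = 35)
#' @export
clickstream <- function(id, actions, t, outcome = NA, total_time = NULL,
                        score = NULL) {
  actions <- as.character(actions)
  t <- as.numeric(t)
  if (length(actions) != length(t)) {
    stop("`actions` and `t` must have the same length", call. = FALSE)
  }
  if (length(t) && any(!is.finite(t))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  if (length(t) && any(t < 0)) {
    stop("negative timestamp in stream '", id, "'", call. = FALSE)
  }
  if (is.unsorted(t)) {
    # stable sort: equal timestamps keep file order
    ord <- order(t)
    actions <- actions[ord]
    t <- t[ord]
    warning("events of stream '", id, "' were out of timestamp order; re-sorted",
            call. = FALSE)
  }
  if (!is.na(outcome) && !outcome %in% c(0, 1)) {
    stop("outcome must be 0, 1, or NA (stream '", id, "')", call. = FALSE)
  }
  if (is.null(total_time)) {
    if (length(t)) {
      total_time <- t[length(t)]
      warning("total_time missing for stream '", id,
              "'; defaulting to last event timestamp", call. = FALSE)
    } else {
      total_time <- 0
    }
  }
  if (length(t) && total_time < t[length(t)]) {
    stop("total_time (", total_time, ") earlier than last event (",
         t[length(t)], ") in stream '", id, "'", call. = FALSE)
  }
  structure(
    list(id = as.character(id),
         events = data.frame(action = actions, t = t,
                             stringsAsFactors = FALSE),
         outcome = outcome,
         total_time = as.numeric(total_time),
         score = score),
    class = "clickstream")
}

#' Number of events in a clickstream
#' @param x A `clickstream`.
#' @return Integer event count (the sequence length a_i).
#' @export
cs_length <- function(x) nrow(x$events)

#' @export
print.clickstream <- function(x, ...) {
  cat(sprintf("<clickstream %s: %d events, %.1f s, outcome %s>\n",
              x$id, cs_length(x), x$total_time,
              if (is.na(x$outcome)) paste0("NA (score ", x$score, ")")
              else if (x$outcome == 1) "1 (failure)" else "0 (success)"))
  invisible(x)
}

#' Bundle clickstreams into a collection
#'
#' @param streams A list of `clickstream` objects with unique ids.
#' @return An object of class `clickstream_set` (a list of clickstreams).
#' @export
clickstream_set <- function(streams) {
  if (!length(streams)) stop("empty clickstream collection", call. = FALSE)
  ok <- vapply(streams, inherits, logical(1), what = "clickstream")
  if (!all(ok)) stop("all elements must be clickstream objects", call. = FALSE)
  ids <- vapply(streams, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate stream id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(unname(streams), class = "clickstream_set")
}

#' @export
print.clickstream_set <- function(x, ...) {
  n <- length(x)
  y <- outcomes(x)
  cat(sprintf("<clickstream_set: %d streams, %d failure / %d success%s>\n",
              n, sum(y == 1, na.rm = TRUE), sum(y == 0, na.rm = TRUE),
              if (anyNA(y)) sprintf(" / %d unscored", sum(is.na(y))) else ""))
  invisible(x)
}

#' @export
`[.clickstream_set` <- function(x, i) {
  structure(unclass(x)[i], class = "clickstream_set")
}

#' Outcome vector of a collection
#' @param streams A `clickstream_set`.
#' @return Numeric vector of outcomes (1 = failure), `NA` where unscored.
#' @export
outcomes <- function(streams) {
  vapply(streams, function(s) as.numeric(s$outcome), numeric(1))
}

#' Ids of a collection
#' @param streams A `clickstream_set`.
#' @return Character vector of stream ids.
#' @export
stream_ids <- function(streams) {
  vapply(streams, `[[`, character(1), "id")
}

#' Read clickstream logs
#'
#' Reads a collection of time-stamped action sequences from one of two generic
#' interchange formats:
#' \describe{
#'   \item{`jsonl`}{JSON Lines; one object per stream:
#'     `{"id": str, "outcome": 0|1 or "score": str,
#'       "events": [{"a": str, "t": num}, ...], "total_time": num?}`.}
#'   \item{`long_csv`}{one row per event with columns
#'     `id`, `action`, `t`, `outcome` (or `score`) and optionally
#'     `total_time`; per-stream fields must be constant within an id.}
#' }
#' Events are sorted by timestamp (stable for ties); records with events out
#' of order are re-sorted with a warning.
#'
#' @param path Path to the log file.
#' @param format `"jsonl"` or `"long_csv"`.
#' @return A [clickstream_set()].
#' @seealso [write_log()] for the inverse operation.
#' @export
read_log <- function(path, format = c("jsonl", "long_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") read_log_jsonl(path) else read_log_csv(path)
}

read_log_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  streams <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON record at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$id)) stop("record at line ", i, " has no id", call. = FALSE)
    if (is.null(rec$outcome) && is.null(rec$score)) {
      stop("record '", rec$id, "' (line ", i,
           ") has neither outcome nor score", call. = FALSE)
    }
    ev <- rec$events
    if (is.null(ev) || !length(ev)) {
      a <- character(0); tt <- numeric(0)
    } else if (is.data.frame(ev)) {
      a <- ev$a; tt <- ev$t
    } else {  # list of objects
      a <- vapply(ev, `[[`, character(1), "a")
      tt <- vapply(ev, `[[`, numeric(1), "t")
    }
    streams[[i]] <- clickstream(
      id = rec$id, actions = a, t = tt,
      outcome = if (is.null(rec$outcome)) NA else rec$outcome,
      total_time = rec$total_time,
      score = rec$score)
  }
  clickstream_set(streams)
}

read_log_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "action", "t")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("long CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("outcome" %in% names(df)) && !("score" %in% names(df))) {
    stop("long CSV needs an `outcome` or `score` column", call. = FALSE)
  }
  df$id <- as.character(df$id)
  streams <- lapply(split(df, factor(df$id, levels = unique(df$id))),
                    function(g) {
    one <- function(col) {
      v <- unique(g[[col]])
      if (length(v) > 1) {
        stop("column `", col, "` not constant within stream '", g$id[1], "'",
             call. = FALSE)
      }
      v
    }
    clickstream(
      id = g$id[1], actions = g$action, t = g$t,
      outcome = if ("outcome" %in% names(g)) one("outcome") else NA,
      total_time = if ("total_time" %in% names(g)) one("total_time") else NULL,
      score = if ("score" %in% names(g)) one("score") else NULL)
  })
  clickstream_set(streams)
}

#' Write clickstream logs
#'
#' Serializes a collection to the JSON-Lines or long-CSV dialect understood by
#' [read_log()]. A write/read round trip reproduces ids, action labels,
#' timestamps, and outcomes.
#'
#' @param streams A [clickstream_set()].
#' @param path Output file path.
#' @param format `"jsonl"` or `"long_csv"`.
#' @return Invisibly, `path`.
#' @export
write_log <- function(streams, path, format = c("jsonl", "long_csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(streams, function(s) {
      rec <- list(id = s$id)
      if (!is.na(s$outcome)) rec$outcome <- s$outcome else rec$score <- s$score
      rec$events <- lapply(seq_len(cs_length(s)), function(i) {
        list(a = s$events$action[i], t = s$events$t[i])
      })
      rec$total_time <- s$total_time
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- lapply(streams, function(s) {
      data.frame(id = s$id, action = s$events$action, t = s$events$t,
                 outcome = s$outcome, total_time = s$total_time,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}
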