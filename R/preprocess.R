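#' Action recoding and dropping rules
#'
#' Configuration for the label-level preprocessing of raw logs: recoding raw
#' actions into aggregate categories, removing score-revealing and submission
#' actions, removing the task-onset token, and removing the terminal
#' proceed-to-next bigram.
#'
#' @param recode Named character vector mapping raw action label to aggregate
#'   category, or `NULL` for the identity map. When supplied it must cover
#'   every raw label encountered (after drops); labels that are already recode
#'   targets pass through unchanged, which makes [preprocess()] idempotent.
#' @param drop_actions Character vector of labels removed wherever they occur
#'   (e.g., form-submission actions whose presence reveals the score).
#' @param drop_start Label of the task-onset token to remove (default
#'   `"Start"`), or `NULL` to keep it.
#' @param drop_terminal_bigram Ordered pair of labels removed when — and only
#'   when — they are the final two events (e.g., `c("Next", "NextOK")`:
#'   proceeding to the next task and confirming). Applied exactly once.
#'   `NULL` disables the rule.
#' @return An object of class `action_map`.
#' @export
action_map <- function(recode = NULL, drop_actions = character(),
                       drop_start = "Start",
                       drop_terminal_bigram = NULL) {
  if (!is.null(recode)) {
    if (is.null(names(recode)) || any(!nzchar(names(recode)))) {
      stop("`recode` must be a fully named character vector", call. = FALSE)
    }
    bad <- intersect(unique(unname(recode)),
                     c(drop_actions, drop_start, drop_terminal_bigram))
    if (length(bad)) {
      stop("recode target(s) collide with drop rules: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(drop_terminal_bigram) && length(drop_terminal_bigram) != 2) {
    stop("`drop_terminal_bigram` must be an ordered pair of labels",
         call. = FALSE)
  }
  structure(list(recode = recode,
                 drop_actions = as.character(drop_actions),
                 drop_start = drop_start,
                 drop_terminal_bigram = drop_terminal_bigram),
            class = "action_map")
}

#' Raw-score to binary-outcome rule
#'
#' Maps raw (possibly polytomous) score labels to the binary outcome used
#' throughout the pipeline, with failure coded 1. Partial credit maps to
#' success: the target of prediction is examinees who fulfilled none of the
#' task's requirements.
#'
#' @param map Named vector mapping raw score label to 0 (success) or 1
#'   (failure). Default treats `"0"`/`"incorrect"` as failure and
#'   `"1"`/`"correct"`/`"partial"` as success.
#' @return An object of class `scoring_rule`.
#' @export
scoring_rule <- function(map = c("0" = 1, "incorrect" = 1,
                                 "1" = 0, "correct" = 0, "partial" = 0)) {
  if (is.null(names(map)) || !all(map %in% c(0, 1))) {
    stop("`map` must be a named vector with values 0 or 1", call. = FALSE)
  }
  structure(list(map = map), class = "scoring_rule")
}

#' Load preprocessing rules from a YAML config
#'
#' Reads an `action_map` and `scoring_rule` from a YAML file with top-level
#' sections `action_map:` (keys `recode`, `drop_actions`, `drop_start`,
#' `drop_terminal_bigram`) and `scoring:` (raw score -> 0/1).
#'
#' @param path Path to the YAML file.
#' @return List with elements `map` and `scoring`.
#' @export
read_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  am <- cfg$action_map
  map <- action_map(
    recode = if (!is.null(am$recode)) unlist(am$recode) else NULL,
    drop_actions = if (!is.null(am$drop_actions)) unlist(am$drop_actions)
                   else character(),
    drop_start = if (is.null(am$drop_start)) "Start"
                 else if (identical(am$drop_start, FALSE)) NULL
                 else am$drop_start,
    drop_terminal_bigram = if (!is.null(am$drop_terminal_bigram))
      unlist(am$drop_terminal_bigram) else NULL)
  scoring <- if (!is.null(cfg$scoring)) scoring_rule(unlist(cfg$scoring))
             else scoring_rule()
  list(map = map, scoring = scoring)
}

preprocess_one <- function(s, map, scoring) {
  a <- s$events$action
  t <- s$events$t
  keep <- rep(TRUE, length(a))
  bg <- map$drop_terminal_bigram
  if (!is.null(bg) && length(a) >= 2) {
    n <- length(a)
    if (a[n - 1] == bg[1] && a[n] == bg[2]) keep[c(n - 1, n)] <- FALSE
  }
  if (!is.null(map$drop_start)) keep[a == map$drop_start] <- FALSE
  if (length(map$drop_actions)) keep[a %in% map$drop_actions] <- FALSE
  a <- a[keep]; t <- t[keep]
  if (!is.null(map$recode) && length(a)) {
    targets <- unique(unname(map$recode))
    hit <- a %in% names(map$recode)
    pass <- a %in% targets
    if (any(!hit & !pass)) {
      stop("unmapped raw action label(s): ",
           paste(unique(a[!hit & !pass]), collapse = ", "), call. = FALSE)
    }
    a[hit] <- unname(map$recode[a[hit]])
  }
  if (!length(a)) return(NULL)  # zero-action stream: excluded
  outcome <- s$outcome
  if (is.na(outcome)) {
    sc <- as.character(s$score)
    if (is.null(s$score) || !sc %in% names(scoring$map)) {
      stop("stream '", s$id, "': raw score '", sc,
           "' not covered by the scoring rule", call. = FALSE)
    }
    outcome <- unname(scoring$map[sc])
  }
  cs <- clickstream(s$id, a, t, outcome = outcome, total_time = s$total_time)
  cs$score <- NULL
  cs
}

#' Preprocess a clickstream collection
#'
#' Applies, per stream and in this order: terminal-bigram removal (only when
#' the configured pair forms the final two events, exactly once), removal of
#' the task-onset token and any dropped actions, recoding into aggregate
#' categories, exclusion of streams left with zero events, and binarization of
#' raw scores into outcomes (failure = 1). The operation is idempotent.
#'
#' @param streams A [clickstream_set()].
#' @param map An [action_map()].
#' @param scoring A [scoring_rule()]; used only for streams carrying a raw
#'   score instead of a binary outcome.
#' @return A preprocessed [clickstream_set()]; errors if no stream survives.
#' @export
preprocess <- function(streams, map = action_map(), scoring = scoring_rule()) {
  stopifnot(inherits(map, "action_map"), inherits(scoring, "scoring_rule"))
  out <- lapply(streams, preprocess_one, map = map, scoring = scoring)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no streams left after preprocessing", call. = FALSE)
  clickstream_set(out)
}

#' Summarize a collection by action and outcome group
#'
#' Per action and outcome group, reports the sequence frequency (proportion of
#' the group's streams containing the action at least once), the action
#' frequency (total occurrence count in the group), and the median time to the
#' action's first occurrence; plus, per group, median and middle-50% range of
#' sequence length and of total time on task.
#'
#' @param streams A preprocessed [clickstream_set()] with binary outcomes.
#' @return List with data.frames `actions` (columns `action`, `group`,
#'   `sequence_frequency`, `action_frequency`, `median_first_time`) and
#'   `groups` (per-group length/time median and quartiles). Quartiles use the
#'   default quantile convention of [stats::quantile()] (type 7).
#' @export
describe <- function(streams) {
  y <- outcomes(streams)
  if (anyNA(y)) stop("streams must carry binary outcomes; run preprocess()",
                     call. = FALSE)
  groups <- list(success = which(y == 0), failure = which(y == 1))
  all_actions <- sort(unique(unlist(
    lapply(streams, function(s) unique(s$events$action)))))
  act_rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    n_g <- length(idx)
    for (a in all_actions) {
      contains <- 0L; count <- 0L; first_t <- numeric(0)
      for (i in idx) {
        hits <- streams[[i]]$events$action == a
        if (any(hits)) {
          contains <- contains + 1L
          count <- count + sum(hits)
          first_t <- c(first_t, streams[[i]]$events$t[which(hits)[1]])
        }
      }
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        action = a, group = g,
        sequence_frequency = if (n_g) contains / n_g else NA_real_,
        action_frequency = count,
        median_first_time = if (length(first_t)) stats::median(first_t)
                            else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  grp_rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    len <- vapply(streams[idx], cs_length, numeric(1))
    tt <- vapply(streams[idx], `[[`, numeric(1), "total_time")
    q <- function(v) if (length(v)) stats::quantile(v, c(.25, .5, .75),
                                                    names = FALSE)
         else rep(NA_real_, 3)
    ql <- q(len); qt <- q(tt)
    data.frame(group = g, n = length(idx),
               length_q25 = ql[1], length_median = ql[2], length_q75 = ql[3],
               time_q25 = qt[1], time_median = qt[2], time_q75 = qt[3],
               stringsAsFactors = FALSE)
  })
  list(actions = do.call(rbind, act_rows),
       groups = do.call(rbind, grp_rows))
}
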