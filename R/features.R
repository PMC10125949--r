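#' Feature-extraction configuration
#'
#' Five feature families are available:
#' \describe{
#'   \item{`first_action`}{time to first action (`FirstTime`), an indicator of
#'     planning time; missing for zero-event trimmed streams.}
#'   \item{`tfidf`}{per-action tf-idf weight (`<action>_tfidf`), see
#'     [tfidf_weight()].}
#'   \item{`first_occurrence`}{per-action time to first occurrence
#'     (`<action>_T`); missing when the action is absent — the missingness
#'     itself is informative and is consumed natively by the tree learner.}
#'   \item{`ngrams`}{one-hot indicators for contiguous bi-/trigrams
#'     (`ngram:<a|b>`); presence only, no counts. Unigram indicators are
#'     deliberately excluded: their information is already carried by the
#'     tf-idf and first-occurrence families.}
#'   \item{`activity`}{interaction intensity within the window: time elapsed
#'     over the retained actions in actions mode, number of retained actions
#'     in time mode.}
#' }
#'
#' @param families Character vector naming the enabled families (at least
#'   one).
#' @param ngram_orders Subset of `c(2, 3)`.
#' @param idf_scope `"subset"` (document frequencies, sequence counts, and the
#'   n-gram vocabulary are computed over the whole early-window data set) or
#'   `"train"` (computed from training rows only and applied to held-out rows,
#'   avoiding leakage of validation information into the features).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(families = c("first_action", "tfidf",
                                        "first_occurrence", "ngrams",
                                        "activity"),
                           ngram_orders = c(2, 3),
                           idf_scope = c("subset", "train")) {
  all_fams <- c("first_action", "tfidf", "first_occurrence", "ngrams",
                "activity")
  if (!length(families)) stop("at least one feature family must be enabled",
                              call. = FALSE)
  families <- match.arg(families, all_fams, several.ok = TRUE)
  if (!all(ngram_orders %in% c(2, 3))) {
    stop("`ngram_orders` must be a subset of {2, 3}", call. = FALSE)
  }
  structure(list(families = families,
                 ngram_orders = sort(unique(as.integer(ngram_orders))),
                 idf_scope = match.arg(idf_scope)),
            class = "feature_config")
}

#' Term-frequency–inverse-document-frequency weight for an action
#'
#' The weight for action g in sequence i is `(1 + ln(tf)) * ln(N / df)` when
#' the action occurs (`tf >= 1`) and 0 otherwise, with natural logarithms.
#' `df` is the number of sequences in the data set containing the action at
#' least once and `N` the number of sequences in the data set. The weight
#' upweighs actions occurring in few sequences while dampening repeated
#' occurrence within one sequence; it is 0 exactly when the action is absent
#' from the sequence or present in every sequence.
#'
#' @param tf Non-negative integer: occurrences of the action in the sequence.
#' @param df Positive integer: number of sequences containing the action.
#' @param N Positive integer: number of sequences in the data set.
#' @return Non-negative real weight.
#' @examples
#' round(tfidf_weight(3, 300, 500), 2)  # 1.07
#' round(tfidf_weight(3, 100, 500), 2)  # 3.38
#' @export
tfidf_weight <- function(tf, df, N) {
  if (any(df <= 0) || any(N <= 0) || any(df > N)) {
    stop("require 0 < df <= N", call. = FALSE)
  }
  if (any(tf < 0)) stop("`tf` must be non-negative", call. = FALSE)
  ifelse(tf >= 1, (1 + log(tf)) * log(N / df), 0)
}

#' Time to first action
#' @param stream A (trimmed) `clickstream`.
#' @return Timestamp of the first event in seconds; `NA` for a zero-event
#'   trimmed stream.
#' @export
time_to_first_action <- function(stream) {
  if (!cs_length(stream)) NA_real_ else stream$events$t[1]
}

#' Time to an action's first occurrence
#' @param stream A (trimmed) `clickstream`.
#' @param action Action label.
#' @return Timestamp of the earliest event with that label; `NA` when the
#'   action does not occur in the stream.
#' @export
time_to_first_occurrence <- function(stream, action) {
  hit <- which(stream$events$action == action)
  if (!length(hit)) NA_real_ else stream$events$t[hit[1]]
}

#' Contiguous n-grams of a stream
#'
#' @param stream A `clickstream`.
#' @param n N-gram order, 2 or 3.
#' @return Character vector of the distinct contiguous n-grams, encoded as
#'   labels joined by `"|"` (presence only; empty for streams shorter than
#'   `n`).
#' @examples
#' s <- clickstream("x", c("A", "B", "A", "B"), 1:4, 0, 5)
#' extract_ngrams(s, 2)  # "A|B" "B|A"
#' @export
extract_ngrams <- function(stream, n) {
  if (!n %in% c(2, 3)) stop("`n` must be 2 or 3", call. = FALSE)
  a <- stream$events$action
  if (length(a) < n) return(character(0))
  k <- length(a) - n + 1L
  grams <- vapply(seq_len(k), function(i) paste(a[i:(i + n - 1L)],
                                                collapse = "|"),
                  character(1))
  unique(grams)
}

#' Activity within an early window
#'
#' Intensity of interaction inside the window: in actions mode the time
#' elapsed while performing the retained actions (timestamp of the last
#' retained event, i.e., t_i^{w^a}); in time mode the number of retained
#' actions. For full sequences the elapsed time over the whole stream is
#' used. Zero-event streams have activity 0.
#'
#' @param stream A trimmed `clickstream`.
#' @param spec The [window_spec()] the stream was trimmed under.
#' @return A real number.
#' @export
activity <- function(stream, spec) {
  n <- cs_length(stream)
  if (spec$mode == "time") return(as.numeric(n))
  if (!n) return(0)
  stream$events$t[n]
}

#' Feature statistics of a scope set
#'
#' Computes the statistics that parameterize feature construction — the
#' action vocabulary with document frequencies, the sequence count N, and the
#' observed n-gram vocabularies — from a scope collection (the whole
#' early-window data set, or the training rows only; see `idf_scope` in
#' [feature_config()]).
#'
#' @param streams A [clickstream_set()] (trimmed streams of the scope).
#' @param config A [feature_config()].
#' @return An object of class `feature_stats` with fields `vocabulary`, `df`
#'   (named integer), `N`, `ngrams` (named list by order).
#' @export
feature_stats <- function(streams, config = feature_config()) {
  per_stream_actions <- lapply(streams, function(s) unique(s$events$action))
  df_tab <- table(unlist(per_stream_actions))
  vocab <- sort(names(df_tab))
  ngrams <- list()
  if ("ngrams" %in% config$families) {
    for (n in config$ngram_orders) {
      obs <- unique(unlist(lapply(streams, extract_ngrams, n = n)))
      ngrams[[as.character(n)]] <- sort(obs)
    }
  }
  structure(list(vocabulary = vocab,
                 df = as.integer(df_tab[vocab]),
                 N = length(streams),
                 ngrams = ngrams),
            class = "feature_stats")
}

# Assemble rows for arbitrary streams under fixed scope statistics.
feature_rows <- function(streams, spec, config, stats) {
  vocab <- stats$vocabulary
  df <- stats$df
  N <- stats$N
  cols <- list()
  fam <- character(0)
  add <- function(name, values, family) {
    cols[[name]] <<- values
    fam[name] <<- family
  }
  if ("first_action" %in% config$families) {
    add("FirstTime", vapply(streams, time_to_first_action, numeric(1)),
        "first_action")
  }
  if ("activity" %in% config$families) {
    add("Activity", vapply(streams, activity, numeric(1), spec = spec),
        "activity")
  }
  if ("tfidf" %in% config$families) {
    for (j in seq_along(vocab)) {
      a <- vocab[j]
      tf <- vapply(streams, function(s) sum(s$events$action == a), numeric(1))
      add(paste0(a, "_tfidf"), tfidf_weight(tf, df[j], N), "tfidf")
    }
  }
  if ("first_occurrence" %in% config$families) {
    for (a in vocab) {
      add(paste0(a, "_T"),
          vapply(streams, time_to_first_occurrence, numeric(1), action = a),
          "first_occurrence")
    }
  }
  if ("ngrams" %in% config$families) {
    for (n in names(stats$ngrams)) {
      grams_per_stream <- lapply(streams, extract_ngrams,
                                 n = as.integer(n))
      for (g in stats$ngrams[[n]]) {
        add(paste0("ngram:", g),
            vapply(grams_per_stream, function(gs) as.numeric(g %in% gs),
                   numeric(1)),
            "ngram")
      }
    }
  }
  x <- do.call(cbind, cols)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(streams), ncol = 0)
  rownames(x) <- NULL
  list(x = x, families = fam)
}

#' Build the feature matrix for an early-window data set
#'
#' Assembles the enabled feature families into a numeric matrix with one row
#' per stream. Missing values occur only in the time-to-first-occurrence
#' columns and in `FirstTime`, and encode informative absence. The action and
#' n-gram vocabularies and the tf-idf document statistics come from `stats`
#' (by default computed over the data set itself; pass statistics from
#' training rows to transform held-out rows without leakage). N-grams and
#' actions unseen in the scope yield no columns.
#'
#' @param dataset An `early_window_dataset` (see [subset_and_trim()]).
#' @param config A [feature_config()].
#' @param stats A [feature_stats()] object, or `NULL` to compute from
#'   `dataset$streams`.
#' @return An object of class `feature_matrix`: list with fields `x` (numeric
#'   matrix, `NA` allowed), `ids`, `labels` (binary outcomes, failure = 1),
#'   `families` (named character vector, one entry per column), `stats`,
#'   `spec`.
#' @export
build_features <- function(dataset, config = feature_config(), stats = NULL) {
  stopifnot(inherits(dataset, "early_window_dataset"),
            inherits(config, "feature_config"))
  if (!dataset$n) stop("empty dataset", call. = FALSE)
  if (is.null(stats)) stats <- feature_stats(dataset$streams, config)
  rows <- feature_rows(dataset$streams, dataset$spec, config, stats)
  structure(list(x = rows$x,
                 ids = stream_ids(dataset$streams),
                 labels = outcomes(dataset$streams),
                 families = rows$families,
                 stats = stats,
                 spec = dataset$spec),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d rows x %d columns (%s)>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%d %s", table(x$families)[unique(x$families)],
                            unique(x$families)), collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' Missing values are written as empty cells; labels go to a dedicated
#' `outcome` column. The sidecar lists the column families so the matrix can
#' be interpreted without the originating configuration.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(id = fm$ids, fm$x, outcome = fm$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(columns = names(fm$families), families = unname(fm$families)),
    paste0(path, ".json"))
  invisible(path)
}
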