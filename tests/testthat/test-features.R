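test_that("tf-idf weight follows the case-split formula with natural logs", {
  expect_equal(round(tfidf_weight(3, 300, 500), 2), 1.07)
  expect_equal(round(tfidf_weight(3, 100, 500), 2), 3.38)
  expect_equal(tfidf_weight(0, 10, 50), 0)
  expect_equal(tfidf_weight(1, 50, 50), 0)   # ln(1) twice
  expect_equal(tfidf_weight(5, 2, 10), (1 + log(5)) * log(5))
  expect_error(tfidf_weight(3, 0, 10), "df")
  expect_error(tfidf_weight(3, 11, 10), "df")
})

test_that("per-stream timing features handle presence, absence, and zero", {
  s <- clickstream("f", c("B", "A", "B"), c(12.5, 20, 55), 0, 60)
  expect_equal(time_to_first_action(s), 12.5)
  expect_equal(time_to_first_occurrence(s, "B"), 12.5)
  expect_equal(time_to_first_occurrence(s, "A"), 20)
  expect_true(is.na(time_to_first_occurrence(s, "Z")))
  z <- clickstream("z", "A", 0, 0, 1)
  expect_equal(time_to_first_action(z), 0)
  empty <- subset_and_trim(clickstream_set(list(
    clickstream("e", "A", 40, 1, 50),
    clickstream("g", "A", 1, 0, 50))), window_spec("time", 10))
  e <- empty$streams[[which(stream_ids(empty$streams) == "e")]]
  expect_true(is.na(time_to_first_action(e)))
})

test_that("ngram extraction is contiguous, deduplicated, presence-only", {
  s <- clickstream("n", c("A", "B", "C"), 1:3, 0, 4)
  expect_setequal(extract_ngrams(s, 2), c("A|B", "B|C"))
  expect_setequal(extract_ngrams(s, 3), "A|B|C")
  rep2 <- clickstream("r", c("A", "B", "A", "B"), 1:4, 0, 5)
  expect_setequal(extract_ngrams(rep2, 2), c("A|B", "B|A"))
  short <- clickstream("s", "A", 1, 0, 2)
  expect_length(extract_ngrams(short, 3), 0)
  expect_error(extract_ngrams(s, 4), "2 or 3")
})

test_that("activity is elapsed time in actions mode, a count in time mode", {
  s <- clickstream("a", c("x", "y", "z"), c(5, 9, 14), 0, 20)
  expect_equal(activity(s, window_spec("actions", 3)), 14)
  expect_equal(activity(s, window_spec("time", 30)), 3)
})

test_that("build_features assembles exactly the enabled families", {
  st <- clickstream_set(list(
    clickstream("p", c("A", "B"), c(1, 2), 1, 6),
    clickstream("q", c("A", "A"), c(2, 3), 0, 6)))
  ds <- full_dataset(st)
  fm <- build_features(ds, feature_config(ngram_orders = 2))
  cols <- colnames(fm$x)
  expect_setequal(cols, c("FirstTime", "Activity", "A_tfidf", "B_tfidf",
                          "A_T", "B_T", "ngram:A|B", "ngram:A|A"))
  # action absent from a stream: tfidf 0 AND its time column missing
  q <- which(fm$ids == "q")
  expect_equal(unname(fm$x[q, "B_tfidf"]), 0)
  expect_true(is.na(fm$x[q, "B_T"]))
  # A occurs in both streams: df = N so its tfidf is 0 everywhere
  expect_true(all(fm$x[, "A_tfidf"] == 0))
  expect_true(all(fm$x[, c("ngram:A|B", "ngram:A|A")] %in% 0:1))
  only_tf <- build_features(ds, feature_config(families = "tfidf"))
  expect_setequal(colnames(only_tf$x), c("A_tfidf", "B_tfidf"))
  expect_error(feature_config(families = character()), "one feature family")
})

test_that("tf-idf columns match brute-force counting over the subset", {
  st <- synthetic_collection(n = 50, seed = 21, max_len = 10)
  ds <- subset_and_trim(st, window_spec("actions", 2))
  fm <- build_features(ds)
  N <- ds$n
  for (a in fm$stats$vocabulary) {
    tf <- vapply(ds$streams, function(s) sum(s$events$action == a),
                 numeric(1))
    df <- sum(tf >= 1)
    manual <- ifelse(tf >= 1, (1 + log(tf)) * log(N / df), 0)
    expect_equal(unname(fm$x[, paste0(a, "_tfidf")]), manual)
  }
})

test_that("tfidf positivity coincides with non-missing first-occurrence time", {
  st <- synthetic_collection(n = 60, seed = 8, max_len = 9)
  ds <- subset_and_trim(st, window_spec("actions", 3))
  fm <- build_features(ds)
  N <- fm$stats$N
  for (j in seq_along(fm$stats$vocabulary)) {
    a <- fm$stats$vocabulary[j]
    if (fm$stats$df[j] == N) next  # tfidf identically 0 regardless
    expect_equal(fm$x[, paste0(a, "_tfidf")] > 0,
                 !is.na(fm$x[, paste0(a, "_T")]))
  }
})

test_that("feature matrix is invariant to stream input order", {
  st <- synthetic_collection(n = 40, seed = 30)
  ds <- full_dataset(st)
  perm <- withr::with_seed(2, sample(length(st)))
  ds_perm <- full_dataset(clickstream_set(unclass(st)[perm]))
  fm <- build_features(ds)
  fm_perm <- build_features(ds_perm)
  expect_setequal(colnames(fm$x), colnames(fm_perm$x))
  reorder <- match(fm$ids, fm_perm$ids)
  expect_equal(fm_perm$x[reorder, colnames(fm$x)], fm$x)
})

test_that("train-scope statistics transform unseen streams without leakage", {
  st <- synthetic_collection(n = 80, seed = 17, max_len = 10)
  ds <- full_dataset(st)
  cfg <- feature_config(idf_scope = "train")
  train_idx <- 1:60
  stats_train <- feature_stats(ds$streams[train_idx], cfg)
  fm_train <- build_features(full_dataset(ds$streams[train_idx]), cfg,
                             stats = stats_train)
  # brute-force recomputation with held-out rows removed gives identical
  # training-row features
  fm_again <- build_features(full_dataset(ds$streams[train_idx]), cfg)
  expect_equal(fm_train$x, fm_again$x)
  # held-out rows use only training vocabulary / df / N
  held <- build_features(full_dataset(ds$streams[61:80]), cfg,
                         stats = stats_train)
  expect_equal(colnames(held$x), colnames(fm_train$x))
  a <- stats_train$vocabulary[1]
  tf_held <- vapply(ds$streams[61:80],
                    function(s) sum(s$events$action == a), numeric(1))
  expect_equal(unname(held$x[, paste0(a, "_tfidf")]),
               unname(tfidf_weight(tf_held,
                                   stats_train$df[1], stats_train$N)))
})

test_that("zero-event trimmed streams get default/missing features", {
  st <- clickstream_set(list(
    clickstream("none", c("A", "B"), c(50, 60), 1, 80),
    clickstream("some", c("A", "B", "A"), c(2, 8, 25), 0, 80)))
  ds <- subset_and_trim(st, window_spec("time", 30))
  fm <- build_features(ds)
  i <- which(fm$ids == "none")
  expect_true(all(fm$x[i, grep("_tfidf$", colnames(fm$x))] == 0))
  expect_true(all(is.na(fm$x[i, grep("_T$", colnames(fm$x))])))
  expect_true(is.na(fm$x[i, "FirstTime"]))
  expect_equal(unname(fm$x[i, "Activity"]), 0)
})

test_that("feature CSV serialization preserves missing cells", {
  st <- synthetic_collection(n = 20, seed = 4)
  fm <- build_features(full_dataset(st))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$outcome, unname(fm$labels))
  mat <- as.matrix(back[, colnames(fm$x)])
  dimnames(mat) <- dimnames(fm$x)
  expect_equal(mat, fm$x)
  expect_true(file.exists(paste0(path, ".json")))
})
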