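make_xy <- function(n = 60, p = 4, seed = 1, signal = 0) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    x[, 1] <- x[, 1] + signal * y
    list(x = x, y = y)
  })
}

test_that("upsample equalizes counts with exact minority replicas", {
  d <- make_xy(40)
  y <- c(rep(1, 10), rep(0, 30))
  up <- upsample(d$x, y, seed = 3)
  expect_equal(as.vector(table(up$y)), c(30, 30))
  # majority rows untouched, in place
  expect_equal(up$x[which(y == 0), ], d$x[which(y == 0), ])
  # every added row is an exact replica of an existing minority row
  added <- up$x[-seq_len(40), , drop = FALSE]
  minority <- d$x[y == 1, , drop = FALSE]
  for (i in seq_len(nrow(added))) {
    expect_true(any(apply(minority, 1, identical, y = added[i, ])))
  }
  # multiset of distinct minority rows unchanged
  expect_setequal(apply(up$x[up$y == 1, ], 1, paste, collapse = ","),
                  apply(minority, 1, paste, collapse = ","))
  # balanced input is returned unchanged
  bal <- upsample(d$x, d$y, seed = 3)
  expect_identical(bal$x, d$x)
  expect_error(upsample(d$x, rep(1, 40)), "both classes")
  # reproducible given seed
  expect_identical(upsample(d$x, y, 7), upsample(d$x, y, 7))
})

test_that("gbt fit separates a perfectly informative binary feature", {
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(flag = y, noise = withr::with_seed(1, rnorm(n)))
  fit <- fit_gbt(x, y, list(n_trees = 50, max_depth = 3,
                            learning_rate = 0.3), seed = 1)
  p <- predict(fit, x)
  cm <- confusion(y, p)
  expect_equal(metrics(cm)[["phi"]], 1)
})

test_that("constant features predict roughly the class prior", {
  n <- 300
  y <- withr::with_seed(5, rbinom(n, 1, 0.3))
  x <- matrix(1, n, 2, dimnames = list(NULL, c("c1", "c2")))
  fit <- fit_gbt(x, y, list(n_trees = 200, max_depth = 3,
                            learning_rate = 0.3), seed = 2)
  p <- predict(fit, x)
  expect_lt(max(abs(p - mean(y))), 0.02)
})

test_that("fitting is deterministic given data, seed, and hyperparameters", {
  d <- make_xy(80, signal = 1)
  hp <- list(n_trees = 60, max_depth = 4, learning_rate = 0.1)
  p1 <- predict(fit_gbt(d$x, d$y, hp, seed = 9), d$x)
  p2 <- predict(fit_gbt(d$x, d$y, hp, seed = 9), d$x)
  expect_identical(p1, p2)
  expect_error(fit_gbt(cbind(d$x, bad = Inf), d$y, hp), "non-finite")
})

test_that("missing values are routed by learned default directions", {
  withr::with_seed(11, {
    n <- 200
    y <- rbinom(n, 1, 0.5)
    # informative missingness: feature observed mostly when y = 1
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "m"))
    x[runif(n) > ifelse(y == 1, 0.9, 0.1), 1] <- NA
  })
  fit <- fit_gbt(x, y, list(n_trees = 50, max_depth = 3,
                            learning_rate = 0.3), seed = 4)
  expect_gt(auc(y, predict(fit, x)), 0.8)
})

test_that("nested_cv predicts every row exactly once out-of-fold", {
  st <- generate_clickstreams(presets(200, seed = 31)[["paper-like"]])
  ds <- subset_and_trim(st, window_spec("actions", 3))
  fit <- nested_cv(ds, grid = hyper_grid(50, 3, 0.1),
                   cv = cv_config(seed = 2))
  expect_false(anyNA(fit$oof))
  expect_true(all(fit$oof >= 0 & fit$oof <= 1))
  covered <- sort(unlist(lapply(fit$folds, `[[`, "test_idx")))
  expect_equal(covered, seq_along(fit$labels))
  # no validation index ever sits in its own training partition
  for (f in fit$folds) {
    expect_length(intersect(f$test_idx, setdiff(covered, f$test_idx)), 0)
  }
})

test_that("inner grid search selects and ties break toward simpler models", {
  d <- make_xy(90, signal = 2, seed = 3)
  fm <- structure(list(x = d$x, ids = as.character(seq_len(90)),
                       labels = d$y,
                       families = setNames(rep("f", 4), colnames(d$x)),
                       stats = NULL, spec = NULL),
                  class = "feature_matrix")
  grid <- hyper_grid(n_trees = c(50, 100), max_depth = 3,
                     learning_rate = 0.1)
  fit <- nested_cv(fm, grid, cv = cv_config(outer_folds = 3, seed = 4))
  for (f in fit$folds) {
    expect_length(f$inner_auc, 2)
    if (f$inner_auc[1] >= f$inner_auc[2]) {
      expect_equal(f$hp$n_trees, 50)  # first (simplest) row wins ties
    }
  }
  # single-row grid skips the inner loop
  fit1 <- nested_cv(fm, hyper_grid(50, 3, 0.1),
                    cv = cv_config(outer_folds = 3, seed = 4))
  expect_null(fit1$folds[[1]]$inner_auc)
})

test_that("train-scope features in nested_cv depend only on training rows", {
  st <- generate_clickstreams(presets(120, seed = 77)[["paper-like"]])
  ds <- subset_and_trim(st, window_spec("actions", 3))
  cfg <- feature_config(idf_scope = "train", ngram_orders = 2)
  fit <- nested_cv(ds, grid = hyper_grid(50, 3, 0.1),
                   cv = cv_config(seed = 6), config = cfg)
  # audit one fold: recompute held-out features from training statistics only
  f <- fit$folds[[1]]
  train_idx <- setdiff(seq_len(ds$n), f$test_idx)
  stats <- feature_stats(ds$streams[train_idx], cfg)
  expect_equal(stats$N, length(train_idx))
  held <- build_features(
    structure(list(spec = ds$spec, streams = ds$streams[f$test_idx],
                   n = length(f$test_idx)),
              class = "early_window_dataset"),
    cfg, stats = stats)
  expect_equal(unname(predict(f$model, held$x)),
               unname(fit$oof[f$test_idx]))
  expect_error(
    nested_cv(build_features(ds), config = cfg),
    "stream-level")
})
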