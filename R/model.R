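#' Hyperparameter grid for the boosted-tree classifier
#'
#' Default grid: number of trees in {50, 100, 150}, maximum tree depth in
#' {3, 6, 9}, learning rate in {0.01, 0.10} (18 combinations). Rows are
#' ordered by number of trees, then depth, then learning rate; ties in
#' inner-loop selection are broken in favor of the earlier (simpler) row.
#'
#' @param n_trees Integer vector of ensemble sizes.
#' @param max_depth Integer vector of maximum tree depths.
#' @param learning_rate Numeric vector of shrinkage rates.
#' @return data.frame with columns `n_trees`, `max_depth`, `learning_rate`.
#' @export
hyper_grid <- function(n_trees = c(50, 100, 150),
                       max_depth = c(3, 6, 9),
                       learning_rate = c(0.01, 0.10)) {
  g <- expand.grid(learning_rate = sort(learning_rate),
                   max_depth = sort(max_depth),
                   n_trees = sort(n_trees))
  g <- g[order(g$n_trees, g$max_depth, g$learning_rate), ]
  rownames(g) <- NULL
  g[, c("n_trees", "max_depth", "learning_rate")]
}

#' Nested cross-validation configuration
#'
#' @param outer_folds Number of outer folds k (model evaluation; default 5).
#' @param inner_folds Number of inner folds l (hyperparameter tuning within
#'   each outer training set; default 3).
#' @param seed Master seed; every stochastic step (fold assignment, upsample
#'   draws, tree training) consumes a sub-seed derived from it.
#' @param upsample Replicate minority-class rows in each training partition
#'   until class counts match (default `TRUE`). Applied after splitting, so
#'   replicas never leak across partitions.
#' @param stratified Stratify fold assignment by outcome (default `TRUE`;
#'   prevents single-class folds in imbalanced windows).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 3, seed = 1,
                      upsample = TRUE, stratified = TRUE) {
  if (outer_folds < 2 || inner_folds < 2) {
    stop("need at least 2 outer and 2 inner folds", call. = FALSE)
  }
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed),
                 upsample = isTRUE(upsample),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Fold assignment; stratified round-robin within class after a shuffle.
make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' Upsample the minority class
#'
#' Equalizes class counts by replicating randomly drawn minority rows; every
#' added row is an exact replica of an existing minority row and majority
#' rows are untouched. Balanced input is returned unchanged.
#'
#' @param x Numeric feature matrix (missing values allowed).
#' @param y Binary label vector aligned with the rows of `x`.
#' @param seed Integer seed for the replication draw.
#' @return List with fields `x` and `y` (equal class counts).
#' @export
upsample <- function(x, y, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present to upsample",
                          call. = FALSE)
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- if (tab["1"] < tab["0"]) 1 else 0
  min_idx <- which(y == minority)
  need <- abs(tab[1] - tab[2])
  extra <- withr::with_seed(seed,
                            sample(min_idx, need, replace = TRUE))
  list(x = rbind(x, x[extra, , drop = FALSE]),
       y = c(y, y[extra]))
}

#' Fit a gradient-boosted classification-tree ensemble
#'
#' Trains an additive ensemble of M binary classification trees with logistic
#' loss: each tree is fit to correct the residual errors of its predecessors,
#' and the prediction is the sum of the trees' leaf scores mapped to a failure
#' probability. Missing feature values are handled natively via sparsity-aware
#' split finding: each split learns a default direction for rows lacking the
#' split feature, so informative missingness (an action never performed) is
#' exploited rather than imputed. The `xgboost` library provides the tree
#' learner.
#'
#' @param x Numeric feature matrix; `NA` encodes missing, other non-finite
#'   values are an error.
#' @param y Binary labels (failure = 1), both classes present.
#' @param hp One-row data.frame (or list) with `n_trees`, `max_depth`,
#'   `learning_rate`.
#' @param seed Integer seed; with the same data, seed, and hyperparameters
#'   the fitted model and its predictions are identical.
#' @return An object of class `gbt_model`.
#' @export
fit_gbt <- function(x, y, hp, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (any(!is.finite(x) & !is.na(x))) {
    stop("non-finite feature values (other than missing) are not allowed",
         call. = FALSE)
  }
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = hp$max_depth,
                  eta = hp$learning_rate,
                  nthread = 1,
                  seed = seed),
    data = dtrain,
    nrounds = hp$n_trees,
    verbose = 0))
  structure(list(booster = booster,
                 hp = as.list(hp)[c("n_trees", "max_depth", "learning_rate")],
                 feature_names = colnames(x),
                 seed = seed),
            class = "gbt_model")
}

#' Predict failure probabilities from a fitted ensemble
#'
#' @param object A `gbt_model`.
#' @param newdata Numeric matrix with the model's feature columns (matched by
#'   name when column names are present; missing allowed).
#' @param ... Unused.
#' @return Numeric vector of failure probabilities in [0, 1].
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss)) {
      stop("newdata lacks feature column(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(newdata, missing = NA))
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model: %d trees, depth %d, learning rate %g, %d features>\n",
              x$hp$n_trees, x$hp$max_depth, x$hp$learning_rate,
              length(x$feature_names)))
  invisible(x)
}

# Build train/test matrices for one outer fold honoring the idf scope.
fold_matrices <- function(data, config, train_idx, test_idx, fm_all) {
  if (config$idf_scope == "train") {
    tr_streams <- data$streams[train_idx]
    stats <- feature_stats(tr_streams, config)
    tr <- feature_rows(tr_streams, data$spec, config, stats)
    te <- feature_rows(data$streams[test_idx], data$spec, config, stats)
    list(x_train = tr$x, x_test = te$x)
  } else {
    list(x_train = fm_all$x[train_idx, , drop = FALSE],
         x_test = fm_all$x[test_idx, , drop = FALSE])
  }
}

#' Nested cross-validation of the boosted-tree classifier
#'
#' Outer k-fold loop for performance estimation; within each outer training
#' set, an inner l-fold grid search selects the hyperparameters (selection
#' criterion: mean inner-validation AUC, ties broken toward the simpler
#' model). Minority upsampling is applied inside each training partition only,
#' after splitting — validation rows are never upsampled and replicas never
#' cross partitions. The selected configuration is refit on the full
#' (upsampled) outer training set and produces out-of-fold failure
#' probabilities for the held-out rows; every row is predicted exactly once.
#'
#' With `idf_scope = "train"` in `config`, feature statistics (document
#' frequencies, N, n-gram vocabulary) are recomputed from the training rows of
#' every split — outer and inner — and applied to the corresponding held-out
#' rows, so no validation information enters the features. With the default
#' `"subset"` scope the feature matrix is built once over the whole data set.
#'
#' @param data An `early_window_dataset`, or a prebuilt [build_features()]
#'   `feature_matrix` (subset scope only).
#' @param grid Hyperparameter grid (see [hyper_grid()]); a single-row grid
#'   skips the inner loop.
#' @param cv A [cv_config()].
#' @param config A [feature_config()].
#' @return An object of class `nested_cv`: list with `folds` (per outer fold:
#'   `test_idx`, `hp`, `model`, `inner_auc`), `oof` (out-of-fold failure
#'   probabilities aligned with the data rows), `labels`, `ids`, `cv`,
#'   `config`.
#' @export
nested_cv <- function(data, grid = hyper_grid(), cv = cv_config(),
                      config = feature_config()) {
  stopifnot(inherits(cv, "cv_config"), inherits(config, "feature_config"))
  if (!nrow(grid)) stop("hyperparameter grid is empty", call. = FALSE)
  is_dataset <- inherits(data, "early_window_dataset")
  if (!is_dataset && !inherits(data, "feature_matrix")) {
    stop("`data` must be an early_window_dataset or feature_matrix",
         call. = FALSE)
  }
  if (config$idf_scope == "train" && !is_dataset) {
    stop("idf_scope = 'train' needs stream-level data; pass the ",
         "early_window_dataset rather than a prebuilt feature matrix",
         call. = FALSE)
  }
  y <- if (is_dataset) outcomes(data$streams) else data$labels
  ids <- if (is_dataset) stream_ids(data$streams) else data$ids
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  fm_all <- NULL
  if (config$idf_scope == "subset") {
    fm_all <- if (is_dataset) build_features(data, config) else data
  }
  n <- length(y)
  outer_fold <- make_folds(y, cv$outer_folds, cv$seed, cv$stratified)
  oof <- rep(NA_real_, n)
  folds <- vector("list", cv$outer_folds)
  for (ko in seq_len(cv$outer_folds)) {
    test_idx <- which(outer_fold == ko)
    train_idx <- which(outer_fold != ko)
    if (length(unique(y[test_idx])) < 2 || length(unique(y[train_idx])) < 2) {
      stop("outer fold ", ko, " is missing a class; use stratified folds ",
           "or fewer folds", call. = FALSE)
    }
    mats <- fold_matrices(data, config, train_idx, test_idx, fm_all)
    inner_auc <- NULL
    if (nrow(grid) > 1) {
      inner_fold <- make_folds(y[train_idx], cv$inner_folds,
                               cv$seed + 100L + ko, cv$stratified)
      inner_auc <- numeric(nrow(grid))
      for (h in seq_len(nrow(grid))) {
        aucs <- numeric(cv$inner_folds)
        for (ki in seq_len(cv$inner_folds)) {
          iv <- train_idx[inner_fold == ki]
          it <- train_idx[inner_fold != ki]
          if (length(unique(y[iv])) < 2) {
            stop("inner fold ", ki, " of outer fold ", ko,
                 " is missing a class; use stratified folds", call. = FALSE)
          }
          im <- fold_matrices(data, config, it, iv, fm_all)
          xtr <- im$x_train; ytr <- y[it]
          sub_seed <- cv$seed + 7919L * ko + 101L * ki + h
          if (cv$upsample) {
            up <- upsample(xtr, ytr, seed = sub_seed)
            xtr <- up$x; ytr <- up$y
          }
          fit <- fit_gbt(xtr, ytr, grid[h, ], seed = sub_seed)
          aucs[ki] <- auc(y[iv], predict(fit, im$x_test))
        }
        inner_auc[h] <- mean(aucs)
      }
      best <- which.max(inner_auc)  # first max: grid rows are simplest-first
    } else {
      best <- 1L
    }
    hp <- grid[best, ]
    xtr <- mats$x_train; ytr <- y[train_idx]
    fit_seed <- cv$seed + 524287L + ko
    if (cv$upsample) {
      up <- upsample(xtr, ytr, seed = fit_seed)
      xtr <- up$x; ytr <- up$y
    }
    model <- fit_gbt(xtr, ytr, hp, seed = fit_seed)
    oof[test_idx] <- predict(model, mats$x_test)
    folds[[ko]] <- list(test_idx = test_idx, hp = hp, model = model,
                        inner_auc = inner_auc)
  }
  structure(list(folds = folds, oof = oof, labels = y, ids = ids,
                 cv = cv, config = config, grid = grid),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv: %d outer folds, %d rows, mean fold AUC %.3f>\n",
              length(x$folds), length(x$labels),
              mean(vapply(x$folds, function(f)
                auc(x$labels[f$test_idx], x$oof[f$test_idx]), numeric(1)))))
  invisible(x)
}
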