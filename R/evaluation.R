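#' Confusion counts at a discrimination threshold
#'
#' Failure is the positive class. An observation is classified as failure
#' when its predicted failure probability strictly exceeds the threshold
#' (a probability exactly at the threshold is classified as success).
#'
#' @param labels Binary observed outcomes (failure = 1).
#' @param probabilities Predicted failure probabilities in [0, 1].
#' @param threshold Discrimination threshold (default 0.50).
#' @return An object of class `confusion_counts`: named integer vector
#'   `TP`, `FP`, `TN`, `FN` summing to `length(labels)`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.50) {
  if (length(labels) != length(probabilities)) {
    stop("`labels` and `probabilities` differ in length", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(probabilities > threshold)
  structure(c(TP = sum(pred == 1 & labels == 1),
              FP = sum(pred == 1 & labels == 0),
              TN = sum(pred == 0 & labels == 0),
              FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values `TP/(TP+FP)` and `TN/(TN+FN)`, and the phi
#' coefficient — the Pearson correlation between observed and predicted
#' failure indicators,
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A rate with zero denominator is reported as `NA` with a warning; phi with
#' any zero marginal is 0 (the conventional completion, keeping reports
#' total).
#'
#' @param counts A [confusion()] result.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `phi`.
#' @export
metrics <- function(counts) {
  cc <- as.numeric(counts)
  names(cc) <- names(unclass(counts))
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- rate(cc["TP"], cc["TP"] + cc["FN"], "sensitivity")
  spec <- rate(cc["TN"], cc["TN"] + cc["FP"], "specificity")
  ppv <- rate(cc["TP"], cc["TP"] + cc["FP"], "PPV")
  npv <- rate(cc["TN"], cc["TN"] + cc["FN"], "NPV")
  marg <- c(cc["TP"] + cc["FP"], cc["TP"] + cc["FN"],
            cc["TN"] + cc["FP"], cc["TN"] + cc["FN"])
  phi <- if (any(marg == 0)) 0
         else (cc["TP"] * cc["TN"] - cc["FP"] * cc["FN"]) / sqrt(prod(marg))
  c(sensitivity = unname(sens), specificity = unname(spec),
    ppv = unname(ppv), npv = unname(npv), phi = unname(phi))
}

#' Area under the ROC curve
#'
#' Rank (Mann–Whitney) formulation: the probability that a randomly drawn
#' positive (failure) outranks a randomly drawn negative, with tied
#' probabilities counted half (midranks). Invariant under strictly monotone
#' transforms of the probabilities.
#'
#' @param labels Binary observed outcomes (failure = 1), both classes
#'   present.
#' @param probabilities Predicted failure scores.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) {
    stop("`labels` and `probabilities` differ in length", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(probabilities)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gain-based feature importance across folds
#'
#' For each fold model, per-feature importance is the total loss-reduction
#' (gain) of the splits using the feature, normalized so the fold's
#' importances sum to 1; features never split on have gain 0. Mean, standard
#' deviation, and maximum across folds are reported, together with a
#' reporting flag for features whose gain exceeded `gain_filter` in at least
#' one fold.
#'
#' @param fold_models List of `gbt_model` objects (e.g.,
#'   `lapply(fit$folds, \(f) f$model)` from [nested_cv()]).
#' @param gain_filter Reporting cutoff on the per-fold normalized gain
#'   (default 0.05).
#' @return data.frame `feature`, `mean_gain`, `sd_gain`, `max_gain`,
#'   `reported`, sorted by decreasing mean gain.
#' @export
feature_importance <- function(fold_models, gain_filter = 0.05) {
  if (!length(fold_models)) stop("need at least one trained model",
                                 call. = FALSE)
  all_feats <- unique(unlist(lapply(fold_models, `[[`, "feature_names")))
  gains <- matrix(0, nrow = length(all_feats), ncol = length(fold_models),
                  dimnames = list(all_feats, NULL))
  for (j in seq_along(fold_models)) {
    imp <- xgboost::xgb.importance(model = fold_models[[j]]$booster)
    if (nrow(imp)) gains[imp$Feature, j] <- imp$Gain  # Gain sums to 1
  }
  out <- data.frame(
    feature = all_feats,
    mean_gain = rowMeans(gains),
    sd_gain = apply(gains, 1, stats::sd),
    max_gain = apply(gains, 1, max),
    stringsAsFactors = FALSE)
  out$reported <- out$max_gain > gain_filter
  out <- out[order(-out$mean_gain), ]
  rownames(out) <- NULL
  out
}

fold_metric_row <- function(labels, probabilities, threshold = 0.50) {
  cc <- confusion(labels, probabilities, threshold)
  c(auc = auc(labels, probabilities),
    phi = metrics(cc)[["phi"]],
    metrics(cc)[c("sensitivity", "specificity", "ppv", "npv")])
}

#' Aggregate per-fold performance into an evaluation report
#'
#' Computes AUC, phi, sensitivity, specificity, PPV, and NPV on each outer
#' fold's held-out predictions (failure as positive class, threshold applied
#' strictly) and their means and standard deviations across folds, passes
#' through the window descriptives, and attaches the gain-importance table.
#'
#' @param fit A [nested_cv()] result.
#' @param dataset The `early_window_dataset` the fit was run on (supplies
#'   Utility, base rate, and Earliness descriptives); optional.
#' @param threshold Discrimination threshold (default 0.50).
#' @param gain_filter Importance reporting cutoff (default 0.05).
#' @return An object of class `evaluation_report`: list with `per_fold`
#'   (data.frame, one row per fold), `mean`, `sd` (named metric vectors),
#'   `descriptives`, `importance`.
#' @export
aggregate_report <- function(fit, dataset = NULL, threshold = 0.50,
                             gain_filter = 0.05) {
  stopifnot(inherits(fit, "nested_cv"))
  per_fold <- t(vapply(fit$folds, function(f) {
    suppressWarnings(
      fold_metric_row(fit$labels[f$test_idx], fit$oof[f$test_idx], threshold))
  }, numeric(6)))
  per_fold <- as.data.frame(per_fold)
  per_fold$fold <- seq_len(nrow(per_fold))
  per_fold <- per_fold[, c("fold", "auc", "phi", "sensitivity",
                           "specificity", "ppv", "npv")]
  m <- colMeans(per_fold[, -1], na.rm = TRUE)
  s <- apply(per_fold[, -1], 2, stats::sd, na.rm = TRUE)
  descriptives <- if (!is.null(dataset)) window_descriptives(dataset) else NULL
  imp <- feature_importance(lapply(fit$folds, `[[`, "model"), gain_filter)
  structure(list(per_fold = per_fold, mean = m, sd = s,
                 descriptives = descriptives, importance = imp,
                 threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Evaluation across", nrow(x$per_fold), "outer folds",
      "(failure = positive class, threshold", x$threshold, "strict)\n")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  if (!is.null(x$descriptives)) {
    d <- x$descriptives
    cat(sprintf("Window: %s w = %s | n = %d, utility = %.3f, base rate = %.3f\n",
                d$mode, format(d$w), d$n, d$utility, d$base_rate))
    if (!is.na(d$earliness_actions[["median"]])) {
      cat(sprintf("Earliness (actions) median %.2f [%.2f; %.2f]; (time) median %.2f [%.2f; %.2f]\n",
                  d$earliness_actions[["median"]], d$earliness_actions[["q25"]],
                  d$earliness_actions[["q75"]], d$earliness_time[["median"]],
                  d$earliness_time[["q25"]], d$earliness_time[["q75"]]))
    }
  }
  top <- x$importance[x$importance$reported, , drop = FALSE]
  if (nrow(top)) {
    cat("Features with fold gain >", format(0.05), "\n")
    print(utils::head(top, 10), digits = digits)
  }
  invisible(x)
}

#' Evaluate one early-window data set end to end
#'
#' Convenience wrapper: nested cross-validation followed by report
#' aggregation.
#'
#' @inheritParams nested_cv
#' @inheritParams aggregate_report
#' @return An `evaluation_report` with the `nested_cv` fit attached as
#'   attribute `"fit"`.
#' @export
evaluate_window <- function(data, grid = hyper_grid(), cv = cv_config(),
                            config = feature_config(), threshold = 0.50,
                            gain_filter = 0.05) {
  fit <- nested_cv(data, grid, cv, config)
  rep <- aggregate_report(
    fit,
    dataset = if (inherits(data, "early_window_dataset")) data else NULL,
    threshold = threshold, gain_filter = gain_filter)
  attr(rep, "fit") <- fit
  rep
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON (`<path>.json`: per-fold metrics, mean/sd,
#' descriptives) and two flat CSVs: `<path>_metrics.csv` (one row per metric
#' and fold plus aggregate rows) and `<path>_importance.csv`.
#'
#' @param report An `evaluation_report`.
#' @param path Output path stem.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(per_fold = report$per_fold,
         mean = as.list(report$mean),
         sd = as.list(report$sd),
         descriptives = report$descriptives,
         threshold = report$threshold),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  long <- stats::reshape(report$per_fold, direction = "long",
                         varying = setdiff(names(report$per_fold), "fold"),
                         v.names = "value", timevar = "metric",
                         times = setdiff(names(report$per_fold), "fold"))
  long <- long[order(long$metric, long$fold), c("metric", "fold", "value")]
  agg <- data.frame(metric = names(report$mean),
                    fold = NA_integer_, value = unname(report$mean))
  utils::write.csv(rbind(long, agg), paste0(path, "_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$importance, paste0(path, "_importance.csv"),
                   row.names = FALSE)
  invisible(path)
}
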