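# O(n^2) pair-counting oracle for the probability that a random positive
# outranks a random negative, ties counted half.
auc_pairwise <- function(labels, probabilities) {
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("confusion applies a strict threshold with failure positive", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(unclass(cc), c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # probability exactly at the threshold counts as predicted success
  at <- confusion(c(1, 0), c(0.5, 0.5))
  expect_equal(unclass(at), c(TP = 0L, FP = 0L, TN = 1L, FN = 1L))
  all_fail <- confusion(c(1, 1, 0, 0, 0), rep(1, 5))
  expect_equal(all_fail[["FP"]], 3L)
  expect_error(confusion(c(1, 0), 0.5), "length")
  expect_equal(sum(confusion(rep(c(0, 1), 10), runif(20))), 20)
})

test_that("metrics recover the standard rates and phi", {
  m <- metrics(confusion(c(1, 0), c(0.9, 0.1)))
  expect_equal(unname(m), c(1, 1, 1, 1, 1))
  sym <- structure(c(TP = 25L, FP = 25L, TN = 25L, FN = 25L),
                   class = "confusion_counts")
  ms <- metrics(sym)
  expect_equal(ms[["sensitivity"]], 0.5)
  expect_equal(ms[["specificity"]], 0.5)
  expect_equal(ms[["phi"]], 0)
  # zero denominator: NA with warning; zero marginal: phi = 0
  degenerate <- confusion(c(0, 0), c(0.2, 0.3))
  warns <- capture_warnings(md <- metrics(degenerate))
  expect_match(warns, "sensitivity", all = FALSE)
  expect_true(is.na(md[["sensitivity"]]))
  expect_equal(md[["phi"]], 0)
})

test_that("phi equals the Pearson correlation of the binary vectors", {
  for (seed in 1:100) {
    cc <- withr::with_seed(seed, {
      c(TP = sample(0:20, 1), FP = sample(0:20, 1),
        TN = sample(0:20, 1), FN = sample(0:20, 1))
    })
    obs <- rep(c(1, 1, 0, 0), cc[c("TP", "FN", "TN", "FP")])
    pred <- rep(c(1, 0, 0, 1), cc[c("TP", "FN", "TN", "FP")])
    phi <- metrics(structure(cc, class = "confusion_counts"))[["phi"]]
    r <- suppressWarnings(stats::cor(obs, pred))
    if (is.na(r)) {
      expect_equal(phi, 0)  # zero-marginal convention
    } else {
      expect_equal(phi, r, tolerance = 1e-12)
    }
  }
})

test_that("auc matches exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  for (seed in 1:100) {
    d <- withr::with_seed(seed, {
      list(y = c(rep(1, 8), rep(0, 12)),
           p = round(runif(20), 1))  # rounding forces ties
    })
    expect_equal(auc(d$y, d$p), auc_pairwise(d$y, d$p))
  }
  expect_error(auc(rep(1, 5), runif(5)), "both classes")
})

test_that("auc is invariant under strictly monotone transforms", {
  d <- withr::with_seed(3, list(y = rbinom(50, 1, 0.4), p = runif(50)))
  base <- auc(d$y, d$p)
  expect_equal(auc(d$y, qlogis(d$p)), base)
  expect_equal(auc(d$y, d$p^3), base)
})

test_that("rate metrics conserve counts", {
  for (seed in 1:20) {
    d <- withr::with_seed(seed,
      list(y = rbinom(40, 1, 0.5), p = runif(40)))
    if (length(unique(d$y)) < 2) next
    cc <- confusion(d$y, d$p)
    m <- suppressWarnings(metrics(cc))
    if (!is.na(m[["sensitivity"]])) {
      expect_equal(m[["sensitivity"]] * (cc[["TP"]] + cc[["FN"]]),
                   cc[["TP"]])
    }
    if (!is.na(m[["specificity"]])) {
      expect_equal(m[["specificity"]] * (cc[["TN"]] + cc[["FP"]]),
                   cc[["TN"]])
    }
  }
})

test_that("feature importance normalizes per fold and filters at 0.05", {
  withr::with_seed(2, {
    n <- 120
    y <- rep(c(0, 1), n / 2)
    x <- cbind(info = y + rnorm(n, sd = 0.1), junk = rnorm(n),
               dead = rep(1, n))
  })
  hp <- list(n_trees = 30, max_depth = 3, learning_rate = 0.3)
  models <- lapply(1:3, function(s) fit_gbt(x, y, hp, seed = s))
  imp <- feature_importance(models)
  expect_equal(sum(imp$mean_gain), 1, tolerance = 1e-6)
  expect_gt(imp$mean_gain[imp$feature == "info"], 0.9)
  dead <- imp[imp$feature == "dead", ]
  expect_equal(dead$mean_gain, 0)
  expect_false(dead$reported)
})

test_that("aggregate_report averages fold metrics and round-trips", {
  st <- generate_clickstreams(presets(150, seed = 19)[["separable"]])
  ds <- full_dataset(st)
  rep <- evaluate_window(ds, grid = hyper_grid(50, 3, 0.1),
                         cv = cv_config(seed = 8))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$per_fold), 5)
  expect_equal(unname(rep$mean["auc"]), mean(rep$per_fold$auc))
  expect_equal(unname(rep$sd["phi"]), sd(rep$per_fold$phi))
  expect_true(all(rep$per_fold$auc >= 0 & rep$per_fold$auc <= 1))
  expect_equal(rep$descriptives$utility, 1)
  path <- withr::local_tempfile()
  write_report(rep, path)
  back <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(back$per_fold$auc, rep$per_fold$auc)
  expect_equal(unname(unlist(back$mean)), unname(rep$mean))
  imp_csv <- utils::read.csv(paste0(path, "_importance.csv"))
  expect_equal(imp_csv$feature, rep$importance$feature)
})
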