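---
title: "Early-window prediction of failure from clickstream data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-window prediction of failure from clickstream data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyclick)
```

## The problem

Computer-administered interactive tasks log a *clickstream* per examinee: an
ordered sequence of action labels with timestamps, from task onset until the
examinee proceeds to the next task, together with a binary outcome (failure
versus at-least-partial success). The question this package addresses is how
*early* in such a session the outcome becomes predictable: can an examinee at
risk of failing be flagged while most of their solution process is still
ahead of them, when an intervention (a hint, a reformulation) could still
help?

The pipeline answers this by a systematic sweep over *early windows*: for a
window of $w^a$ actions, only examinees with sequence length $a_i > w^a$ are
retained and their streams are cut to the first $w^a$ events; for a window of
$w^t$ seconds, only examinees with time on task $t_i > w^t$ are retained and
events after $w^t$ are dropped. Each windowed data set is then featurized,
classified, and evaluated on its own, and the trajectory of performance
across windows shows when prediction becomes possible.

## Preprocessing assumptions

Raw logs are expected to arrive as JSON-Lines or long CSV (`read_log()`).
`preprocess()` applies rules that mirror standard practice for assessment
logs: actions are recoded into aggregate categories; the task-onset token and
the terminal proceed-to-next bigram are removed (the latter only when it is
literally the final pair of events, exactly once — it encodes leaving the
task, not solving it); actions that reveal the score (form contents,
submission events) are dropped; streams left with zero events are excluded;
and polytomous raw scores are binarized with partial credit counting as
success, because the target construct is *complete* failure. Timestamps are
seconds from task onset with task onset at $t = 0$; when a log lacks an
explicit time on task, the last event's timestamp is used as a floor and a
warning is raised. Ties in timestamps keep file order, since n-gram features
depend on action order.

## Monitored descriptives

Besides subset size and base rate (proportion correct — its complement is
the failure rate, so the two always sum to one), each window carries:

* **Earliness** per stream — the relative distance from the prediction point
  to the end of the sequence, in both currencies. Trimming by actions:
  $1 - w^a/a_i$ (actions) and $1 - t_i^{w^a}/t_i$ (time), where $t_i^{w^a}$
  is the timestamp of the $w^a$-th event. Trimming by time: $1 -
  a_i^{w^t}/a_i$ and $1 - w^t/t_i$, where $a_i^{w^t}$ counts events up to
  $w^t$. Both $a_i$ and $t_i$ are taken from the *untrimmed* stream. Medians
  and middle-50% ranges are reported; quantiles use R's default convention
  (`stats::quantile` type 7), which the descriptives document — any standard
  convention would serve, but one had to be fixed.
* **Utility** — the fraction of *all* failing examinees that survive the
  window's inclusion rule, i.e., that could still be flagged before
  finishing. Utility is non-increasing in window width and drops early when
  many examinees abandon the task after a handful of quick actions.

The inclusion rule is strict (`>`), and time-mode event retention uses the
closed boundary `t <= w^t`, mirroring the strict actions-mode rule by
symmetry. A time-mode stream whose first event falls after $w^t$ is retained
with zero events: the absence of any action within the window is itself
informative and such streams are classified from the defaults below.

## Features

Five families (`feature_config()`), all computed per windowed stream:

* `FirstTime` — time to the first action, a classical indicator of planning
  time; missing for zero-event streams.
* `<action>_tfidf` — $(1 + \ln \mathrm{tf}_{gi}) \ln(N_w/\mathrm{df}_g)$ for
  $\mathrm{tf}_{gi} \ge 1$, else 0. Logarithms are natural — the convention
  is pinned by the package's reference examples
  (`tfidf_weight(3, 300, 500)` $= 1.07$, `tfidf_weight(3, 100, 500)` $=
  3.38$). The weight is zero exactly when the action is absent or occurs in
  every sequence of the scope.
* `<action>_T` — time to the action's first occurrence, *missing* when the
  action was never performed. Missingness is deliberately preserved (no
  sentinel values): the tree learner's sparsity-aware splits learn a default
  direction per node, so non-occurrence is exploited as information.
* `ngram:<a|b>` / `ngram:<a|b|c>` — one-hot indicators of contiguous bi- and
  trigrams, presence only. Counts add nothing in short windows, and one-hot
  unigrams are excluded since tf-idf and `<action>_T` already carry
  occurrence information.
* `Activity` — the intensity of interaction: elapsed time over the retained
  actions (actions mode) or the number of retained actions (time mode).

**Scope of the statistics.** Document frequencies, $N_w$, and the n-gram
vocabulary can be computed over the whole windowed data set
(`idf_scope = "subset"`, the default and the convention the descriptive
literature uses) or over training rows only (`"train"`). The subset scope
lets a little information about validation rows into the features; the train
scope recomputes the statistics inside every cross-validation split — outer
and inner — and applies them to the held-out rows, which is the leakage-free
choice. Both are first-class because the difference is itself of
methodological interest; the package's hygiene tests audit the train scope by
recomputing held-out features from scratch. N-grams and actions unseen in
the scope yield no columns (rather than all-zero columns) to bound
dimensionality.

## Classifier and cross-validation

The classifier is an additive ensemble of $M$ binary classification trees
with logistic loss, $\hat y = \sum_{m=1}^{M} f_m(x)$, trained stagewise with
shrinkage and complexity regularization; the `xgboost` library supplies the
learner, including its native handling of missing values. The package fixes
the contract (`fit_gbt()`): deterministic predictions given data, seed, and
hyperparameters; single-threaded training for reproducibility; `NA` as the
only admissible non-finite value.

Model selection and evaluation use nested cross-validation
(`nested_cv()`): $k = 5$ outer folds for evaluation, $l = 3$ inner folds for
a grid search over $M \in \{50, 100, 150\}$, depth $\in \{3, 6, 9\}$, and
learning rate $\in \{0.01, 0.10\}$. Class imbalance is handled by
upsampling — replicating randomly drawn minority rows until counts match —
applied *after* splitting and only inside training partitions, so replicas
can never straddle a fold boundary. Several choices here were genuinely
open and are resolved as defaults, all configurable:

* inner-loop selection criterion: mean inner-validation AUC (it matches the
  headline evaluation metric);
* folds stratified by outcome (prevents single-class folds in imbalanced
  windows; unstratified assignment is available);
* ties in the grid search break toward the simpler model (fewer trees, then
  shallower, then slower learning);
* a single master seed drives fold assignment, upsampling draws, and tree
  training through documented sub-seeds, so a run is reproducible from one
  integer.

## Evaluation

Failure is the positive class. The confusion matrix uses a strict threshold:
a stream is classified as failure when its predicted failure probability
*exceeds* 0.50; a probability of exactly 0.50 counts as success. From it:
sensitivity, specificity, PPV, NPV, and $\phi$ (the Pearson correlation of
the observed and predicted indicators). A rate with a zero denominator is
reported missing with a warning; $\phi$ with a zero marginal is set to 0 so
reports stay total. AUC uses the rank (Mann–Whitney) formulation with
midranks for ties, making it invariant under monotone transforms of the
scores. Per-fold metrics are aggregated as mean and standard deviation
across the outer folds (`aggregate_report()`).

Feature importance is the gain — total loss reduction across all splits a
feature is used in — normalized per fold so each fold's importances sum to
one, then averaged. The per-fold normalization makes the conventional
reporting filter (a gain above 0.05 in at least one fold) scale-free across
folds; it is exposed as `gain_filter` since the convention is an inference,
not a law.

## The synthetic generator

Access-restricted assessment logs cannot ship with a package, so
`generate_clickstreams()` provides a structural emulation against which
every stage is testable. Per stream: a Bernoulli outcome at the failure base
rate; actions from a class-conditional first-order Markov chain over a
27-label vocabulary (the simplest process under which bi-/trigram features
are meaningful; the transition matrices are built deterministically, with a
mild sequential preference so bigrams carry structure, and class-specific
propensities for "exploration" versus "solution" actions); sequence length
$1 + \mathrm{NegBin}(\mu, \text{size})$ per class; log-normal latencies
(right-skewed positive times — reported timing descriptives are skewed but
no distributional form is established, so log-normal is a choice of
convenience) accumulated into timestamps, with a log-normal initial latency
standing in for instruction reading and a terminal latency separating the
last action from time on task.

The `"paper-like"` preset targets published class-conditional descriptives
of a medium-difficulty interactive task: failure rate 0.46; failure-class
lengths with median/quartiles near 11 [7; 19] versus success near 30
(achieved by $\mu = 13$, size 1.7 and $\mu = 31$, size 5, chosen from the
negative-binomial quantile function at design time); per-action latencies
slightly slower for the failure class; and 10% of failure streams generated
as 1–3 quick actions, reproducing the early drop in Utility caused by
examinees abandoning the task. The `"null"` preset makes the two class
generators *identical* — the end-to-end pipeline must then sit at AUC 0.5 —
and `"separable"` makes them strongly divergent, so full-sequence
classification should be near-perfect.

What the generator does **not** emulate: task structure (no notion of a
correct solution path, no action grammar constraints), higher-order
sequential dependence, population heterogeneity in speed or ability, or any
parameter fitted to real logs. Passing tests on synthetic data therefore
demonstrate that the machinery recovers signal of the kinds injected —
repertoire, timing, length — not that any particular real task is
predictable.

## Numerical and scale choices

Degenerate inputs are handled explicitly: zero-event trimmed streams get all
tf-idf weights 0, all time features missing, activity 0; empty windows raise
an error naming the spec; duplicate window specs are kept with a warning.
Timestamps are doubles (millisecond precision or better survives
serialization).

The shipped test-suite and verification runs are sized to desk scale and the
vignette records those sizes as the package's own choices: signal-recovery
checks run the null and separable presets at $n = 2000$ full sequences with
bigram features and a single hyperparameter point (100 trees, depth 3, rate
0.1) — the preset, not the grid, is what those checks constrain — the
trimming audit uses 1000 streams, and the fold-hygiene audit about 200 rows
with the train scope. A real analysis would use the full grid and both
n-gram orders, as the defaults do.

## A minimal run

```{r example, eval = FALSE}
streams <- generate_clickstreams(presets(n_streams = 500, seed = 1)[["paper-like"]])
ds <- subset_and_trim(streams, window_spec("actions", 4))
report <- evaluate_window(ds,
                          grid = hyper_grid(100, 3, 0.1),
                          cv = cv_config(seed = 1))
report
```

## Limitations

Only fixed window grids are supported (no per-examinee stopping rules); the
classifier family is fixed to gradient-boosted trees (no cost-sensitive
learning, no recurrent or kernel alternatives); features are generic
(no task-specific expert features, no frequency-weighted n-grams, no learned
sequence embeddings). These boundaries are deliberate: the package's scope is
the early-window evaluation protocol itself.
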