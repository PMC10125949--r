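#' Class-signal specification for the synthetic generator
#'
#' Controls how strongly the two outcome classes differ:
#' \describe{
#'   \item{`repertoire`}{log-odds divergence of action propensities. Actions
#'     are split into an "exploration" third (favored by the failure class),
#'     a neutral third, and a "solution" third (favored by the success
#'     class); a value of `r` multiplies a favored action's weight by
#'     `exp(r/2)` and a disfavored one's by `exp(-r/2)`.}
#'   \item{`timing`}{additive shift of the failure class's latency
#'     log-scale (positive = failing examinees act more slowly per action).}
#'   \item{`length_ratio`}{ratio of success to failure mean sequence
#'     length.}
#' }
#' With all three at their neutral values (0, 0, 1) the class-conditional
#' generators are identical.
#'
#' @param repertoire Non-negative real (default 0).
#' @param timing Real log-scale shift (default 0).
#' @param length_ratio Positive real (default 1).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(repertoire = 0, timing = 0, length_ratio = 1) {
  if (repertoire < 0 || length_ratio <= 0) {
    stop("`repertoire` must be >= 0 and `length_ratio` > 0", call. = FALSE)
  }
  structure(list(repertoire = repertoire, timing = timing,
                 length_ratio = length_ratio),
            class = "signal_spec")
}

# Deterministic class-conditional Markov components. Action k gets signature
# s_k in {-1, 0, +1} (exploration / neutral / solution); transition rows have
# a mild sequential preference for the next actions in vocabulary order so
# that bigrams carry structure.
markov_components <- function(vocabulary, repertoire, class_sign) {
  V <- length(vocabulary)
  thirds <- rep(c(-1, 0, 1), times = c(ceiling(V / 3), ceiling(V / 3), 0))
  sig <- c(thirds, rep(1, V - length(thirds)))[seq_len(V)]
  w <- exp(repertoire / 2 * sig * class_sign)
  trans <- matrix(0, V, V, dimnames = list(vocabulary, vocabulary))
  for (j in seq_len(V)) {
    base <- rep(1, V)
    base[(j %% V) + 1L] <- base[(j %% V) + 1L] + 3
    base[(j + 1L) %% V + 1L] <- base[(j + 1L) %% V + 1L] + 1.5
    base[j] <- 0.25  # immediate repeats are rare but possible
    row <- base * w
    trans[j, ] <- row / sum(row)
  }
  start <- w * c(3, 2, rep(1, V - 2))  # sessions mostly open the same way
  list(trans = trans, start = start / sum(start), signature = sig)
}

#' Synthetic clickstream generator configuration
#'
#' Fully parameterizes the class-conditional generative process: labels are
#' Bernoulli draws with the failure base rate; action labels follow a
#' class-conditional first-order Markov chain over the vocabulary; sequence
#' lengths are `1 + NegBin(mu, size)` per class; timestamps are cumulative
#' sums of right-skewed log-normal latencies starting from a log-normal
#' initial latency (time to first action, emulating instruction reading);
#' total time on task adds a terminal latency after the last action. A
#' configurable fraction of failure streams are "dropout" streams of 1–3
#' quick actions, emulating examinees abandoning the task almost
#' immediately.
#'
#' @param n_streams Number of streams to generate.
#' @param failure_rate Failure base rate in (0, 1).
#' @param vocabulary Action labels (default 27 generic categories, a typical
#'   size for aggregate-level action codings of interactive tasks).
#' @param signal A [signal_spec()].
#' @param length_success List `mu`, `size` of the success-class negative
#'   binomial for (length - 1); the failure class uses `mu / length_ratio`
#'   and the same `size` unless `length_failure` is supplied.
#' @param length_failure Optional explicit failure-class `mu`, `size`.
#' @param latency Success-class latency log-parameters
#'   `c(meanlog, sdlog)`; failure adds the `timing` shift to `meanlog`.
#' @param initial_latency Log-parameters of the time to first action.
#' @param terminal_latency Log-parameters of the time between last action and
#'   proceeding to the next task.
#' @param action_latency_offset Optional named per-action additive offsets on
#'   the latency `meanlog` (default: a fixed mild spread, some actions
#'   take longer than others).
#' @param dropout_rate Fraction of failure streams generated as near-empty
#'   dropouts (default 0).
#' @param seed Integer master seed; generation is fully reproducible.
#' @return An object of class `generator_config` with explicit per-class
#'   components (`trans`, `start`, `length`, `latency`).
#' @export
generator_config <- function(n_streams,
                             failure_rate = 0.46,
                             vocabulary = sprintf("act%02d", 1:27),
                             signal = signal_spec(),
                             length_success = list(mu = 31, size = 5),
                             length_failure = NULL,
                             latency = c(meanlog = log(3.5), sdlog = 0.8),
                             initial_latency = c(meanlog = log(20),
                                                 sdlog = 0.6),
                             terminal_latency = c(meanlog = log(5),
                                                  sdlog = 0.5),
                             action_latency_offset = NULL,
                             dropout_rate = 0,
                             seed = 1) {
  stopifnot(inherits(signal, "signal_spec"))
  if (failure_rate <= 0 || failure_rate >= 1) {
    stop("`failure_rate` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("`dropout_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (latency[["sdlog"]] <= 0 || initial_latency[["sdlog"]] <= 0 ||
      terminal_latency[["sdlog"]] <= 0) {
    stop("latency sdlog parameters must be positive", call. = FALSE)
  }
  V <- length(vocabulary)
  if (V < 2 || anyDuplicated(vocabulary)) {
    stop("`vocabulary` must hold at least two distinct labels", call. = FALSE)
  }
  if (is.null(length_failure)) {
    length_failure <- list(mu = length_success$mu / signal$length_ratio,
                           size = length_success$size)
  }
  if (length_success$mu <= 0 || length_success$size <= 0 ||
      length_failure$mu <= 0 || length_failure$size <= 0) {
    stop("length distribution parameters must be positive", call. = FALSE)
  }
  if (is.null(action_latency_offset)) {
    action_latency_offset <- stats::setNames(
      log(seq(0.7, 1.4, length.out = V)), vocabulary)
  }
  success <- markov_components(vocabulary, signal$repertoire, +1)
  failure <- markov_components(vocabulary, signal$repertoire, -1)
  structure(
    list(n_streams = as.integer(n_streams),
         failure_rate = failure_rate,
         vocabulary = vocabulary,
         signal = signal,
         trans = list(success = success$trans, failure = failure$trans),
         start = list(success = success$start, failure = failure$start),
         length = list(success = length_success, failure = length_failure),
         latency = list(
           success = latency,
           failure = c(meanlog = latency[["meanlog"]] + signal$timing,
                       sdlog = latency[["sdlog"]])),
         initial_latency = initial_latency,
         terminal_latency = terminal_latency,
         action_latency_offset = action_latency_offset,
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "generator_config")
}

sample_chain <- function(len, start, trans, vocabulary) {
  a <- integer(len)
  a[1] <- sample.int(length(vocabulary), 1, prob = start)
  if (len > 1) {
    for (k in 2:len) {
      a[k] <- sample.int(length(vocabulary), 1, prob = trans[a[k - 1], ])
    }
  }
  vocabulary[a]
}

#' Generate a labeled synthetic clickstream collection
#'
#' Draws `n_streams` streams from the class-conditional process described in
#' [generator_config()]. Latencies are strictly positive, so timestamps
#' strictly increase within a stream. Given the same configuration (including
#' its seed), output is identical across calls.
#'
#' @param config A [generator_config()].
#' @return A [clickstream_set()] with binary outcomes (failure = 1).
#' @export
generate_clickstreams <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    streams <- vector("list", config$n_streams)
    for (i in seq_len(config$n_streams)) {
      y <- stats::rbinom(1, 1, config$failure_rate)
      cls <- if (y == 1) "failure" else "success"
      dropout <- y == 1 && config$dropout_rate > 0 &&
        stats::runif(1) < config$dropout_rate
      if (dropout) {
        len <- sample(1:3, 1)
        init <- stats::rlnorm(1, log(8), 0.5)
        lat_ml <- log(2); lat_sd <- 0.5
      } else {
        lp <- config$length[[cls]]
        len <- 1L + stats::rnbinom(1, mu = lp$mu, size = lp$size)
        init <- stats::rlnorm(1, config$initial_latency[["meanlog"]],
                              config$initial_latency[["sdlog"]])
        lat_ml <- config$latency[[cls]][["meanlog"]]
        lat_sd <- config$latency[[cls]][["sdlog"]]
      }
      a <- sample_chain(len, config$start[[cls]], config$trans[[cls]],
                        config$vocabulary)
      gaps <- if (len > 1) {
        stats::rlnorm(len - 1,
                      lat_ml + config$action_latency_offset[a[-1]],
                      lat_sd)
      } else numeric(0)
      t <- cumsum(c(init, gaps))
      total <- t[len] + stats::rlnorm(1,
                                      config$terminal_latency[["meanlog"]],
                                      config$terminal_latency[["sdlog"]])
      streams[[i]] <- clickstream(sprintf("s%05d", i), a, t,
                                  outcome = y, total_time = total)
    }
    clickstream_set(streams)
  })
}

#' Named generator presets
#'
#' Three structural emulations of clickstream data from interactive tasks:
#' \describe{
#'   \item{`"null"`}{no class signal: both class generators are identical
#'     (balanced classes, no dropout). Downstream classification should sit
#'     at chance.}
#'   \item{`"paper-like"`}{class differences shaped like published
#'     descriptives of a medium-difficulty interactive assessment task:
#'     failure base rate 0.46; failing examinees produce markedly shorter
#'     sequences (median around 11 versus 30 events), act slightly more
#'     slowly per action, favor exploration over solution actions, and a
#'     fraction of 0.10 abandon the task after 1–3 quick actions.}
#'   \item{`"separable"`}{strong repertoire, timing, and length divergence;
#'     full-sequence classification should be near-perfect.}
#' }
#' These presets are structural emulations only; they are not fit to any real
#' assessment log data.
#'
#' @param n_streams Number of streams per configuration.
#' @param seed Master seed stored in each configuration.
#' @return Named list of [generator_config()] objects.
#' @export
presets <- function(n_streams = 2000, seed = 20220601) {
  list(
    "null" = generator_config(
      n_streams, failure_rate = 0.5,
      signal = signal_spec(0, 0, 1),
      dropout_rate = 0, seed = seed),
    "paper-like" = generator_config(
      n_streams, failure_rate = 0.46,
      signal = signal_spec(repertoire = 1.5, timing = 0.25,
                           length_ratio = 31 / 13),
      length_failure = list(mu = 13, size = 1.7),
      dropout_rate = 0.10, seed = seed),
    "separable" = generator_config(
      n_streams, failure_rate = 0.5,
      signal = signal_spec(repertoire = 4, timing = 0.6,
                           length_ratio = 3),
      dropout_rate = 0.05, seed = seed))
}
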