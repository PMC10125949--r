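# Small in-code fixtures used across test files.

# A handful of hand-written streams with known structure.
tiny_streams <- function() {
  clickstream_set(list(
    clickstream("a", c("open", "search", "read", "submit"),
                c(5, 12, 20, 31), outcome = 0, total_time = 35),
    clickstream("b", c("open", "read"), c(8, 15), outcome = 1,
                total_time = 18),
    clickstream("c", c("search", "read", "search", "read", "submit"),
                c(3, 9, 14, 22, 40), outcome = 0, total_time = 44),
    clickstream("d", c("open", "open", "read"), c(10, 25, 55), outcome = 1,
                total_time = 60)
  ))
}

# Deterministic labeled collection of arbitrary size with varied lengths.
synthetic_collection <- function(n = 100, seed = 42, max_len = 12) {
  withr::with_seed(seed, {
    clickstream_set(lapply(seq_len(n), function(i) {
      len <- sample.int(max_len, 1)
      gaps <- rlnorm(len, log(4), 0.7)
      clickstream(sprintf("x%04d", i),
                  sample(LETTERS[1:6], len, replace = TRUE),
                  cumsum(gaps),
                  outcome = rbinom(1, 1, 0.4),
                  total_time = sum(gaps) + rlnorm(1, log(3), 0.4))
    }))
  })
}

expect_same_streams <- function(a, b, tol = 1e-9) {
  expect_equal(stream_ids(a), stream_ids(b))
  expect_equal(outcomes(a), outcomes(b))
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$events$action, b[[i]]$events$action)
    expect_equal(a[[i]]$events$t, b[[i]]$events$t, tolerance = tol)
    expect_equal(a[[i]]$total_time, b[[i]]$total_time, tolerance = tol)
  }
}
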