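test_that("strict pairing aligns indices and enforces its contract", {
  p <- pair_events(c(1.0, 2.5), c(1.12, 2.62))
  expect_equal(p$sent_index, 1:2)
  expect_equal(p$detected_index, 1:2)

  expect_error(pair_events(c(1, 2), 1.5), "2 sent vs 1 detected",
    class = "photolag_mismatch_error"
  )
  expect_error(pair_events(1.0, 0.9), "precedes",
    class = "photolag_mismatch_error"
  )
})

test_that("nearest_following pairs each trigger with the next free detection", {
  p <- pair_events(c(1.0, 2.5), 2.62, policy = "nearest_following")
  expect_equal(p$sent_index, 2L)
  expect_equal(p$detected_index, 1L)
  expect_equal(attr(p, "unmatched_sent"), 1L)

  # window is (sent, sent + max_lag]: a detection beyond the lag is not taken
  p2 <- pair_events(1.0, 2.62, policy = "nearest_following", max_lag_s = 1)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "unmatched_detected"), 1L)

  # each detection is consumed once
  p3 <- pair_events(c(1.0, 1.05), c(1.2, 1.3), policy = "nearest_following")
  expect_equal(p3$detected_index, 1:2)
})

test_that("latencies are (tD - tS) * 1000 with mean and n-1 sd", {
  r <- compute_latencies(1.0, 1.12198, "S1")
  expect_equal(r$latency_ms, 121.98)

  t <- c(1, 2, 3.5)
  r0 <- compute_latencies(t, t, "S2")
  expect_equal(r0$latency_ms, c(0, 0, 0))
  expect_equal(glance(r0)$mean_ms, 0)
  expect_equal(glance(r0)$sd_ms, 0)

  # identity: recomputing from the stored columns is bit-exact
  expect_identical(r0$latency_ms, (r0$tD_s - r0$tS_s) * 1000)

  # shift invariance
  sent <- c(1, 2.3, 4.1)
  det <- sent + c(0.1, 0.12, 0.09)
  a <- compute_latencies(sent, det)
  b <- compute_latencies(sent + 100, det + 100)
  expect_equal(a$latency_ms, b$latency_ms)

  # explicit check of the n-1 denominator
  r2 <- compute_latencies(c(0, 0), c(0.1, 0.2))
  expect_equal(glance(r2)$sd_ms, sd(c(100, 200)))
})

test_that("empty input gives an n = 0 result with flagged mean/sd", {
  r <- compute_latencies(numeric(), numeric(), "S1")
  expect_equal(nrow(r), 0)
  g <- glance(r)
  expect_equal(g$n, 0L)
  expect_true(is.na(g$mean_ms))
  expect_true(is.na(g$sd_ms))
})

test_that("Monte-Carlo latency recovery at n = 1000 (noiseless detection)", {
  withr::with_seed(77, {
    sent <- cumsum(runif(1000, 1.3, 1.8))
    lat <- rnorm(1000, 80, 7)
    r <- compute_latencies(sent, sent + lat / 1000)
    g <- glance(r)
    expect_lt(abs(g$mean_ms - 80), 3 * 7 / sqrt(1000))
    expect_lt(abs(g$sd_ms - 7) / 7, 0.10)
  })
})

test_that("histogram counts always sum to n", {
  withr::with_seed(8, {
    lat <- rnorm(250, 120, 9)
    r <- compute_latencies(seq_along(lat), seq_along(lat) + lat / 1000)
    h <- attr(r, "histogram")
    expect_equal(sum(h$count), 250)
    expect_equal(h$bin_right_ms - h$bin_left_ms, rep(1, nrow(h)))
  })
})

test_that("summarize_run aggregates types and flags empty ones", {
  withr::with_seed(12, {
    r1 <- compute_latencies(1:100, 1:100 + rnorm(100, 0.12, 0.008), "S1")
    r2 <- compute_latencies(1:100, 1:100 + rnorm(100, 0.12, 0.009), "S2")
  })
  rep2 <- summarize_run(list(r1, r2))
  expect_equal(rep2$summary$stimulus_type, c("S1", "S2"))
  expect_equal(rep2$summary$n, c(100L, 100L))
  expect_false(any(rep2$summary$empty))
  expect_equal(sort(unique(rep2$histogram$stimulus_type)), c("S1", "S2"))
  # the two series share one binning
  s1 <- rep2$histogram[rep2$histogram$stimulus_type == "S1", ]
  s2 <- rep2$histogram[rep2$histogram$stimulus_type == "S2", ]
  expect_equal(s1$bin_left_ms, s2$bin_left_ms)

  rep3 <- summarize_run(list(r1, compute_latencies(numeric(), numeric(), "S2")))
  expect_equal(rep3$summary$empty, c(FALSE, TRUE))
})

test_that("tidy/glance/autoplot provide the broom-style surface", {
  r <- compute_latencies(c(1, 2), c(1.1, 2.1), "S1")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "latency_result"))
  expect_named(td, c("stimulus_type", "event_index", "tS_s", "tD_s", "latency_ms"))
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(summarize_run(r)), "ggplot")
})
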