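test_that("find_all_peaks returns strict local maxima with plateau-first samples", {
  expect_equal(
    find_all_peaks(make_recording(c(0, 1, 0, 2, 0))),
    tibble::tibble(sample = c(2L, 4L), height = c(1, 2))
  )
  expect_equal(nrow(find_all_peaks(make_recording(1:100))), 0)
  # plateau contributes its first sample
  pk <- find_all_peaks(make_recording(c(0, 3, 3, 3, 1, 0)))
  expect_equal(pk$sample, 2L)
  expect_equal(pk$height, 3)
  # agreement with a brute-force scan on random traces
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- sample(0:5, 300, replace = TRUE)
      expect_identical(find_all_peaks(make_recording(x))$sample,
                       as.integer(bf_find_peaks(x)))
    }
  })
})

test_that("a synthetic refresh train has one peak per refresh period", {
  fs <- 500
  spacing <- round(fs / 90)
  x <- numeric(fs) # 1 s
  pk_pos <- seq(2, fs - 1, by = spacing)
  x[pk_pos] <- 50000
  pk <- find_all_peaks(make_recording(x, fs = fs))
  expect_equal(pk$sample, as.integer(pk_pos))
})

test_that("small_peak_mask marks exactly the peaks in qualifying runs", {
  fs <- 500
  n <- 600
  pos <- seq(2, by = 6, length.out = 20)
  x <- numeric(n)
  x[pos] <- 5000
  peaks <- find_all_peaks(make_recording(x, fs = fs))

  mask <- small_peak_mask(peaks, n, thd2 = 8000, run_window = 11)
  expect_identical(which(mask == 1L), as.integer(pos)) # all 20 marked
  expect_true(all(mask[-pos] == 0L)) # zero off-peak

  # alternating small/large peaks never form a run of 11 small ones
  x2 <- numeric(n)
  x2[pos] <- rep(c(5000, 200000), 10)
  peaks2 <- find_all_peaks(make_recording(x2, fs = fs))
  expect_identical(small_peak_mask(peaks2, n, 8000, 11), integer(n))

  # fewer peaks than the window: all-zero mask plus a warning
  x3 <- numeric(n)
  x3[pos[1:5]] <- 5000
  peaks3 <- find_all_peaks(make_recording(x3, fs = fs))
  expect_warning(m3 <- small_peak_mask(peaks3, n, 8000, 11), "run window")
  expect_identical(m3, integer(n))
})

test_that("window rule matches the literal 4-index rule on homogeneous runs", {
  withr::with_seed(9, {
    for (i in 1:20) {
      # homogeneous: every run of 11 consecutive peaks is all-small or has a
      # large peak in its first three or last position <=> generated as blocks
      # of >= 11 equal-height peaks
      heights <- unlist(lapply(
        sample(c(5000, 50000), 6, replace = TRUE),
        function(h) rep(h, sample(11:20, 1))
      ))
      pos <- seq(2, by = 6, length.out = length(heights))
      n <- max(pos) + 2L
      x <- numeric(n)
      x[pos] <- heights
      peaks <- find_all_peaks(make_recording(x))
      expect_identical(
        small_peak_mask(peaks, n, 8000, 11, rule = "window"),
        small_peak_mask(peaks, n, 8000, 11, rule = "literal")
      )
      expect_identical(
        small_peak_mask(peaks, n, 8000, 11, rule = "literal"),
        bf_small_peak_mask_literal(peaks$height, peaks$sample, n, 8000, 11)
      )
    }
  })
})

test_that("the two run rules differ when interior peaks of a window are large", {
  # small at positions 1,2,3 and 11, large in between: literal qualifies,
  # all-of-window does not
  heights <- c(rep(5000, 3), rep(50000, 7), 5000, rep(50000, 10))
  pos <- seq(2, by = 6, length.out = length(heights))
  n <- max(pos) + 2L
  x <- numeric(n)
  x[pos] <- heights
  peaks <- find_all_peaks(make_recording(x))
  expect_identical(small_peak_mask(peaks, n, 8000, 11, rule = "window"), integer(n))
  lit <- small_peak_mask(peaks, n, 8000, 11, rule = "literal")
  expect_identical(which(lit == 1L), as.integer(pos[1:11]))
})

test_that("HMD detection recovers injected onsets on clean synthetic data", {
  cfg <- synthetic_config("hmd",
    n_white = 10, n_black = 10,
    latency_ms = 80, latency_jitter_ms = 0, seed = 31
  )
  sim <- simulate_photodiode(cfg)
  p <- hmd_params()

  w <- detect_onsets_hmd(sim$recording, p, "white")
  tw <- truth_of(sim, "S1")
  expect_equal(nrow(w), 10)
  expect_true(all(abs(w$time_s - tw$onset_s) <= 1 / cfg$fs))

  b <- detect_onsets_hmd(sim$recording, p, "black")
  tb <- truth_of(sim, "S2")
  expect_equal(nrow(b), 10)
  expect_true(all(abs(b$time_s - tb$onset_s) <= 1 / cfg$fs))

  # regression: with the phase-anchored generator the black-onset detection
  # delay is exactly zero at every event (the run rule marks the first small
  # peak, which sits on the display onset)
  expect_equal(b$time_s, tb$onset_s)
})

test_that("the white HMD path is bit-identical to the LED pipeline", {
  sim <- simulate_photodiode(synthetic_config("hmd", n_white = 8, n_black = 8, seed = 13))
  via_hmd <- detect_onsets_hmd(sim$recording, hmd_params(), "white")
  via_led <- detect_onsets_led(
    sim$recording,
    detection_params("led", thd1 = 180000, thd2 = 8000), "white"
  )
  expect_identical(via_hmd, via_led)
})

test_that("a neutral-height peak train yields no onsets of either type", {
  fs <- 500
  x <- numeric(6000)
  x[seq(2, 5998, by = 6)] <- 50000 # between ThD2 = 8000 and ThD1 = 180000
  rec <- make_recording(x, fs = fs)
  expect_warning(w <- detect_onsets_hmd(rec, hmd_params(), "white"), "no white")
  expect_warning(b <- detect_onsets_hmd(rec, hmd_params(), "black"), "no black")
  expect_equal(nrow(w), 0)
  expect_equal(nrow(b), 0)
})
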