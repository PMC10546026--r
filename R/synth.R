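#' Configuration for the synthetic photodiode simulator
#'
#' The defaults reproduce the protocol the package targets: roughly one
#' hundred white and one hundred black full-screen stimuli in random order,
#' each shown for 0.3 s, separated by an inter-stimulus interval (stimulus
#' offset to next onset) drawn uniformly from 1.0–1.5 s, recorded at 500 Hz.
#' The LED screen refreshes at 100 Hz and produces a step-like waveform; the
#' HMD refreshes at 90 Hz and produces a continuous peak train whose peak
#' heights jump with the displayed colour. Injected per-event latency is
#' `latency_ms + Normal(0, latency_jitter_ms)`, truncated at zero; the
#' defaults are calibrated to the latency distributions such hardware
#' produces (LED about 122 ms for both colours, HMD about 83 ms white /
#' 70 ms black).
#'
#' @param mode `"led"` or `"hmd"`.
#' @param fs Sampling rate in Hz (default 500).
#' @param n_white,n_black Stimulus counts per type (default 100 each).
#' @param isi_range_s Inter-stimulus interval range (s), offset-to-onset
#'   (default `c(1.0, 1.5)`).
#' @param stim_dur_s Stimulus duration (s, default 0.3).
#' @param latency_ms Mean injected display latency (ms); length 1, or length
#'   2 as `c(white, black)`. Defaults: LED `c(121.98, 121.66)`, HMD
#'   `c(82.80, 69.82)`.
#' @param latency_jitter_ms SD of the per-event latency (ms); length 1 or 2.
#'   Defaults: LED `c(8.71, 8.80)`, HMD `c(7.63, 5.52)`.
#' @param refresh_hz Display refresh rate (default 100 LED / 90 HMD).
#' @param levels Named amplitudes `c(neutral=, white=, black=)` of the three
#'   display regimes (trace levels for LED, refresh-peak heights for HMD).
#'   Defaults put white above the canonical white threshold (60000 LED /
#'   180000 HMD) and black below the canonical black threshold (20000 LED /
#'   8000 HMD): LED `c(40000, 75000, 5000)`, HMD `c(50000, 200000, 5000)`.
#' @param noise_sd SD of additive Gaussian noise (default 0). Must stay
#'   below 10% of the smallest gap between a level and its threshold so
#'   that every stimulus crosses its threshold exactly once.
#' @param seed RNG seed (default 1); the generator is deterministic for a
#'   fixed seed.
#' @return A `synthetic_config` list.
#' @examples
#' synthetic_config("hmd", n_white = 10, n_black = 10, seed = 7)
#' @export
synthetic_config <- function(mode = c("led", "hmd"), fs = 500,
                             n_white = 100L, n_black = 100L,
                             isi_range_s = c(1.0, 1.5), stim_dur_s = 0.3,
                             latency_ms = NULL, latency_jitter_ms = NULL,
                             refresh_hz = NULL, levels = NULL,
                             noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  defaults <- if (mode == "led") {
    list(
      latency_ms = c(white = 121.98, black = 121.66),
      latency_jitter_ms = c(white = 8.71, black = 8.80),
      refresh_hz = 100,
      levels = c(neutral = 40000, white = 75000, black = 5000),
      thd1 = 60000, thd2 = 20000
    )
  } else {
    list(
      latency_ms = c(white = 82.80, black = 69.82),
      latency_jitter_ms = c(white = 7.63, black = 5.52),
      refresh_hz = 90,
      levels = c(neutral = 50000, white = 200000, black = 5000),
      thd1 = 180000, thd2 = 8000
    )
  }
  two <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, x)
    stats::setNames(as.numeric(x[1:2]), c("white", "black"))
  }
  latency_ms <- if (is.null(latency_ms)) defaults$latency_ms else two(latency_ms)
  latency_jitter_ms <- if (is.null(latency_jitter_ms)) {
    defaults$latency_jitter_ms
  } else {
    two(latency_jitter_ms)
  }
  refresh_hz <- refresh_hz %||% defaults$refresh_hz
  levels <- levels %||% defaults$levels
  if (is.null(names(levels)) || !all(c("neutral", "white", "black") %in% names(levels))) {
    stop_usage("`levels` must be named c(neutral=, white=, black=)")
  }
  if (any(latency_ms < 0)) stop_usage("`latency_ms` must be >= 0")
  if (fs <= 0 || stim_dur_s <= 0) stop_usage("`fs` and `stim_dur_s` must be > 0")
  if (length(isi_range_s) != 2L || isi_range_s[1] <= 0 || diff(isi_range_s) < 0) {
    stop_usage("`isi_range_s` must be c(low, high) with 0 < low <= high")
  }
  cfg <- structure(
    list(
      mode = mode, fs = fs, n_white = as.integer(n_white),
      n_black = as.integer(n_black), isi_range_s = as.numeric(isi_range_s),
      stim_dur_s = stim_dur_s, latency_ms = latency_ms,
      latency_jitter_ms = latency_jitter_ms, refresh_hz = refresh_hz,
      levels = levels, noise_sd = noise_sd, seed = as.integer(seed),
      thd1 = defaults$thd1, thd2 = defaults$thd2
    ),
    class = "synthetic_config"
  )
  check_detectability(cfg)
  cfg
}

# every stimulus must cross its threshold exactly once: white must sit above
# ThD1, black below ThD2, neutral strictly between, and the noise must be
# small relative to the tightest level/threshold margin.
check_detectability <- function(cfg) {
  lv <- cfg$levels
  gaps <- c(
    white_over_thd1 = lv[["white"]] - cfg$thd1,
    neutral_under_thd1 = cfg$thd1 - lv[["neutral"]],
    neutral_over_thd2 = lv[["neutral"]] - cfg$thd2,
    black_under_thd2 = cfg$thd2 - lv[["black"]]
  )
  if (any(gaps <= 0)) {
    bad <- names(gaps)[gaps <= 0]
    stop_usage(sprintf(
      "levels violate the detectability guarantee (%s); adjust `levels`",
      paste(bad, collapse = ", ")
    ))
  }
  if (cfg$noise_sd > 0.1 * min(gaps)) {
    stop_usage(sprintf(
      "`noise_sd` (%g) exceeds 10%% of the smallest level/threshold gap (%g)",
      cfg$noise_sd, min(gaps)
    ))
  }
  invisible(cfg)
}

#' Simulate a photodiode recording with known latencies
#'
#' Generates the trigger schedule, the injected per-event display latencies
#' and the photodiode waveform for one run, together with the marker table
#' ("S7" at the start, one "S1"/"S2" per stimulus, "S8" at the end) and a
#' ground-truth table for parameter-recovery checks. Trigger times are
#' snapped to the sample grid (they enter the marker file as sample
#' positions); display onsets are snapped to the nearest sample, and the
#' ground-truth latency is recomputed from the snapped times, so detection
#' on a clean trace can recover every latency to within one sample.
#'
#' LED mode draws a neutral baseline with, per stimulus, a two-sample
#' half-way ramp into a plateau at the white (or black) level for the
#' stimulus duration. HMD mode draws a continuous train of single-sample
#' refresh peaks spaced `round(fs / refresh_hz)` samples apart whose heights
#' take the neutral/white/black level of the current regime; the peak phase
#' restarts at each regime change, placing one peak exactly at each display
#' onset.
#'
#' @param config A [synthetic_config()].
#' @return A list with `recording` ([photodiode_recording()]), `markers`
#'   (tibble), and `truth` (tibble: `event`, `stimulus_type`, `send_s`,
#'   `onset_s`, `latency_ms`).
#' @examples
#' sim <- simulate_photodiode(synthetic_config("led", n_white = 5, n_black = 5))
#' sim$truth
#' @export
simulate_photodiode <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n_ev <- cfg$n_white + cfg$n_black
    types <- sample(c(rep("S1", cfg$n_white), rep("S2", cfg$n_black)))
    isi <- runif(n_ev - 1L, cfg$isi_range_s[1], cfg$isi_range_s[2])
    sends <- cumsum(c(2.0, isi + cfg$stim_dur_s))
    sends <- round(sends * cfg$fs) / cfg$fs # triggers live on the sample grid
    is_white <- types == "S1"
    lat_mean <- ifelse(is_white, cfg$latency_ms[["white"]], cfg$latency_ms[["black"]])
    lat_sd <- ifelse(is_white, cfg$latency_jitter_ms[["white"]],
      cfg$latency_jitter_ms[["black"]]
    )
    lat <- pmax(0, rnorm(n_ev, lat_mean, lat_sd))
    onset_idx <- round((sends + lat / 1000) * cfg$fs) + 1L
    onsets <- (onset_idx - 1L) / cfg$fs
    offset_idx <- onset_idx + round(cfg$stim_dur_s * cfg$fs)

    if (any(diff(onset_idx) <= round(cfg$stim_dur_s * cfg$fs))) {
      stop_usage("injected latency jitter makes stimulus regimes overlap; lower the jitter")
    }

    n_samp <- offset_idx[n_ev] + as.integer(2 * cfg$fs)
    lv <- cfg$levels
    stim_level <- ifelse(is_white, lv[["white"]], lv[["black"]])

    if (cfg$mode == "led") {
      trace <- rep(lv[["neutral"]], n_samp)
      for (k in seq_len(n_ev)) {
        i0 <- onset_idx[k]
        i1 <- offset_idx[k]
        trace[i0:(i1 - 1L)] <- stim_level[k]
        trace[i0 - 1L] <- (lv[["neutral"]] + stim_level[k]) / 2
        trace[i1] <- (lv[["neutral"]] + stim_level[k]) / 2
      }
    } else {
      spacing <- round(cfg$fs / cfg$refresh_hz)
      trace <- numeric(n_samp)
      # regime segments: [start, end) index + peak height; phase restarts at
      # every boundary so a peak sits exactly on each display onset
      seg_start <- c(1L, as.integer(rbind(onset_idx, offset_idx)))
      seg_level <- c(lv[["neutral"]], as.numeric(rbind(stim_level, lv[["neutral"]])))
      seg_end <- c(seg_start[-1L], n_samp + 1L)
      for (s in seq_along(seg_start)) {
        if (seg_end[s] <= seg_start[s]) next
        pk <- seq.int(seg_start[s], seg_end[s] - 1L, by = spacing)
        # a peak touching the next segment's onset peak would stop that onset
        # from being a strict local maximum; drop it (a skipped frame at the
        # transition) so every regime change stays detectable at its onset
        if (s < length(seg_start)) pk <- pk[pk < seg_end[s] - 1L]
        trace[pk] <- seg_level[s]
      }
    }
    if (cfg$noise_sd > 0) trace <- trace + rnorm(n_samp, 0, cfg$noise_sd)

    markers <- marker_table(
      label = c("S7", types, "S8"),
      onset_s = c(0.5, sends, (n_samp - 1L) / cfg$fs - 0.5)
    )
    truth <- tibble(
      event = seq_len(n_ev),
      stimulus_type = types,
      send_s = sends,
      onset_s = onsets,
      latency_ms = (onsets - sends) * 1000
    )
    list(
      recording = photodiode_recording(trace, fs = cfg$fs, channel_name = "PHOTO"),
      markers = markers,
      truth = truth
    )
  })
}

#' Write a recording and markers as a BrainVision triplet
#'
#' Emits `.vhdr`/`.vmrk`/`.eeg` files (IEEE_FLOAT_32, multiplexed by
#' default) that [read_brainvision()] and standard third-party readers can
#' load. Marker onsets are converted back to 1-based sample positions with
#' `round(onset_s * fs) + 1`.
#'
#' @param recording A [photodiode_recording()].
#' @param markers A marker table.
#' @param dir_path Output directory (created if needed).
#' @param basename File stem for the triplet (default `"synthetic"`).
#' @param binary_format `"IEEE_FLOAT_32"` (default), `"INT_16"` or
#'   `"INT_32"` — the integer formats truncate towards zero and are meant
#'   for reader testing.
#' @param orientation `"MULTIPLEXED"` (default) or `"VECTORIZED"`.
#' @return Named list of the three file paths (`vhdr`, `vmrk`, `eeg`).
#' @export
write_fixture <- function(recording, markers, dir_path, basename = "synthetic",
                          binary_format = c("IEEE_FLOAT_32", "INT_16", "INT_32"),
                          orientation = c("MULTIPLEXED", "VECTORIZED")) {
  binary_format <- match.arg(binary_format)
  orientation <- match.arg(orientation)
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  vhdr <- file.path(dir_path, paste0(basename, ".vhdr"))
  vmrk <- file.path(dir_path, paste0(basename, ".vmrk"))
  eeg <- file.path(dir_path, paste0(basename, ".eeg"))

  interval_us <- round(1e6 / recording$fs)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; generated by the photolag synthetic-signal simulator",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    "NumberOfChannels=1",
    paste0("SamplingInterval=", interval_us),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    "; Each entry: Ch<n>=<Name>,<Reference>,<Resolution>,<Unit>",
    sprintf("Ch1=%s,,1,µV", bv_escape(recording$channel_name))
  ), vhdr, useBytes = FALSE)

  pos <- round(markers$onset_s * recording$fs) + 1
  mk_lines <- sprintf(
    "Mk%d=%s,%s,%d,1,0",
    seq_len(nrow(markers)) + 1L, markers$type, bv_escape(markers$label), pos
  )
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    "",
    "[Marker Infos]",
    "; Each entry: Mk<n>=<Type>,<Description>,<Position>,<Size>,<Channel>",
    "Mk1=New Segment,,1,1,0,20230101000000000000",
    mk_lines
  ), vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(recording$samples), con, size = 4L, endian = "little")
  } else {
    size <- if (binary_format == "INT_16") 2L else 4L
    writeBin(as.integer(round(recording$samples)), con, size = size, endian = "little")
  }
  list(vhdr = vhdr, vmrk = vmrk, eeg = eeg)
}
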