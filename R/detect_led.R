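#' Binary threshold mask of a photodiode trace
#'
#' Marks each sample that is at or beyond a threshold: `direction = "above"`
#' gives `1` where `samples >= threshold` (white-stimulus excursions),
#' `direction = "below"` gives `1` where `samples <= threshold`
#' (black-stimulus drops). Both comparisons are inclusive.
#'
#' @param recording A [photodiode_recording()].
#' @param threshold Amplitude threshold in the trace's raw units.
#' @param direction `"above"` or `"below"`.
#' @return An integer vector of 0/1, one entry per sample.
#' @examples
#' rec <- photodiode_recording(c(10, 70000, 70000, 10), fs = 500)
#' threshold_mask(rec, 60000, "above")
#' @export
threshold_mask <- function(recording, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  x <- recording$samples
  if (direction == "above") {
    as.integer(x >= threshold)
  } else {
    as.integer(x <= threshold)
  }
}

#' Rising edges of a binary mask
#'
#' First-difference edge detection with a leading zero pad: the difference
#' series of the mask is prefixed with 0 and every position where it equals
#' +1 is an edge, i.e. every index `i >= 2` with `bits[i] == 1` and
#' `bits[i - 1] == 0`. Because of the pad, the first sample can never be an
#' edge even if the mask starts at 1 — a stimulus already in progress when
#' the recording starts has no detectable onset.
#'
#' @param mask Integer 0/1 vector, e.g. from [threshold_mask()].
#' @return Ascending integer vector of edge indices (1-based).
#' @examples
#' rising_edges(c(0, 0, 1, 1, 0, 1)) # 3 and 6
#' rising_edges(c(1, 1, 0)) # none: leading pad suppresses index 1
#' @export
rising_edges <- function(mask) {
  if (length(mask) == 0L) {
    return(integer())
  }
  d <- c(0L, diff(as.integer(mask)))
  which(d == 1L)
}

#' Group edges into stimulus onsets by minimum index gap
#'
#' The first edge is always kept. Each subsequent edge is kept iff it
#' exceeds the immediately preceding *edge* (not the last kept onset) by
#' more than `indx_gap` samples — a literal transcription of the original
#' grouping rule. The two readings differ only on pathological edge trains;
#' see the methods vignette.
#'
#' @param edges Ascending integer vector of edge indices.
#' @param indx_gap Minimum separation in samples, typically
#'   `round(fs * lisi)`; must be >= 1.
#' @return Ascending integer vector of onset sample indices.
#' @examples
#' group_onsets(c(100, 105, 700), 500) # 100 and 700
#' group_onsets(c(100, 400, 800), 500) # only 100
#' @export
group_onsets <- function(edges, indx_gap) {
  if (length(indx_gap) != 1L || !is.finite(indx_gap) || indx_gap < 1) {
    stop_usage("`indx_gap` must be a single value >= 1")
  }
  edges <- as.integer(edges)
  if (length(edges) == 0L) {
    return(integer())
  }
  edges[c(TRUE, diff(edges) > indx_gap)]
}

onset_tibble <- function(recording, onset_samples) {
  tibble(
    sample = as.integer(onset_samples),
    time_s = recording$t0 + (as.integer(onset_samples) - 1) / recording$fs
  )
}

#' Detect stimulus onsets in an LED-screen photodiode trace
#'
#' Runs the step-waveform pipeline: threshold mask, padded first-difference
#' rising edges, and inter-stimulus-gap grouping with
#' `indx_gap = round(fs * lisi)`. White stimuli use the mask above `thd1`;
#' black stimuli use the mask below `thd2` by default (set
#' `led_black_polarity = "above"` in [detection_params()] for the literal
#' printed comparator).
#'
#' @param recording A [photodiode_recording()].
#' @param params A [detection_params()] with `mode = "led"`.
#' @param stimulus `"white"` or `"black"`.
#' @return A tibble (`sample`, `time_s`) of detected onsets, strictly
#'   increasing and separated by more than the index gap. Zero detections
#'   yield an empty tibble with a warning, not an error.
#' @examples
#' cfg <- synthetic_config("led", n_white = 5, n_black = 5, seed = 1)
#' sim <- simulate_photodiode(cfg)
#' p <- detection_params("led", thd1 = 60000, thd2 = 20000)
#' detect_onsets_led(sim$recording, p, "white")
#' @export
detect_onsets_led <- function(recording, params, stimulus = c("white", "black")) {
  stimulus <- match.arg(stimulus)
  stopifnot(inherits(params, "detection_params"))
  if (params$mode != "led") stop_usage("`params$mode` must be 'led' for detect_onsets_led()")
  mask <- if (stimulus == "white") {
    threshold_mask(recording, params$thd1, "above")
  } else if (params$led_black_polarity == "below") {
    threshold_mask(recording, params$thd2, "below")
  } else {
    threshold_mask(recording, params$thd2, "above")
  }
  finish_onsets(recording, mask, params, stimulus)
}

finish_onsets <- function(recording, mask, params, stimulus) {
  indx_gap <- round(recording$fs * params$lisi)
  onsets <- group_onsets(rising_edges(mask), indx_gap)
  if (length(onsets) == 0L) {
    warn(sprintf("no %s-stimulus onsets detected; check the thresholds", stimulus))
  }
  onset_tibble(recording, onsets)
}

#' Detect onsets with either display algorithm
#'
#' Dispatches on `params$mode` to [detect_onsets_led()] or
#' [detect_onsets_hmd()].
#'
#' @inheritParams detect_onsets_led
#' @return A tibble (`sample`, `time_s`) of detected onsets.
#' @export
detect_onsets <- function(recording, params, stimulus = c("white", "black")) {
  stopifnot(inherits(params, "detection_params"))
  if (params$mode == "led") {
    detect_onsets_led(recording, params, stimulus)
  } else {
    detect_onsets_hmd(recording, params, stimulus)
  }
}
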