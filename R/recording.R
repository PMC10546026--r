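#' Photodiode recording
#'
#' A lightweight container for a single-channel photodiode trace: the sampled
#' amplitudes (raw ADC units), the sampling rate and the recording start
#' offset. Sample `i` (1-based, as everywhere in R) sits at time
#' `t0 + (i - 1) / fs` seconds, i.e. the first sample is at `t0`.
#'
#' @param samples Numeric vector of amplitudes. Must be non-empty and finite;
#'   non-finite values are rejected because every downstream step thresholds
#'   raw amplitudes.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_name Name of the source channel.
#' @param t0 Time (s) of the first sample in recording coordinates.
#'
#' @return An object of class `photodiode_recording` with fields `samples`,
#'   `fs`, `channel_name` and `t0`.
#' @examples
#' rec <- photodiode_recording(c(0, 0, 1, 1, 0), fs = 500)
#' rec$fs
#' @export
photodiode_recording <- function(samples, fs, channel_name = "PHOTO", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop_data("a photodiode recording must contain at least one sample")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_data("photodiode samples contain non-finite values; refusing to threshold them")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_data("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      channel_name = as.character(channel_name),
      t0 = as.numeric(t0)
    ),
    class = "photodiode_recording"
  )
}

#' @export
print.photodiode_recording <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<photodiode_recording> channel %s: %d samples @ %g Hz (%.1f s), t0 = %g s\n",
    x$channel_name, length(x$samples), x$fs, dur, x$t0
  ))
  invisible(x)
}

#' Times of all samples in a recording
#'
#' @param recording A [photodiode_recording()].
#' @return Numeric vector of sample times (s), same length as the trace.
#' @export
sample_times <- function(recording) {
  recording$t0 + (seq_along(recording$samples) - 1) / recording$fs
}

#' @method as_tibble photodiode_recording
#' @export
as_tibble.photodiode_recording <- function(x, ...) {
  tibble(time_s = sample_times(x), amplitude = x$samples)
}

#' Restrict a recording to a time window
#'
#' Keeps the samples whose times fall in `[from_s, to_s]` and shifts `t0` so
#' that downstream onset times stay in the original recording coordinates.
#' Used to confine detection to the span between start and end markers.
#'
#' @param recording A [photodiode_recording()].
#' @param from_s,to_s Window bounds in recording coordinates (s).
#' @return A `photodiode_recording` covering the window.
#' @export
window_recording <- function(recording, from_s, to_s) {
  if (to_s < from_s) stop_data("`to_s` must be >= `from_s`")
  t <- sample_times(recording)
  keep <- which(t >= from_s & t <= to_s)
  if (length(keep) == 0L) {
    stop_data("the requested window contains no samples")
  }
  photodiode_recording(
    recording$samples[keep],
    fs = recording$fs,
    channel_name = recording$channel_name,
    t0 = t[keep[1]]
  )
}

# markers --------------------------------------------------------------------

#' Build a marker table
#'
#' Markers are the timestamped labels the presentation software injects into
#' the EEG recording ("S1" for white stimuli, "S2" for black, "S7"/"S8" for
#' start/end of a run). The table is kept sorted by onset, stably for ties.
#'
#' @param label Character vector of marker descriptions.
#' @param onset_s Numeric vector of onset times (s), same length, all >= 0.
#' @param type Marker type column (BrainVision "Stimulus", "New Segment", ...).
#' @param strict If `TRUE`, stimulus labels must come from
#'   `c("S1", "S2", "S7", "S8")`.
#' @return A tibble with columns `type`, `label`, `onset_s`.
#' @export
marker_table <- function(label, onset_s, type = "Stimulus", strict = FALSE) {
  if (length(label) != length(onset_s)) {
    stop_data("`label` and `onset_s` must have the same length")
  }
  onset_s <- as.numeric(onset_s)
  if (anyNA(onset_s) || any(onset_s < 0)) {
    stop_data("marker onsets must be finite and >= 0")
  }
  tb <- tibble(
    type = rep_len(as.character(type), length(label)),
    label = as.character(label),
    onset_s = onset_s
  )
  if (strict) {
    bad <- setdiff(unique(tb$label[tb$type == "Stimulus"]), c("S1", "S2", "S7", "S8"))
    if (length(bad) > 0L) {
      stop_data(sprintf(
        "unexpected stimulus labels in strict mode: %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  tb[order(tb$onset_s), , drop = FALSE]
}

#' Onset times of one marker label
#'
#' @param markers A marker table (see [marker_table()]).
#' @param label The label to select, e.g. `"S1"`.
#' @return Ascending numeric vector of onset times (s).
#' @export
marker_onsets <- function(markers, label) {
  sort(markers$onset_s[markers$label == label])
}
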