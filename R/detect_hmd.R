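#' Find all local maxima of a photodiode trace
#'
#' Returns every strict local maximum; a plateau (run of equal values whose
#' neighbours on both sides are lower) contributes its first sample. No
#' prominence or width filtering is applied — an HMD photodiode trace is a
#' clean train of refresh peaks and the thresholding happens downstream.
#'
#' @param recording A [photodiode_recording()] with at least 3 samples.
#' @return A tibble with columns `sample` (ascending indices) and `height`
#'   (`samples[sample]`).
#' @examples
#' rec <- photodiode_recording(c(0, 1, 0, 2, 0), fs = 500)
#' find_all_peaks(rec)
#' @export
find_all_peaks <- function(recording) {
  x <- recording$samples
  if (length(x) < 3L) stop_usage("peak finding needs at least 3 samples")
  r <- rle(x)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_peak <- logical(k)
  if (k >= 3L) {
    mid <- 2:(k - 1L)
    is_peak[mid] <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  }
  idx <- starts[is_peak]
  tibble(sample = as.integer(idx), height = x[idx])
}

#' Mark runs of small refresh peaks
#'
#' An HMD shows black stimuli as stretches where the refresh peaks shrink
#' below `thd2`. A peak qualifies when it begins a run of `run_window`
#' consecutive peaks whose heights are all strictly below `thd2`
#' (`rule = "window"`, the default), or when it belongs to such a run; the
#' mask is 1 at the sample positions of every qualifying peak and 0
#' everywhere else (in particular at every non-peak sample). With
#' `rule = "literal"` only the 1st, 2nd, 3rd and last peak heights of each
#' window are tested; on traces whose 11-peak windows are homogeneous the
#' two rules give identical masks.
#'
#' @param peaks A tibble from [find_all_peaks()].
#' @param n_samples Length of the underlying trace.
#' @param thd2 Height threshold (strict `<`, as specified).
#' @param run_window Run length in peaks (default 11); must be >= 2.
#' @param rule `"window"` or `"literal"`.
#' @return Integer 0/1 mask of length `n_samples`. Fewer than `run_window`
#'   peaks in total yield an all-zero mask with a warning.
#' @export
small_peak_mask <- function(peaks, n_samples, thd2, run_window = 11L,
                            rule = c("window", "literal")) {
  rule <- match.arg(rule)
  run_window <- as.integer(run_window)
  if (is.na(run_window) || run_window < 2L) stop_usage("`run_window` must be >= 2")
  mask <- integer(n_samples)
  k <- nrow(peaks)
  if (k < run_window) {
    warn(sprintf(
      "only %d peaks found but the run window is %d; returning an all-zero mask",
      k, run_window
    ))
    return(mask)
  }
  small <- peaks$height < thd2
  n_starts <- k - run_window + 1L
  idx <- seq_len(n_starts)
  ok <- if (rule == "window") {
    cs <- cumsum(c(0L, as.integer(small)))
    (cs[idx + run_window] - cs[idx]) == run_window
  } else {
    small[idx] & small[idx + 1L] & small[idx + 2L] & small[idx + run_window - 1L]
  }
  if (!any(ok)) {
    return(mask)
  }
  # every peak covered by at least one qualifying window is marked
  covered <- logical(k)
  delta <- integer(k + 1L)
  ok_idx <- which(ok)
  delta[ok_idx] <- delta[ok_idx] + 1L
  delta[ok_idx + run_window] <- delta[ok_idx + run_window] - 1L
  covered <- cumsum(delta[seq_len(k)]) > 0L
  mask[peaks$sample[covered]] <- 1L
  mask
}

#' Detect stimulus onsets in an HMD photodiode trace
#'
#' White stimuli raise the refresh-peak heights above `thd1`; their onsets
#' are found with exactly the same mask/edge/group pipeline as the LED
#' screen, applied to the peak-train trace (the result is bit-identical to
#' [detect_onsets_led()] run with the HMD thresholds). Black stimuli shrink
#' the peaks below `thd2`; their onsets are found by substituting the
#' small-peak-run mask from [small_peak_mask()] into the same edge/group
#' steps.
#'
#' @param recording A [photodiode_recording()].
#' @param params A [detection_params()] with `mode = "hmd"`.
#' @param stimulus `"white"` or `"black"`.
#' @return A tibble (`sample`, `time_s`) of detected onsets.
#' @examples
#' cfg <- synthetic_config("hmd", n_white = 5, n_black = 5, seed = 1)
#' sim <- simulate_photodiode(cfg)
#' p <- detection_params("hmd", thd1 = 180000, thd2 = 8000)
#' detect_onsets_hmd(sim$recording, p, "black")
#' @export
detect_onsets_hmd <- function(recording, params, stimulus = c("white", "black")) {
  stimulus <- match.arg(stimulus)
  stopifnot(inherits(params, "detection_params"))
  if (params$mode != "hmd") stop_usage("`params$mode` must be 'hmd' for detect_onsets_hmd()")
  mask <- if (stimulus == "white") {
    threshold_mask(recording, params$thd1, "above")
  } else {
    peaks <- find_all_peaks(recording)
    small_peak_mask(peaks, length(recording$samples), params$thd2,
      run_window = params$hmd_run_window, rule = params$hmd_rule
    )
  }
  finish_onsets(recording, mask, params, stimulus)
}
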