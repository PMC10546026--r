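#' Detection parameters
#'
#' Bundles the tunables of the onset-detection algorithms. `thd1` is the
#' amplitude above which a white-stimulus excursion is detected; `thd2` the
#' amplitude below which a black-stimulus signature is detected (for an LED
#' screen a transient drop, for an HMD the height of the small refresh peaks
#' between stimuli). `lisi` is the lower bound of the inter-stimulus
#' interval: threshold crossings closer than `round(fs * lisi)` samples
#' (the index gap) are folded into a single onset.
#'
#' Thresholds are deliberately mandatory: they depend on the photodiode,
#' display and gain, and are meant to be read off a plot of the raw trace
#' (see [suggest_thresholds()] for a starting point; it is never applied
#' silently).
#'
#' @param mode `"led"` (step-like waveform of a constantly lit screen) or
#'   `"hmd"` (refresh-rate peak train of a head-mounted display).
#' @param thd1 Amplitude threshold (ADC units) for white-stimulus detection.
#' @param thd2 Amplitude threshold (ADC units) for black-stimulus detection.
#' @param lisi Lower inter-stimulus-interval bound in seconds (default 1).
#' @param hmd_run_window Number of consecutive small peaks that must fall
#'   below `thd2` to mark a black period in HMD mode (default 11).
#' @param led_black_polarity `"below"` (default: black stimuli are detected
#'   where the trace drops to or below `thd2`) or `"above"` (the literal
#'   printed comparator of the original procedure, kept selectable).
#' @param hmd_rule `"window"` (default: all `hmd_run_window` consecutive peak
#'   heights must be below `thd2`) or `"literal"` (only the 1st, 2nd, 3rd and
#'   last peak of the window are tested; see the methods vignette).
#' @return An object of class `detection_params`.
#' @examples
#' detection_params("led", thd1 = 60000, thd2 = 20000)
#' detection_params("hmd", thd1 = 180000, thd2 = 8000)
#' @export
detection_params <- function(mode = c("led", "hmd"), thd1, thd2, lisi = 1,
                             hmd_run_window = 11L,
                             led_black_polarity = c("below", "above"),
                             hmd_rule = c("window", "literal")) {
  mode <- match.arg(mode)
  led_black_polarity <- match.arg(led_black_polarity)
  hmd_rule <- match.arg(hmd_rule)
  if (missing(thd1) || missing(thd2)) {
    stop_usage("both `thd1` and `thd2` must be supplied (read them off the raw trace)")
  }
  if (!is.finite(lisi) || lisi <= 0) stop_usage("`lisi` must be > 0 seconds")
  hmd_run_window <- as.integer(hmd_run_window)
  if (is.na(hmd_run_window) || hmd_run_window < 2L) {
    stop_usage("`hmd_run_window` must be an integer >= 2")
  }
  if (mode == "led" && led_black_polarity == "below" && !(thd2 < thd1)) {
    stop_usage("for LED mode with the default polarity, `thd2` must be < `thd1`")
  }
  structure(
    list(
      mode = mode, thd1 = as.numeric(thd1), thd2 = as.numeric(thd2),
      lisi = as.numeric(lisi), hmd_run_window = hmd_run_window,
      led_black_polarity = led_black_polarity, hmd_rule = hmd_rule
    ),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "<detection_params> mode=%s thd1=%g thd2=%g lisi=%gs run_window=%d\n",
    x$mode, x$thd1, x$thd2, x$lisi, x$hmd_run_window
  ))
  invisible(x)
}

#' Suggest detection thresholds from a raw trace
#'
#' Convenience starting point replacing nothing: the midpoint between the
#' 99.9th amplitude percentile and the baseline median is proposed for the
#' white threshold, and the midpoint between the 0.1th percentile and the
#' median for the black threshold. The values are returned, never applied —
#' thresholds remain an explicit user input, matching the intended
#' inspect-the-plot workflow.
#'
#' @param recording A [photodiode_recording()].
#' @return A tibble with columns `thd1` and `thd2`.
#' @export
suggest_thresholds <- function(recording) {
  x <- recording$samples
  med <- median(x)
  hi <- quantile(x, 0.999, names = FALSE)
  lo <- quantile(x, 0.001, names = FALSE)
  tibble(thd1 = (hi + med) / 2, thd2 = (lo + med) / 2)
}
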