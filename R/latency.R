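#' Pair sent triggers with detected onsets
#'
#' With `policy = "strict"` the two arrays must have equal lengths and are
#' paired index-by-index (the protocol guarantees one detection per
#' stimulus); unequal lengths, or any detection preceding its trigger, is an
#' error. With `policy = "nearest_following"` each sent time is paired with
#' the earliest not-yet-consumed detection in `(sent, sent + max_lag_s]`;
#' events with no detection in that window are reported unmatched. The
#' relaxed policy is for non-ideal traces where an onset may be missed or
#' spurious.
#'
#' @param sent Ascending numeric vector of trigger times (s).
#' @param detected Ascending numeric vector of detected onset times (s).
#' @param policy `"strict"` or `"nearest_following"`.
#' @param max_lag_s Matching window for `nearest_following` (s, > 0;
#'   default 1, the usual lower ISI bound).
#' @return A tibble with columns `sent_index`, `detected_index` (1-based),
#'   with attributes `unmatched_sent` and `unmatched_detected` (integer
#'   index vectors).
#' @examples
#' pair_events(c(1.0, 2.5), c(1.12, 2.62))
#' pair_events(c(1.0, 2.5), 2.62, policy = "nearest_following")
#' @export
pair_events <- function(sent, detected, policy = c("strict", "nearest_following"),
                        max_lag_s = 1) {
  policy <- match.arg(policy)
  if (is.unsorted(sent) || is.unsorted(detected)) {
    stop_usage("`sent` and `detected` must be ascending")
  }
  if (!is.finite(max_lag_s) || max_lag_s <= 0) stop_usage("`max_lag_s` must be > 0")
  if (policy == "strict") {
    if (length(sent) != length(detected)) {
      stop_mismatch(sprintf(
        "strict pairing needs equal counts: %d sent vs %d detected",
        length(sent), length(detected)
      ))
    }
    if (any(detected < sent)) {
      stop_mismatch("a detection precedes its trigger under strict pairing")
    }
    out <- tibble(sent_index = seq_along(sent), detected_index = seq_along(detected))
    attr(out, "unmatched_sent") <- integer()
    attr(out, "unmatched_detected") <- integer()
    return(out)
  }
  used <- logical(length(detected))
  si <- integer()
  di <- integer()
  for (i in seq_along(sent)) {
    cand <- which(!used & detected > sent[i] & detected <= sent[i] + max_lag_s)
    if (length(cand) > 0L) {
      j <- cand[1]
      used[j] <- TRUE
      si <- c(si, i)
      di <- c(di, j)
    }
  }
  out <- tibble(sent_index = si, detected_index = di)
  attr(out, "unmatched_sent") <- setdiff(seq_along(sent), si)
  attr(out, "unmatched_detected") <- which(!used)
  out
}

#' Per-event trigger-to-display latencies
#'
#' The core quantity: for paired, equal-length arrays of sent trigger times
#' and detected display-onset times, the latency of event `k` is
#' `(detected[k] - sent[k]) * 1000` milliseconds. The result carries the
#' event table plus summary statistics (arithmetic mean, sample standard
#' deviation with the n-1 denominator) and a histogram of the latency
#' distribution.
#'
#' @param sent Ascending numeric vector of trigger times (s).
#' @param detected Ascending numeric vector of detected onset times (s),
#'   same length.
#' @param stimulus_type Label for the stimulus set, e.g. `"S1"` (white) or
#'   `"S2"` (black).
#' @param binwidth_ms Histogram bin width in ms (default 1).
#' @return A `latency_result`: a tibble with columns `stimulus_type`,
#'   `event_index`, `tS_s`, `tD_s`, `latency_ms` and attributes `n`,
#'   `mean_ms`, `sd_ms`, `histogram` (tibble of `bin_left_ms`,
#'   `bin_right_ms`, `count`). Empty inputs give an empty result with
#'   `n = 0` and `NA` mean/sd.
#' @examples
#' compute_latencies(c(1.0, 2.5), c(1.12, 2.62), "S1")
#' @export
compute_latencies <- function(sent, detected, stimulus_type = "S1", binwidth_ms = 1) {
  if (length(sent) != length(detected)) {
    stop_mismatch(sprintf(
      "`sent` and `detected` must be paired and equal length (%d vs %d); see pair_events()",
      length(sent), length(detected)
    ))
  }
  lat <- (detected - sent) * 1000
  out <- tibble(
    stimulus_type = rep_len(as.character(stimulus_type), length(lat)),
    event_index = seq_along(lat),
    tS_s = as.numeric(sent),
    tD_s = as.numeric(detected),
    latency_ms = lat
  )
  n <- length(lat)
  attr(out, "n") <- n
  attr(out, "mean_ms") <- if (n > 0L) mean(lat) else NA_real_
  attr(out, "sd_ms") <- if (n > 1L) sd(lat) else if (n == 1L) 0 else NA_real_
  attr(out, "histogram") <- latency_histogram(lat, binwidth_ms)
  attr(out, "stimulus_type") <- as.character(stimulus_type)[1]
  class(out) <- c("latency_result", class(out))
  out
}

latency_histogram <- function(latencies_ms, binwidth_ms = 1) {
  if (length(latencies_ms) == 0L) {
    return(tibble(bin_left_ms = numeric(), bin_right_ms = numeric(), count = integer()))
  }
  lo <- floor(min(latencies_ms) / binwidth_ms) * binwidth_ms
  hi <- ceiling(max(latencies_ms) / binwidth_ms) * binwidth_ms
  if (hi <= lo) hi <- lo + binwidth_ms
  breaks <- seq(lo, hi, by = binwidth_ms)
  h <- graphics::hist(latencies_ms, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  tibble(
    bin_left_ms = head(h$breaks, -1),
    bin_right_ms = tail(h$breaks, -1),
    count = as.integer(h$counts)
  )
}

#' @export
print.latency_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<latency_result> %s: n=%d, mean=%.2f ms, sd=%.2f ms\n",
    g$stimulus_type, g$n, g$mean_ms, g$sd_ms
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-event latency table of a latency result
#'
#' @param x A `latency_result`.
#' @param ... Unused.
#' @return A plain tibble with one row per event.
#' @method tidy latency_result
#' @export
tidy.latency_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "latency_result")
  attr(out, "n") <- attr(out, "mean_ms") <- attr(out, "sd_ms") <- NULL
  attr(out, "histogram") <- attr(out, "stimulus_type") <- NULL
  as_tibble(out)
}

#' One-row summary of a latency result
#'
#' @param x A `latency_result`.
#' @param ... Unused.
#' @return A tibble with columns `stimulus_type`, `n`, `mean_ms`, `sd_ms`.
#' @method glance latency_result
#' @export
glance.latency_result <- function(x, ...) {
  tibble(
    stimulus_type = attr(x, "stimulus_type"),
    n = attr(x, "n"),
    mean_ms = attr(x, "mean_ms"),
    sd_ms = attr(x, "sd_ms")
  )
}

#' Latency distribution histogram of one result
#'
#' @param object A `latency_result`.
#' @param binwidth_ms Bin width in ms (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latency_result
#' @export
autoplot.latency_result <- function(object, binwidth_ms = 1, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth_ms, boundary = 0,
                            fill = "steelblue", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(
      x = "Latency (ms)", y = "Events",
      title = sprintf("Trigger-to-display latency (%s)", attr(object, "stimulus_type"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a set of latency results
#'
#' Aggregates one or more per-type latency results into a run-level report:
#' a per-type summary table (n, mean, sd) and the per-type histogram series
#' on a common binning, ready for an overlaid distribution plot. Types with
#' zero events are flagged in the summary (`empty` column) rather than
#' dropped.
#'
#' @param results A `latency_result` or list of them.
#' @param binwidth_ms Histogram bin width in ms (default 1).
#' @return A `latency_report`: list with `summary` (tibble), `histogram`
#'   (long tibble: `stimulus_type`, `bin_left_ms`, `bin_right_ms`, `count`)
#'   and `events` (all per-event rows).
#' @export
summarize_run <- function(results, binwidth_ms = 1) {
  if (inherits(results, "latency_result")) results <- list(results)
  if (length(results) == 0L) stop_usage("`results` must contain at least one latency result")
  summary <- dplyr::bind_rows(lapply(results, glance))
  summary$empty <- summary$n == 0L
  events <- dplyr::bind_rows(lapply(results, tidy))
  histogram <- if (nrow(events) > 0L) {
    lo <- floor(min(events$latency_ms) / binwidth_ms) * binwidth_ms
    hi <- ceiling(max(events$latency_ms) / binwidth_ms) * binwidth_ms
    if (hi <= lo) hi <- lo + binwidth_ms
    breaks <- seq(lo, hi, by = binwidth_ms)
    events |>
      dplyr::group_by(.data$stimulus_type) |>
      dplyr::reframe({
        h <- graphics::hist(.data$latency_ms, breaks = breaks, plot = FALSE,
                            right = FALSE, include.lowest = TRUE)
        tibble(
          bin_left_ms = head(h$breaks, -1),
          bin_right_ms = tail(h$breaks, -1),
          count = as.integer(h$counts)
        )
      })
  } else {
    tibble(stimulus_type = character(), bin_left_ms = numeric(),
           bin_right_ms = numeric(), count = integer())
  }
  structure(
    list(summary = summary, histogram = histogram, events = events,
         binwidth_ms = binwidth_ms),
    class = "latency_report"
  )
}

#' @export
print.latency_report <- function(x, ...) {
  cat("<latency_report>\n")
  print(x$summary)
  invisible(x)
}

#' Overlaid latency distributions of a run
#'
#' Mirrors the usual way such runs are reported: one semi-transparent
#' histogram per stimulus type on a shared latency axis.
#'
#' @param object A `latency_report` from [summarize_run()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latency_report
#' @export
autoplot.latency_report <- function(object, ...) {
  ggplot2::ggplot(
    object$events,
    ggplot2::aes(x = .data$latency_ms, fill = .data$stimulus_type)
  ) +
    ggplot2::geom_histogram(
      binwidth = object$binwidth_ms, boundary = 0,
      position = "identity", alpha = 0.55, colour = NA
    ) +
    ggplot2::labs(x = "Latency (ms)", y = "Events", fill = "Stimulus") +
    ggplot2::theme_minimal()
}
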