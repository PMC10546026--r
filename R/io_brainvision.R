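#' Read a BrainVision recording triplet
#'
#' Parses a BrainVision Core Data Format 1.0 triplet (`.vhdr` text header,
#' `.vmrk` marker list, `.eeg` binary samples), extracts one channel as a
#' [photodiode_recording()] and the markers as a tibble. Supported binary
#' formats are `INT_16`, `INT_32` and `IEEE_FLOAT_32`; supported orientations
#' are `MULTIPLEXED` and `VECTORIZED`. Samples are scaled by the per-channel
#' resolution declared in the header; the sampling rate is derived from the
#' header's `SamplingInterval` (microseconds). BrainVision marker positions
#' are 1-based sample numbers and are converted to seconds as
#' `(pos - 1) / fs`, so a marker on the first sample is at 0 s.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @param channel Name of the channel to extract (e.g. the photodiode AUX
#'   channel).
#' @param strict_labels If `TRUE`, stimulus marker labels are restricted to
#'   `S1`/`S2`/`S7`/`S8`.
#' @return A list with elements `recording` (a `photodiode_recording`) and
#'   `markers` (a tibble with columns `type`, `label`, `onset_s`; all markers
#'   are kept, in file order for equal onsets).
#' @examples
#' cfg <- synthetic_config("led", n_white = 3, n_black = 3, seed = 1)
#' sim <- simulate_photodiode(cfg)
#' paths <- write_fixture(sim$recording, sim$markers, tempdir(), "example")
#' rec <- read_brainvision(paths$vhdr, channel = "PHOTO")
#' rec$recording
#' @export
read_brainvision <- function(header_path, channel, strict_labels = FALSE) {
  if (!file.exists(header_path)) {
    stop_data(sprintf("header file not found: %s", header_path))
  }
  hdr <- parse_vhdr(header_path)
  base_dir <- dirname(header_path)
  eeg_path <- file.path(base_dir, hdr$data_file)
  vmrk_path <- file.path(base_dir, hdr$marker_file)
  if (!file.exists(eeg_path)) {
    stop_data(sprintf("data file referenced by header is missing: %s", eeg_path))
  }
  if (!file.exists(vmrk_path)) {
    stop_data(sprintf("marker file referenced by header is missing: %s", vmrk_path))
  }

  ch_idx <- match(channel, hdr$channels$name)
  if (is.na(ch_idx)) {
    stop_data(sprintf(
      "channel '%s' not found; available channels: %s",
      channel, paste(hdr$channels$name, collapse = ", ")
    ))
  }

  dat <- read_eeg_binary(eeg_path, hdr)
  samples <- dat[, ch_idx] * hdr$channels$resolution[ch_idx]
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_data("non-finite samples in channel after scaling; refusing to load")
  }

  markers <- read_vmrk(vmrk_path, fs = hdr$fs, strict = strict_labels)

  list(
    recording = photodiode_recording(samples,
      fs = hdr$fs,
      channel_name = channel, t0 = 0
    ),
    markers = markers
  )
}

# INI-style header parser. Sections are [Name]; entries Key=Value; comments
# start with ';'. Returns fs, file references, binary layout and channel table.
parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  section <- ""
  common <- list()
  binary <- list()
  ch_names <- character()
  ch_res <- numeric()
  for (ln in lines) {
    ln <- sub("^\ufeff", "", ln)
    if (grepl("^\\s*;", ln) || !nzchar(trimws(ln))) next
    sec <- regmatches(ln, regexec("^\\s*\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(sec) == 2L) {
      section <- tolower(sec[2])
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- trimws(kv[2])
    val <- trimws(kv[3])
    if (section == "common infos") {
      common[[tolower(key)]] <- val
    } else if (section == "binary infos") {
      binary[[tolower(key)]] <- val
    } else if (section == "channel infos" && grepl("^Ch[0-9]+$", key)) {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      ch_names <- c(ch_names, bv_unescape(parts[1]))
      res <- suppressWarnings(as.numeric(parts[3]))
      ch_res <- c(ch_res, if (length(parts) < 3L || is.na(res)) 1 else res)
    }
  }
  fmt <- toupper(common[["dataformat"]] %||% "BINARY")
  if (fmt != "BINARY") {
    stop_data(sprintf("unsupported DataFormat '%s' (only BINARY is supported)", fmt))
  }
  bin_fmt <- toupper(binary[["binaryformat"]] %||% "")
  if (!bin_fmt %in% c("INT_16", "INT_32", "IEEE_FLOAT_32")) {
    stop_data(sprintf(
      "unsupported BinaryFormat '%s' (supported: INT_16, INT_32, IEEE_FLOAT_32)",
      bin_fmt
    ))
  }
  orientation <- toupper(common[["dataorientation"]] %||% "MULTIPLEXED")
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED")) {
    stop_data(sprintf("unsupported DataOrientation '%s'", orientation))
  }
  n_chan <- as.integer(common[["numberofchannels"]] %||% length(ch_names))
  interval_us <- as.numeric(common[["samplinginterval"]])
  if (is.na(interval_us) || interval_us <= 0) {
    stop_data("header is missing a valid SamplingInterval")
  }
  if (length(ch_names) != n_chan) {
    stop_data(sprintf(
      "header declares %d channels but lists %d in [Channel Infos]",
      n_chan, length(ch_names)
    ))
  }
  list(
    data_file = common[["datafile"]],
    marker_file = common[["markerfile"]],
    fs = 1e6 / interval_us,
    n_chan = n_chan,
    binary_format = bin_fmt,
    orientation = orientation,
    channels = tibble(name = ch_names, resolution = ch_res)
  )
}

bv_unescape <- function(x) gsub("\\1", ",", x, fixed = TRUE)
bv_escape <- function(x) gsub(",", "\\1", x, fixed = TRUE)

read_eeg_binary <- function(path, hdr) {
  n_bytes <- file.size(path)
  size <- switch(hdr$binary_format,
    INT_16 = 2L,
    INT_32 = 4L,
    IEEE_FLOAT_32 = 4L
  )
  what <- if (hdr$binary_format == "IEEE_FLOAT_32") "numeric" else "integer"
  n_values <- n_bytes %/% size
  if (n_values %% hdr$n_chan != 0L) {
    stop_data("binary data size is not a multiple of the channel count")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = what, n = n_values, size = size, endian = "little")
  n_samp <- n_values %/% hdr$n_chan
  if (hdr$orientation == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_samp, ncol = hdr$n_chan, byrow = TRUE)
  } else {
    matrix(raw_vals, nrow = n_samp, ncol = hdr$n_chan, byrow = FALSE)
  }
}

read_vmrk <- function(path, fs, strict = FALSE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  mk <- regmatches(lines, regexec("^Mk[0-9]+=([^,]*),([^,]*),([0-9]+)", lines))
  mk <- mk[lengths(mk) == 4L]
  if (length(mk) == 0L) {
    return(marker_table(character(), numeric(), type = character(), strict = strict))
  }
  type <- vapply(mk, function(m) m[2], character(1))
  label <- vapply(mk, function(m) bv_unescape(m[3]), character(1))
  pos <- vapply(mk, function(m) as.numeric(m[4]), numeric(1))
  marker_table(label, (pos - 1) / fs, type = type, strict = strict)
}

# latency CSV ----------------------------------------------------------------

#' Write a latency table to CSV
#'
#' Writes one row per event (`stimulus_type, event_index, tS_s, tD_s,
#' latency_ms`, all times with six decimals) followed by a trailing summary
#' block (`stimulus_type, n, mean_ms, sd_ms`) separated by a `# summary`
#' line. [read_latency_table()] reads the file back bit-exactly at the
#' printed precision.
#'
#' @param result A [compute_latencies()] result (or a list of them; all are
#'   written into one file).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_latency_table <- function(result, path) {
  results <- if (inherits(result, "latency_result")) list(result) else result
  total <- sum(vapply(results, nrow, integer(1)))
  if (length(results) == 0L || total == 0L) {
    stop_data("refusing to write an empty latency table")
  }
  rows <- unlist(lapply(results, function(r) {
    sprintf(
      "%s,%d,%.6f,%.6f,%.6f",
      r$stimulus_type, r$event_index, r$tS_s, r$tD_s, r$latency_ms
    )
  }))
  summaries <- vapply(results, function(r) {
    g <- glance(r)
    sprintf("%s,%d,%.6f,%.6f", g$stimulus_type, g$n, g$mean_ms, g$sd_ms)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "stimulus_type,event_index,tS_s,tD_s,latency_ms",
    rows,
    "# summary",
    "stimulus_type,n,mean_ms,sd_ms",
    summaries
  ), con)
  invisible(path)
}

#' Read back a latency table written by [write_latency_table()]
#'
#' @param path Path to the CSV file.
#' @return A list with `events` (tibble of per-event rows) and `summary`
#'   (tibble of per-type n/mean/sd).
#' @export
read_latency_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  split_at <- match("# summary", lines)
  if (is.na(split_at)) stop_data("not a latency table: missing '# summary' block")
  events <- utils::read.csv(text = lines[seq_len(split_at - 1)], stringsAsFactors = FALSE)
  summary <- utils::read.csv(text = lines[(split_at + 1):length(lines)], stringsAsFactors = FALSE)
  list(events = as_tibble(events), summary = as_tibble(summary))
}
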