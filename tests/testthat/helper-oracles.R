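# Independent brute-force oracles: literal, element-by-element transcriptions
# of the detection steps, kept free of the vectorised implementation paths.

bf_rising_edges <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(integer())
  posdiff <- numeric(n)
  posdiff[1] <- 0 # leading pad
  if (n >= 2L) {
    for (i in 2:n) posdiff[i] <- bits[i] - bits[i - 1]
  }
  which(posdiff == 1)
}

bf_group_onsets <- function(edges, gap) {
  if (length(edges) == 0L) return(integer())
  onsets <- numeric(length(edges))
  onsets[1] <- edges[1]
  if (length(edges) >= 2L) {
    for (n in 2:length(edges)) {
      if (edges[n] > edges[n - 1] + gap) onsets[n] <- edges[n]
    }
  }
  as.integer(onsets[onsets != 0]) # prune zero placeholders
}

bf_find_peaks <- function(x) {
  res <- integer()
  n <- length(x)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i]) res <- c(res, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

# literal 4-index run rule: test heights at n, n+1, n+2 and n+w-1 only,
# marking every peak of a qualifying window
bf_small_peak_mask_literal <- function(heights, samples, n_samples, thd2, w = 11L) {
  mask <- integer(n_samples)
  k <- length(heights)
  if (k < w) return(mask)
  marked <- logical(k)
  for (n in 1:(k - w + 1L)) {
    if (heights[n] < thd2 && heights[n + 1L] < thd2 &&
        heights[n + 2L] < thd2 && heights[n + w - 1L] < thd2) {
      marked[n:(n + w - 1L)] <- TRUE
    }
  }
  mask[samples[marked]] <- 1L
  mask
}

make_recording <- function(x, fs = 500) photodiode_recording(x, fs = fs)

led_params <- function(...) detection_params("led", thd1 = 60000, thd2 = 20000, ...)
hmd_params <- function(...) detection_params("hmd", thd1 = 180000, thd2 = 8000, ...)

truth_of <- function(sim, type) sim$truth[sim$truth$stimulus_type == type, ]
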