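---
title: "Measuring trigger-to-display latency from a photodiode channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trigger-to-display latency from a photodiode channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolag)
```

## The problem

ERP analysis time-locks EEG epochs to trigger markers that the stimulus
software injects into the recording at the moment it *issues* a stimulus.
The stimulus does not appear on the display at that moment: rendering,
transmission and panel refresh add tens of milliseconds, and the delay
differs between display technologies. If epochs are not shifted by this
trigger-to-display latency, components get misassigned. The standard way to
measure it is to tape a photodiode to the display, record it as an auxiliary
amplifier channel alongside the EEG, flash full-screen white and black
stimuli, and compare the marker times with the moments the light level
actually changes.

`photolag` implements that comparison for the two display families that
produce qualitatively different photodiode waveforms:

* **LED screen** (constantly lit panel): the trace sits at a neutral grey
  level, rises above it for the duration of a white stimulus and drops below
  it for a black stimulus — a step-like waveform.
* **HMD** (head-mounted display): the panel is dark between refreshes, so
  the trace is a continuous train of narrow peaks at the refresh rate; the
  *heights* of the peaks jump with the displayed colour. White stimuli are
  tall peaks; black stimuli are stretches of unusually small peaks.

## Detection model

For event type $j \in \{\text{white}, \text{black}\}$ with sent trigger
times $t^{S}_{j,k}$ and detected display onsets $t^{D}_{j,k}$, the per-event
latency is

$$L_{j,k} = (t^{D}_{j,k} - t^{S}_{j,k}) \cdot 1000 \ \text{ms},$$

summarised by the arithmetic mean and the sample standard deviation
($n-1$ denominator) over events, and by a histogram of the distribution.

Onset detection is a three-stage pipeline on the raw trace $x_i$
(1-based sample index $i$, sampling rate $f_s$, sample $i$ at time
$(i-1)/f_s$):

1. **Threshold mask.** White: $m_i = \mathbf{1}[x_i \ge \theta_1]$.
   Black (LED): $m_i = \mathbf{1}[x_i \le \theta_2]$. Both comparisons are
   inclusive.
2. **Rising edges.** The first difference of $m$ is padded with a leading
   zero and every $+1$ position is an edge. The pad means sample 1 can never
   be an edge: a stimulus already in progress at recording start has no
   measurable onset.
3. **Gap grouping.** Edges are grouped with the minimum index gap
   $g = \mathrm{round}(f_s \cdot L_\text{isi})$, where $L_\text{isi}$ is the
   lower bound of the inter-stimulus interval (1 s by default). The first
   edge is kept; each later edge is kept iff it exceeds the *immediately
   preceding edge* by more than $g$.

For the HMD, white onsets use exactly the same pipeline (the tall refresh
peaks cross $\theta_1$; the result is bit-identical to the LED path run with
the HMD thresholds). Black onsets first locate all strict local maxima of
the trace (plateaus contribute their first sample; no prominence or width
filtering), then build a mask that is 1 at the sample positions of every
peak belonging to a run of `hmd_run_window` (default 11) consecutive peaks
whose heights are all strictly below $\theta_2$, and 0 everywhere else —
in particular at every non-peak sample. That mask feeds the same edge and
grouping stages.

Thresholds $\theta_1$ and $\theta_2$ are deliberately mandatory inputs: they
depend on photodiode placement, display brightness and amplifier gain, and
the intended workflow is to read them off a plot of the raw trace.
`suggest_thresholds()` offers a percentile-based starting point (midpoints
between the 99.9th/0.1th percentiles and the median) but is never applied
silently.

### Design choices where the procedure was ambiguous

Several details of the published description of this family of algorithms
are internally inconsistent; the package fixes one reading as its default
and keeps the alternatives selectable:

* **Black-stimulus comparator (LED).** The black mask is defined here as
  $x_i \le \theta_2$, because $\theta_2$ is described as a level the trace
  *drops below* during black stimuli. The opposite comparator
  ($x_i \ge \theta_2$) is reachable via
  `detection_params(led_black_polarity = "above")`; as the unit tests
  demonstrate, it marks everything *except* the black stretch and therefore
  detects black offsets rather than onsets, which is why it is not the
  default.
* **Grouping reference.** The grouping comparison is made against the
  previous edge, transcribed literally, not against the last *kept* onset.
  The two differ only for edge trains whose inter-edge gaps hover around the
  index gap; a property test pins the literal behaviour.
* **Loop extent.** The grouping loop runs over every edge after the first.
* **HMD run rule.** The printed run condition tests peak heights at window
  positions 1, 2, 3 and 11 only. The default here requires *all* 11
  consecutive heights below $\theta_2$ — the strictest consistent reading of
  what looks like an elided enumeration. The 4-index variant is available as
  `detection_params(hmd_rule = "literal")`; on traces whose 11-peak windows
  are homogeneous the two rules produce identical masks (property-tested),
  and they differ exactly when the interior of a window is heterogeneous.
* **Run marking.** Every peak of a qualifying run is marked, not only the
  run's first peak, so the rising-edge stage finds the run's first marked
  sample as the onset.
* **Back-correction.** The black-onset time is *not* corrected for any
  run-detection delay; with the phase-anchored synthetic generator (below)
  that delay is exactly zero, which a regression test documents.
* **No sub-sample interpolation.** Onsets are reported on the sample grid;
  at the default 500 Hz this bounds the timing quantisation at 2 ms.

### Pairing and statistics

`pair_events()` pairs triggers with detections. The default `strict` policy
requires equal counts and pairs index-by-index, erroring on any negative
implied latency — appropriate for clean protocol-conforming runs where every
stimulus is detected exactly once. `nearest_following` pairs each trigger
with the earliest unconsumed detection within `(sent, sent + max_lag_s]` and
reports unmatched events; it is the right choice when per-event latency
jitter or noise can make an occasional event undetectable. The jitter case
is not hypothetical: with latency jitter $\sigma$, the gap between two
same-type onsets that are adjacent in the schedule can fall below
$L_\text{isi}$ plus the grouping margin with probability on the order of
$10^{-3}$ per pair, in which case the literal grouping rule drops the second
event. The jittered validation runs and the acceptance script therefore use
`nearest_following`; the clean (jitter-free) runs use `strict`.

The standard deviation uses the sample ($n-1$) convention. Histograms use
1-ms bins by default, configurable (`binwidth_ms`); the run-level report
bins all types on a common grid aligned to multiples of the bin width.

## The synthetic generator

`synthetic_config()` / `simulate_photodiode()` emulate the measurement
protocol so the full pipeline — including the BrainVision file round trip —
is testable without hardware. The defaults are the study conditions and are
fixed once:

| parameter | default | meaning |
|---|---|---|
| `fs` | 500 Hz | amplifier sampling rate (real readers take it from the file header) |
| `n_white`, `n_black` | 100, 100 | stimuli per type, randomly interleaved |
| `isi_range_s` | 1.0–1.5 s | inter-stimulus interval, **offset-to-onset**, uniform |
| `stim_dur_s` | 0.3 s | stimulus duration |
| `refresh_hz` | 100 (LED) / 90 (HMD) | display refresh rate |
| `levels` | LED 40000/75000/5000, HMD 50000/200000/5000 | neutral/white/black amplitudes, placed around the canonical thresholds 60000/20000 (LED) and 180000/8000 (HMD) |
| `latency_ms` | LED (121.98, 121.66), HMD (82.80, 69.82) | injected mean latency (white, black), calibrated to the latency distributions this class of hardware produces |
| `latency_jitter_ms` | LED (8.71, 8.80), HMD (7.63, 5.52) | per-event latency SD |
| `noise_sd` | 0 | additive Gaussian noise |

ISI is taken in its classical psychophysics sense — the gap from stimulus
*offset* to the next *onset* — so consecutive triggers are
`stim_dur_s + isi` apart. This is also the only reading under which the
grouping stage, whose index gap equals `round(fs * lisi)`, retains every
same-type onset with certainty on clean data: onset-to-onset gaps of
same-type neighbours are then at least `lisi + stim_dur_s`, comfortably
above the gap, whereas an onset-to-onset reading of the ISI would make the
pipeline drop same-type neighbours by construction.

Per-event latency is `latency_ms + Normal(0, latency_jitter_ms)`, truncated
at zero — a Gaussian matches the unimodal single-display latency spreads
such setups produce. Trigger times are snapped to the sample grid (they are
stored in the marker file as sample positions), display onsets are snapped
to the nearest sample, and the ground-truth table records the *snapped*
times, so on clean data detection recovers every latency to within one
sample.

Waveforms: the LED trace ramps through a single half-way sample into a
plateau at the stimulus level for `stim_dur_s`, then ramps back — the
threshold crossing, not the ramp shape, is what detection consumes. The HMD
trace is zero except for single-sample peaks spaced
`round(fs / refresh_hz)` samples apart (at the defaults, 90 Hz sampled at
500 Hz aliases to a 6-sample spacing, i.e. 83.3 Hz — the documented
quantisation of peak positions to the sample grid); peak heights take the
current regime's level.

Two deliberate idealisations, and what they imply for the tests:

* **Phase anchoring.** The peak train restarts its phase at every regime
  boundary, so one peak sits exactly on each display onset (and a refresh
  peak that would touch the next onset's sample is dropped, as a skipped
  frame, so that onset peak remains a strict local maximum). Real displays
  refresh asynchronously with respect to stimulus onsets, which adds a
  uniform 0–1 refresh-period delay the generator does not emulate; passing
  parameter-recovery tests therefore validate the detection logic, not the
  absence of refresh quantisation in real hardware.
* **Clean baseline.** With `noise_sd = 0` the only local maxima are refresh
  peaks. Moderate noise is supported (a configuration error rejects any
  `noise_sd` above 10% of the smallest level-to-threshold margin, which
  would break the one-crossing-per-stimulus guarantee), but real photodiode
  artefacts — drift, mains hum, ambient-light leakage — are out of scope;
  on real data the thresholds absorb them or they do not.

`write_fixture()` emits the triplet as IEEE_FLOAT_32 BrainVision files that
both this package's reader and standard third-party readers load (one test
cross-checks samples and marker times against the Python MNE reader).

## Validation problem sizes

The shipped validation suite runs entirely on synthetic data: exhaustive
equivalence of the edge/grouping stages against a brute-force interpreter on
1000 random masks up to 10 000 samples; per-event latency recovery at
100 events per type for both displays (exact to one sample at zero jitter;
mean within $3\sigma/\sqrt{n}$ and SD within 15% at 7 ms jitter); count
conservation over 20 seeds; amplitude-scale equivariance; and the file
round trip. The distribution-report check uses 1000 events per type to keep
the Monte-Carlo error of the modal 5-ms bin small; with the calibrated LED
defaults the modal bin is 120–125 ms. The acceptance script pools three
replicate 200-event sessions per display for the same reason. Reproducing
the published summary statistics from the *original* recordings requires
fetching the separately deposited datasets; the corresponding check fails
with instructions when they are absent.

## Known limitations

* Thresholds are manual by design; no adaptive or learned thresholding.
* No sub-sample onset interpolation, so latency resolution is `1000/fs` ms.
* The HMD's two eyepiece panels are treated as one display; per-lens
  latency averaging is not implemented.
* Onsets only: stimulus *offsets* are not measured (though the literal LED
  black polarity incidentally detects them).
* The reader covers BrainVision Core Format 1.0 binary data (INT_16,
  INT_32, IEEE_FLOAT_32; multiplexed or vectorized); EDF/GDF/XDF are out of
  scope.
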