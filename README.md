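# photolag

Trigger-to-display latency estimation from photodiode recordings.

In ERP experiments the stimulus software injects trigger markers (e.g.
`"S1"` for a white flash, `"S2"` for a black one) into the EEG recording at
the moment it *issues* each stimulus. The stimulus reaches the screen tens
of milliseconds later, and the delay depends on the display: epochs
time-locked to the raw markers are systematically misaligned unless they are
shifted by the measured trigger-to-display latency. The standard measurement
tapes a photodiode to the display, records it as an auxiliary amplifier
channel, flashes white and black full-screen stimuli, and compares marker
times with the moments the light level actually changes.

`photolag` is for EEG/BCI researchers who need that number — especially for
VR work where an LED screen and a head-mounted display (HMD) behave
differently. For each stimulus type with sent trigger times `tS` and
detected display onsets `tD`, it computes the per-event latencies

```
Lat[k] = (tD[k] - tS[k]) * 1000   (ms)
```

and reports their mean, sample SD and distribution. Onsets are detected
from the raw trace by an inclusive threshold mask (white: `x >= ThD1`;
black: `x <= ThD2`), padded first-difference rising-edge detection, and
grouping of edges closer than `round(fs * Lisi)` samples (`Lisi` = lower
inter-stimulus-interval bound, default 1 s). An HMD, whose photodiode trace
is a refresh-rate peak train rather than a step waveform, uses the same
pipeline for white stimuli and, for black stimuli, a mask marking runs of
11 consecutive refresh peaks whose heights fall below `ThD2`.

The package reads BrainVision triplets (`.vhdr`/`.vmrk`/`.eeg`; INT_16,
INT_32, IEEE_FLOAT_32; multiplexed or vectorized), writes latency tables as
CSV, plots distributions via `autoplot()`, and ships a synthetic
photodiode-signal generator with known injected latencies so the whole
pipeline is testable without hardware. A thin command-line front end
(`inst/cli/photolag.R`: `detect`, `simulate`, `report`) wraps the same
functions.

## Worked example

Simulate an HMD session under the default study conditions (100 white + 100
black stimuli, 0.3 s duration, offset-to-onset ISI uniform in 1.0–1.5 s,
90 Hz refresh sampled at 500 Hz), then measure the white-stimulus latency:

```r
library(photolag)

cfg    <- synthetic_config("hmd", seed = 42)
sim    <- simulate_photodiode(cfg)
params <- detection_params("hmd", thd1 = 180000, thd2 = 8000)

sim$recording
#> <photodiode_recording> channel PHOTO: 155349 samples @ 500 Hz (310.7 s), t0 = 0 s

white <- detect_onsets(sim$recording, params, "white")
sent  <- marker_onsets(sim$markers, "S1")
pairs <- pair_events(sent, white$time_s, policy = "nearest_following")
res   <- compute_latencies(sent[pairs$sent_index],
                           white$time_s[pairs$detected_index], "S1")
glance(res)
#> # A tibble: 1 × 4
#>   stimulus_type     n mean_ms sd_ms
#>   <chr>         <int>   <dbl> <dbl>
#> 1 S1              100    82.3  7.65
```

The generator injected a mean white latency of 82.80 ms with 7.63 ms
per-event jitter; the pipeline recovers 82.28 ± 7.65 ms from the waveform
alone, i.e. within the Monte-Carlo error of 100 events and the 2 ms
sample-grid quantisation. `tidy(res)` gives the per-event table,
`autoplot(summarize_run(list(...)))` the overlaid per-type distribution
plot, and `write_latency_table(res, "latencies.csv")` a fixed-precision
CSV with a trailing per-type summary block.

The same analysis end-to-end from files:

```r
run_simulate("hmd", outdir = "run1", seed = 42)
run_detect("run1/hmd_synthetic.vhdr", channel = "PHOTO", mode = "hmd",
           thd1 = 180000, thd2 = 8000, outdir = "run1")
```

or from a shell:

```sh
Rscript inst/cli/photolag.R simulate --mode hmd --outdir run1 --seed 42
Rscript inst/cli/photolag.R detect --vhdr run1/hmd_synthetic.vhdr \
    --channel PHOTO --mode hmd --thd1 180000 --thd2 8000 --outdir run1
```

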