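# sleepperiods

Rule-based detection of NREM and REM sleep periods from overnight
polysomnography, with a time-matched multitaper EEG spectrogram.

## What it does, and for whom

A polysomnography (PSG) study yields a *hypnogram* — one sleep stage
(W, N1, N2, N3 or R) per 30-second scoring epoch — alongside multichannel
EEG. Sleep clinicians and researchers work with the night's *periods*: runs
of epochs dominated by NREM sleep (NREMPs) or REM sleep (REMPs), whose
number, order and durations differ between age groups and between healthy
sleepers and patients with sleep disorders. Delineating those periods by
hand is slow and irreproducible; `sleepperiods` does it with an explicit
rule set and pairs the result with a per-epoch spectral view of the EEG on
the same time axis.

The rule engine scans the hypnogram from lights-off to lights-on
(half-open, 0-based epoch intervals throughout):

* an NREMP opens at the first N1/N2 epoch; every NREMP before the first
  REMP ends at the first R epoch; thereafter periods end at an
  opposite-family run of ≥ 5 min;
* a wake run of ≥ 5 min (10 epochs) ends the current period, the wake is
  excluded, and the next sleep epoch opens a new period — so two
  consecutive NREMPs (or REMPs) are legitimate output, and "sleep cycles"
  are deliberately not modelled as objects;
* NREMPs shorter than 15 min (wake-excluded) and non-first REMPs shorter
  than 5 min are merged into adjacent periods; the first REMP has no
  minimum;
* an NREMP longer than 120 min is split at an *arousal* point (first N3 run
  immediately preceded by > 1 min of wake; cut at the N3) or a *lightening
  of sleep* point (first N1 run of > 3 min immediately followed by N3; cut
  at the N1 run start), with candidate selection under caller control; REM
  periods are never split.

The spectral side computes, for each retained epoch and channel, the average
of 7 Slepian-tapered periodograms (time-bandwidth 4) on a fixed 901-point
grid — 0 to 45 Hz in 0.05 Hz steps — giving an epochs × 901 × channels
power array exactly aligned with the hypnogram.

Inputs are EDF/EDF+ files with embedded stage annotations, or plain-text
two-column annotation files (epoch number, stage). Outputs are the
hypnogram + spectrogram figure (JPEG/PNG/SVG), stage and period listings
(TSV), and the power matrix as NumPy-compatible `.npy` files. A synthetic
generator (template hypnograms with known ground truth, band-structured
EEG, EDF+ writer) makes the whole pipeline testable without clinical data.

## Worked example

```r
library(sleepperiods)

# a synthetic night with known structure: settling wake, an NREMP going
# into deep sleep, a REMP, and a second NREMP
tpl <- period_template(
  template_block("WAKE_GAP", rep("W", 12)),
  template_block("NREMP", c(rep("N2", 25), rep("N3", 15))),
  template_block("REMP", rep("R", 14)),
  template_block("NREMP", rep("N2", 35)))
g <- generate_hypnogram(tpl)
rec <- generate_eeg(g$hypnogram, fs = 200, n_channels = 2, seed = 42)
write_recording(rec, g$hypnogram, "night.edf")

run <- run_pipeline(run_config(input = "night.edf", outdir = "night_out",
                               channels = c("F3", "F4")))
run$detection$periods
#> <sleep_periods> 3 period(s)
#>   kind start_epoch end_epoch ordinal label duration_min
#>  NREMP          12        52       1   NC1         20.0
#>   REMP          52        66       1   RC1          7.0
#>  NREMP          66       101       2   NC2         17.5
```

The leading 12 wake epochs belong to no period; the first NREMP spans
epochs 12–51 (20 min of sleep), the first REMP follows with no minimum
duration applied, and the labels `NC1/RC1/NC2` match the shading in
`night_out/figure.jpeg`. The spectrogram is epoch-aligned, so stage-specific
band power falls out directly — mean delta-band (0.5–4 Hz) power per stage:

```r
spec <- run$spectrogram
dim(spec$power)
#> [1] 101 901   2
delta <- rowMeans(spec$power[, spec$freqs_hz >= 0.5 & spec$freqs_hz < 4, 1])
round(tapply(delta, run$detection$hypnogram$stages, mean), 1)
#>    N2    N3     R     W
#>   0.3 129.9   0.3   0.3
```

The N3 epochs carry ~130 µV²/Hz of delta power (the generator's 30 µV delta
component) against a flat ~0.3 µV²/Hz noise floor elsewhere — deep sleep is
visible at a glance in the figure's heatmap.

The same pipeline runs from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sleepperiods.R", package = "sleepperiods"))') \
    run night.edf --outdir night_out --channels F3,F4
```

with `simulate` and `cutpoints` subcommands for fixture generation and for
listing the split options of an over-long NREMP (`--cut N` then applies
one non-interactively).

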