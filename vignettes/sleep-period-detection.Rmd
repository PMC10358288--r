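---
title: "Sleep-period detection and time-matched spectrograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-period detection and time-matched spectrograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepperiods)
```

## The problem

An overnight polysomnography (PSG) study produces two intertwined records:
multichannel EEG voltages, and a hypnogram — a sequence of 30-second scoring
epochs each annotated by a technician with one of five stages: wake (W), the
three NREM stages (N1, N2, N3) and REM (R). Sleep architecture alternates
between periods dominated by NREM sleep (NREMPs) and periods dominated by REM
sleep (REMPs); the number, order and duration of these periods carry
clinically useful information, and reading them off a raw hypnogram by eye is
error-prone and irreproducible.

`sleepperiods` segments a hypnogram into NREMPs and REMPs with an explicit
rule set, and pairs the result with a multitaper EEG spectrogram computed
per scoring epoch, so both views share one time axis. Everything downstream —
figure, listings, exported power matrix — derives from those two objects.

## The rule set

All indices are 0-based and all intervals half-open `[start, end)`. Rules
stated in minutes are converted to epoch counts against the epoch length
`L` seconds: a run of `k` epochs satisfies an "at least `m` minutes" rule iff
`k * L >= 60 m`, and an "exceeding `m` minutes" rule iff `k * L > 60 m`. At
the default `L = 30` the thresholds are 10 epochs (5 min), 3 epochs
(exceeding 1 min) and 7 epochs (exceeding 3 min).

**Scan** (`scan_periods()`). The scan runs from the first N1/N2 epoch; wake
and REM epochs before it are ignored, as is wake after the last period. A
leading run of N3 with no prior N1/N2 also opens an NREMP — the onset
definition names only N1/N2, so this is logged as atypical rather than
rejected. From there:

* Every NREMP that precedes the first REMP ends at the first R epoch
  encountered, which opens that REMP. We apply this to *every* NREMP before
  the first REMP, not just the chronologically first NREMP, because wake
  breaks can split the pre-REM part of the night into several NREMPs and the
  rule's intent — the night's first R epoch starts the first REMP — should
  not depend on that.
* Once a REMP has occurred, periods end only at an opposite-family run of at
  least 5 minutes (`transition_run_min`): an NREMP ends at the start of the
  first qualifying R run, a REMP at the start of the first qualifying
  N1/N2/N3 run. Shorter opposite-family runs stay inside the period.
* A wake run of at least 5 minutes (`wake_break_min`) ends the current
  period at its last sleep epoch. The wake epochs belong to no period; the
  next non-wake epoch opens a new period whose type follows that epoch's
  stage (R opens a REMP, anything else an NREMP — the rule text only says "a
  new sleep period begins", so the type must come from the data). Wake runs
  below the threshold stay inside the period but never count toward its
  duration, and a period never begins or ends on a wake epoch.

**Duration minima** (`merge_short_periods()`). Period durations are
wake-excluded: non-W epochs in the interval times `L / 60`. An NREMP shorter
than 15 minutes, or a REMP other than the first shorter than 5 minutes, is
absorbed into the immediately preceding period when no wake break intervenes,
otherwise into the following adjacent period, otherwise — isolated by wake
breaks on both sides — dropped with a log entry. The preceding-first order is
our choice; the rule text says only "merges it into the adjacent respective
sleep periods". After each absorption, same-kind adjacent periods coalesce,
and the whole step iterates to a fixpoint (each step removes a period, so at
most as many iterations as raw periods). The first REMP — lowest start among
current REMPs — is exempt from the REMP minimum.

**Splitting over-long NREMPs** (`find_cut_candidates()`, `apply_cut()`). An
NREMP whose wake-excluded duration exceeds 120 minutes is split at one of
two kinds of cut points, listed in epoch order:

* *arousal*: the first epoch of an N3 run immediately preceded by a wake run
  exceeding 1 minute; the cut lands on the N3 epoch and the wake run is
  trimmed out when the cut is applied;
* *lightening of sleep*: the first epoch of an N1 run exceeding 3 minutes
  that is immediately followed by N3; the cut lands on the start of the N1
  run.

Candidates that would leave either fragment under the 15-minute NREMP
minimum are suppressed (and logged): splitting must not create a period the
merge step would immediately have to undo. Several candidates can coexist;
`detect_periods()` takes the earliest by default, and the caller (or the
CLI's repeatable `--cut` flag) can select by index. An over-long NREMP with
no viable candidate is kept whole with a warning. REM periods are never
split. We implement the cut positions exactly as described above; a
coarser summary elsewhere ("split at the arousal or lightening point") is
superseded by this more precise placement.

Two plausible-sounding global invariants deliberately hold only in
restricted form. *Idempotence* — re-running detection after deleting all
non-period epochs — fails whenever two consecutive periods share a kind,
because deleting the separating wake fuses them into a single run; it holds,
and is tested, on alternating-kind nights. *Monotonicity in the wake
threshold* — more tolerance, fewer periods — is structurally true for the
raw scan and is tested there; after merging it can be violated, since two
short fragments that are each dropped at a low threshold can survive as one
period at a higher one.

## Epoch handling and filters

`epoch_and_align()` intersects the signal and the hypnogram: trailing
partial signal epochs, epochs with signal but no annotation, and epochs with
annotation but no signal are all removed from *both* streams, so detection
and spectral analysis always see identical epochs. Annotation labels outside
the five stages must be mapped explicitly — either to a stage or to the
exclusion marker (bathroom breaks, movement time); excluded epochs are
treated exactly like unannotated ones.

Frequency filters (off by default, mirroring an "apply filters" switch) are
zero-phase: an RBJ biquad notch (default 60 Hz, Q = 30), then a band-pass
(default 0.3–45 Hz) realized as an order-8 Butterworth low-pass cascaded
with an order-2 Butterworth high-pass, each run forward-backward. The
asymmetric orders are deliberate: the 45 Hz edge needs a steep skirt (the
test suite asserts at least 20 dB attenuation of a 50 Hz tone at
`fs = 200`), while the 0.3 Hz edge sits at 0.3% of Nyquist, where
high-order recursive filters lose numerical stability; order 2 is safe there
and the passband stays flat to under 0.5 dB. Epoch-quality filters flag
epochs whose absolute amplitude exceeds 500 µV on any channel, whose
standard deviation falls below 0.1 µV on any channel (flat/disconnected
electrode), or whose annotation is in a user-supplied exclusion list.

## The multitaper spectrogram

Each retained epoch of each channel is demeaned and multiplied by `k = 7`
discrete prolate spheroidal (Slepian) tapers with time-bandwidth product
`nw = 4`; the 7 periodograms are averaged. Over a 30-s window this gives a
half-bandwidth of `nw/T ≈ 0.13` Hz with the variance reduction of 7
near-independent estimates — standard practice for sleep EEG, and
configurable. Windows coincide with scoring epochs, without overlap, so
spectrogram column `i` *is* hypnogram epoch `i` after joint filtering;
sub-epoch time resolution is out of scope.

Power is one-sided spectral density in µV²/Hz, evaluated on a fixed
inclusive grid of 901 frequencies — 0 to 45 Hz in 0.05 Hz steps, covering
the delta (<4 Hz) through gamma (>30 Hz) bands. The transform length is the
smallest multiple of `fs / 0.05` covering the epoch, so every grid frequency
falls exactly on an FFT bin and no interpolation occurs; this requires
`fs / 0.05` to be an integer, which every common PSG rate satisfies. The
export is the epochs x 901 x channels array. For display the power is
converted to dB re 1 µV²/Hz with a floor at −60 dB; zero power maps exactly
to the floor (and anything below 10^-6 µV²/Hz clamps to it).

The tapers are computed from the symmetric tridiagonal operator whose
eigenvectors are the Slepian sequences: eigenvalues by Sturm-sequence
bisection, eigenvectors by inverse iteration with tridiagonal solves, then a
modified Gram-Schmidt polish, cached per `(n, nw, k)`. The test suite checks
orthonormality to 1e-6, the eigen-equation residual to 1e-10, and the
leading taper's spectral concentration in the design band; a tone test
checks peak placement on the grid and Parseval (total one-sided power of a
unit 10 Hz sinusoid within 20% of its variance 0.5, the slack coming from
the Riemann sum over the 0.05 Hz grid and taper leakage).

## EDF input and output

EDF/EDF+ I/O is implemented directly over the format: ASCII headers, 16-bit
little-endian samples in 1-second data records, and an EDF+ annotations
signal carrying NUL-terminated time-stamped annotation lists. The reader
tolerates a truncated final record, converts `mV` channels to µV, and
linearly resamples channels recorded at a lower rate to the highest rate
among the selection (logged; PSG montages occasionally mix rates and the
alternative — refusing the file — helps nobody). Stage events are snapped to
the epoch grid when their onset is within 0.5 s of a boundary; vendor files
jitter by fractions of a second, and a hard tolerance keeps behaviour
reproducible — larger offsets are an alignment error, not a guess. Only the
standard EDF/EDF+ annotation layout is handled; vendor dialects that deviate
from it need a user-supplied text annotation file. The writer uses a ±1000 µV
physical range over the 16-bit digital range, so round-tripped samples are
exact to half a quantization step (≈0.015 µV); the round trip and the
quantization bound are tested.

## The synthetic generator

Templates (`period_template()`) assemble a night from NREMP, REMP and
WAKE_GAP blocks and return both the hypnogram and the exact period intervals
detection must recover. Validation rejects any block the rule engine would
re-segment — internal wake runs at or above the break threshold, opposite-
family runs at or above the transition threshold, R epochs in a pre-first-REMP
NREMP, durations outside the configured bounds, same-kind neighbours without
a wake gap, and transitions whose opening run is too short to fire. Synthetic
EEG (`generate_eeg()`) is a sum of stage-specific sinusoids (alpha-dominated
wake, theta in N1/REM, theta plus a 13 Hz spindle-band component in N2,
30 µV delta in N3) over seeded white Gaussian noise, phase-continuous across
epochs.

This emulates exactly what the pipeline consumes — stage-dependent band
power on a known schedule — and nothing more: no 1/f background, no spindle
or K-complex morphology, no artifacts, no inter-scorer disagreement.
Passing tests therefore demonstrate that the rules and the spectral
machinery do what they claim on well-posed input, not that the defaults are
clinically optimal for any population.

## Problem sizes and verification

The test suite cross-checks the rule engine against an independent
brute-force transcription of the rules (written as global searches over the
stage string, not a scanning automaton) on 10,000 random run-structured
stage sequences of up to 200 epochs, recovers ground truth on random valid
templates, round-trips EDF files, and verifies the multitaper core against
closed-form tone properties; the full suite runs in well under a minute.
The `scripts/acceptance.R` script recomputes the headline quantities — the
901-point frequency axis, the 10-epoch wake tolerance, the five-NREMP/
one-REMP segmentation of a wake-interrupted night, and the tone fidelity
numbers — from scratch against the installed package.

## Known limitations

* Rules target children and adults; newborn sleep architecture needs a
  different rule set entirely.
* Whether brief R epochs inside an NREMP should count toward its duration is
  genuinely ambiguous; only wake is excluded here, so they do count. Flagged
  rather than silently decided: the choice is localized in
  `period_duration()`.
* Period ordinals are numbered per kind (NC1…, RC1…), matching the figure
  labels, rather than globally.
* No automatic sleep staging: annotations are required for detection; an
  EDF without stage events yields only the spectrogram.
* Sleep cycles are intentionally not modelled as objects: consecutive
  same-kind periods are legitimate output (e.g. around long awakenings), so
  pairing NREMP+REMP into cycles is left to the analyst.
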