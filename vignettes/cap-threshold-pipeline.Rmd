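---
title: "Simulating and analysing CAP threshold-shift studies"
author: "capshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing CAP threshold-shift studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capshift)
```

## The problem

Severing the suspensory attachments of the middle-ear ossicles — in the
gerbil, the anterior mallear process (AMP) and the posterior incudal
ligament (PIL) — may or may not impair sound transmission. The standard
physiological readout is the compound action potential (CAP): the summed
auditory-nerve onset response recorded at the round window. An ear's CAP
threshold at a given frequency is the lowest stimulus level that still
evokes a detectable CAP; a threshold elevation under air conduction with
stable bone-conduction thresholds indicates a conductive (middle-ear)
loss rather than cochlear damage.

`capshift` implements the full computational chain of such a study as
reusable, tested code: a forward model that synthesizes CAP recordings
with known ground truth, the windowed-SNR threshold detector with
no-response censoring, and the statistical layer (shift tables, unbalanced
two-way ANOVA with Cohen's *f*, Tukey–Kramer post hoc comparisons,
cumulative threshold curves). Because per-animal data of this kind are
rarely published in machine-readable form, the synthetic generator is a
first-class module: it gives every downstream stage a ground truth to be
tested against.

## Study design and ground truth

The default design mirrors a four-condition severing experiment:
`baseline`, `amp` (AMP only), `pil` (PIL only) and `both`, with 17
baseline ears of which 7 are measured AMP-only, 7 PIL-only and 14 with
both attachments severed. Air conduction uses seven octave frequencies
(500–32,000 Hz), bone conduction six (500–16,000 Hz). Levels descend in
5 dB steps from the transducer's maximum output to a floor.

The measured true threshold of one session is

\[
\theta_{e,c,f} \;=\; b_{e,f} \;+\; \delta_{e,c,f} \;+\; \varepsilon_{e,c,f},
\]

where \(b_{e,f}\) is the ear's stable baseline truth (per-frequency
population mean plus a between-ear deviation, SD 6 dB),
\(\delta_{e,c,f}\) is the condition elevation drawn per ear and frequency
from a normal with the condition's configured mean and SD (identically 0
for baseline — positive means worse hearing), and \(\varepsilon\) is a
per-session test-retest deviation (SD 3 dB). Injecting the elevation per
*(ear, frequency)* measurement, rather than per ear, matches how such
studies report pooled mean ± SD over ears and frequencies. The default
elevation distributions are the condition summaries of a severing study of
this design: air −1 ± 16 (AMP), 5 ± 16 (PIL), 23 ± 26 dB (both); bone
1.3 ± 7, −2 ± 24, −4 ± 18 dB.

Baseline threshold means (air: 35/25/20/15/20/30/35 dB SPL from 500 Hz to
32 kHz) follow the U-shaped CAP audiogram of a healthy low-frequency
hearing rodent. They are deliberately healthy: with the 70 dB SPL output
ceiling at 32 kHz, sicker baselines would censor much of the severed
condition and the recovered pooled shift would no longer estimate the
injected mean. Even so, a mild downward censoring bias (≈1 dB pooled over
seven frequencies) remains in the both-severed air shift; it is visible in
the recovery checks and is a faithful property of max-output substitution,
not a defect.

### Bone-conduction sign convention

Bone thresholds are reported in dB attenuation of the transducer drive
(0 dB = loudest). Internally the package uses `level = -attenuation`, so
"larger = louder" and "positive shift = worse" hold for both modalities;
the conversion to dB attenuation happens only in `write_threshold_table()`
/ `read_threshold_table()`, and is noted in the CSV header comment.

## The recording forward model

One epoch lasts 49 ms: 5 ms pre-stimulus, a 24 ms tone burst (2 ms
raised-cosine rise/fall, 20 ms plateau — the cos² gate is the standard
audiological choice), 20 ms post-stimulus. The default sampling rate is
250 kHz. A single trial is the sum of three components:

* **CAP** — a fixed biphasic (negative-then-positive) template, one sine
  cycle 3 ms wide at 2.5 ms latency, entirely inside the 0–10 ms response
  window. Its amplitude is \(\min(A_{sat},\, s\,(L-\theta)_+)\) with slope
  *s* = 1 µV/dB and saturation 60 µV: the simplest growth law with a
  well-defined disappearance point. No species-specific morphology is
  claimed — any waveform confined to the response window would serve.
* **Artifact** — a scaled copy of the stimulus waveform (1 µV) whose sign
  flips with stimulus phase, emulating the cochlear microphonic.
* **Noise** — zero-mean Gaussian noise band-limited to the recording band
  by the same filter as below, scaled to 3 µV RMS per trial.

The recording chain filter is a single causal 2nd-order Butterworth
band-pass (300–3000 Hz), applied once in the forward direction: a
zero-phase filter would be cleaner but would falsify the latency
bookkeeping of an analog preamplifier. Its skirts fall at 6 dB/octave per
side (a 12 dB/octave combined order), which leaves a 30 kHz carrier at
least 18 dB below the 1 kHz response — enough to make high-frequency
artifact leakage into the 300–3000 Hz band negligible.

Averaging 128 trials with alternating phase cancels the artifact *exactly*
(pairwise negation, independent of noise) and reduces noise RMS by
\(\sqrt{128}\). `fast_mode` (default on) synthesizes the averaged trace
directly — CAP plus noise at RMS\(/\sqrt{n}\), no artifact — which is
mathematically equivalent for everything downstream of the average; the
raw-trial path is retained and tested for the cancellation property
itself. In fast mode the stimulus waveform is never synthesized, so the
sampling rate can be reduced to any rate that resolves the recording band;
desk-scale analyses in the package's own tests and scripts use 25 kHz.

## Threshold detection

For each level, the detector compares peak-to-peak amplitudes in two
equal, disjoint windows: the response window (0–10 ms post onset) and a
reference window placed in the final 10 ms of the epoch (34–44 ms post
onset, i.e. 10–20 ms after stimulus offset) — the latest span of equal
length guaranteed free of auditory response. The SNR is
\(20\log_{10}(pp_{resp}/pp_{ref})\), and a level *passes* when SNR ≥
criterion.

Scanning from the highest tested level down, the threshold is the lowest
level of the contiguous passing run that starts at the top — mirroring a
descending measurement stopped when the response visually disappears.
Isolated passes below a failure are noise and are ignored; a `"global"`
rule (minimum passing level anywhere) is available by flag. If the highest
tested level already fails, no response was recorded: the cell is flagged
censored and the maximum transducer output is substituted as its
threshold, and that substituted value is used in all downstream statistics
(the flag is kept for sensitivity re-runs).

Two criterion presets exist because both are in use in practice: 3 dB
(default) and a stricter 6 dB. The choice matters at the margins: with the
3 dB criterion, two noise-only windows exceed the criterion in ≈2% of
cells, so a truly response-free series is occasionally assigned a
threshold at the top level rather than censored (numerically the same
substituted value, different flag). The censoring demonstrations in the
test suite therefore use the 6 dB preset, where that false-pass
probability is negligible.

Quantization: a detected threshold is by construction the first 5 dB grid
level above the true threshold (plus a ~1 dB delay where the CAP is still
within the noise floor). The resulting ≈ +3 dB offset is common to
baseline and condition measurements and cancels in every shift.

## Statistics

* **Shifts** — `condition − baseline` per ear, modality and frequency;
  summaries are pooled means and SDs over ears × frequencies.
* **ANOVA** — fixed-effects two-way ANOVA of raw thresholds on condition
  (4 levels, baseline included) and frequency, with interaction, Type-II
  sums of squares for the unbalanced design (the SS type is a
  reporting-convention choice; Type II is the conventional default when
  the interaction is not the focus). Cohen's *f* per term from partial
  \(\eta^2\): \(f=\sqrt{SS_{\mathrm{eff}}/SS_{\mathrm{res}}}\). Air and
  bone are analysed separately. Degenerate input with zero variance
  reports F = 0, p = 1 by convention.
* **Tukey–Kramer** — over all condition × frequency cells:
  \(q_{ij} = |m_i-m_j|/\sqrt{\tfrac{MSE}{2}(1/n_i+1/n_j)}\) with the
  cell-means-model residual MSE, p-values from the studentized-range
  distribution with (number of cells, residual df); `by = "condition"`
  pools frequencies.
* **Cumulative curves** — right-continuous ECDFs of thresholds per
  condition on the 5 dB grid; censored ears, carrying the substituted
  ceiling value, join the curve only at that level.

A caveat the package surfaces rather than hides: in the paired design the
same ears appear in several condition arms, so observations share ear
effects and the plain two-way ANOVA (the conventional analysis for this
design) is not exactly calibrated. The type-I calibration property is
therefore checked on null studies generated with between-ear SD set to 0,
which makes observations independent; a mixed-effects model per ear would
be the principled extension and is deliberately out of scope.

## Problem sizes and reproducibility of the checks

All simulation-backed checks run the full default design in fast mode at
25 kHz. The pooled mean shift of a single study has sampling SE ≈ 2.7 dB
for the both-severed air condition (shift SD 26, n = 98), so the recovery
checks in the test suite average three replicate studies at fixed seeds
and require the recovered pooled mean to sit within ±4 dB of the injected
mean; type-I calibration uses 500 replicate null tables generated without
waveform synthesis (`simulate_threshold_table()`), and the Tukey–Kramer
p-value is validated against a \(10^5\)-draw Monte-Carlo studentized-range
null. Every stochastic step is seeded; identical configuration and seed
reproduce every output byte for byte.

## What the generator does not emulate

* No middle-ear mechanics: conductive loss is injected directly as a
  threshold elevation, so the model cannot say *why* severing shifts
  thresholds, only propagate a given shift through recording and analysis.
* CAP latency, width and growth slope are plausible placeholders, not
  species measurements; conclusions that depend on waveform morphology
  (rather than on windowed peak-to-peak energy) are outside the model.
* The artifact amplitude is level-independent, and no operator
  "visual confirmation" exists — the detector is fully deterministic.
* Passing recovery tests show the pipeline is consistent under the model's
  assumptions (normal elevations, linear growth, stationary band-limited
  noise); real recordings can violate any of them.

## A short tour

```{r tour, eval = FALSE}
cfg <- default_config()
cfg$simulation$sampling_rate <- 25000   # desk scale, fast mode
cfg$simulation$seed <- 1

study      <- generate_study(cfg)
thresholds <- detect_study(study, window_config(criterion_db = 3))
shifts     <- build_shift_table(thresholds)

summarize_shifts(shifts)
threshold_anova(thresholds, "air")
tukey_kramer(thresholds, "air")$pairs
plot_shift_panels(shifts, "air")
plot_cumulative_curves(cumulative_curves(thresholds, "air", 32000))
```

The same chain, with figures, tables and a run log, is available as
`run_pipeline(cfg, out_dir)` and from the shell via
`inst/cli/capshift.R` (`simulate`, `detect`, `stats`, `plot`, `run-all`).
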