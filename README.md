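# capshift

Simulation and analysis of compound action potential (CAP) threshold-shift
studies of middle-ear function.

## What it is for

In animal studies of conductive hearing loss — e.g. severing the
suspensory attachments of the ossicles (the anterior mallear process,
AMP, and the posterior incudal ligament, PIL, in the gerbil) — hearing
sensitivity is read out as the CAP threshold: the lowest tone-burst level
that evokes a detectable auditory-nerve response at the round window,
measured per frequency under air and bone conduction. `capshift` provides,
as one tested pipeline:

* a **synthetic study generator** with known ground truth: per-ear true
  thresholds, condition-specific elevations, and the full recording
  forward model (24 ms gated tone bursts, biphasic CAP with linear growth
  above threshold, phase-locked cochlear-microphonic artifact,
  band-limited noise, 128-trial alternating-phase averaging, 49 ms epochs);
* the **threshold detector**: for each stimulus level the peak-to-peak
  amplitude in the 0–10 ms response window is compared with an equally
  long response-free reference window, SNR = 20·log10(pp_resp/pp_ref);
  scanning the 5 dB level grid from the top, the threshold is the lowest
  level of the contiguous run with SNR ≥ criterion (3 dB default, 6 dB
  preset). Cells where even the highest level fails are **censored** and
  the maximum transducer output is substituted;
* the **statistical layer**: threshold-shift tables (condition −
  baseline, positive = worse for both modalities), pooled mean ± SD
  summaries, unbalanced two-way ANOVA (condition × frequency, Type-II SS)
  with Cohen's f from partial η², Tukey–Kramer comparisons over
  condition × frequency cells via the studentized-range distribution, and
  cumulative threshold curves (percentage of ears at/below threshold per
  level).

See the methods vignette (`vignettes/cap-threshold-pipeline.Rmd`) for the
model, its assumptions and the design choices.

## Worked example

```r
library(capshift)

cfg <- default_config()          # 17/7/7/14-ear severing design
cfg$simulation$sampling_rate <- 25000   # desk scale (fast mode)
cfg$simulation$seed <- 1

study      <- generate_study(cfg)                  # 585 measurement cells
thresholds <- detect_study(study)                  # 3 dB SNR criterion
shifts     <- build_shift_table(thresholds)
summarize_shifts(shifts)
```

```
# A tibble: 6 × 5
  modality condition mean_db sd_db     n
  <chr>    <chr>       <dbl> <dbl> <int>
1 air      amp         -1.33  14.3    49
2 air      both        21.0   28.5    98
3 air      pil          6.02  16.9    49
4 bone     amp          3.57   8.79   42
5 bone     both        -5.12  18.1    84
6 bone     pil         -1.43  22.2    42
```

Each row pools one severing condition's threshold shifts over ears ×
frequencies: with both attachments severed, air-conduction thresholds are
elevated by ~21 dB on average (injected truth: 23 ± 26 dB; the pooled
mean of a single 14-ear study has a sampling SE of ≈2.7 dB), while
single-severing air shifts and all bone-conduction shifts stay near zero —
the signature of a conductive loss that appears only when both
attachments are cut.

```r
threshold_anova(thresholds, "air")
```

```
# A tibble: 3 × 6
  term                   df sum_sq     f        p cohens_f
  <chr>               <dbl>  <dbl> <dbl>    <dbl>    <dbl>
1 condition               3 28015. 27.4  1.25e-15    0.536
2 frequency               6 11186.  5.48 2.19e- 5    0.338
3 condition:frequency    18  7054.  1.15 3.02e- 1    0.269
```

The condition main effect is large (Cohen's f ≈ 0.5) and the
condition-by-frequency interaction negligible: severing shifts thresholds
broadly across frequency. `tukey_kramer(thresholds, "air")` then shows
which condition × frequency cells differ, and
`plot_cumulative_curves(cumulative_curves(thresholds, "air", 32000))`
displays the rightward shift of the both-severed group's cumulative
threshold curve.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "capshift.R", package = "capshift")` with subcommands
`simulate | detect | stats | plot | run-all`, configured by a YAML file
(fully commented example:
`system.file("extdata", "pipeline-config.yaml", package = "capshift")`).

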