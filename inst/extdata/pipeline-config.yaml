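# capshift pipeline configuration
#
# Every field is optional: omitted fields keep the package defaults
# (see ?default_config). Values below mirror the default study design,
# except the sampling rate, which is reduced to desk scale.

simulation:
  # ears per condition arm; the severing arms are nested in the baseline
  # group (amp = first 7 ears, pil = next 7, both = first 14)
  n_ears:
    baseline: 17
    amp: 7
    pil: 7
    both: 14

  # which stimulation modalities to simulate
  modalities: [air, bone]

  # octave frequency grids in Hz
  frequencies:
    air: [500, 1000, 2000, 4000, 8000, 16000, 32000]
    bone: [500, 1000, 2000, 4000, 8000, 16000]

  # stimulus levels descend from the per-frequency maximum output to this
  # floor in level_step dB steps. Bone levels are internal dB
  # (= minus dB attenuation; 0 is the loudest drive).
  level_floor:
    air: 0
    bone: -80
  level_step: 5

  # maximum transducer output per frequency (dB SPL for air, internal dB
  # for bone); thresholds with no response are censored at these values
  max_output:
    air: {500: 100, 1000: 100, 2000: 100, 4000: 100, 8000: 100,
          16000: 100, 32000: 70}
    bone: {500: 0, 1000: 0, 2000: 0, 4000: 0, 8000: 0, 16000: 0}

  # population mean of the baseline true threshold per frequency, the
  # between-ear SD around it, and the per-session test-retest SD (all dB)
  baseline_mean:
    air: {500: 35, 1000: 25, 2000: 20, 4000: 15, 8000: 20,
          16000: 30, 32000: 35}
    bone: {500: -30, 1000: -35, 2000: -40, 4000: -40, 8000: -35,
           16000: -30}
  baseline_sd: 6
  test_retest_sd: 3

  # additive threshold elevation (dB, positive = worse hearing) drawn per
  # (ear, frequency) for each severing condition
  condition_effects:
    air:
      amp: {mean: -1, sd: 16}
      pil: {mean: 5, sd: 16}
      both: {mean: 23, sd: 26}
    bone:
      amp: {mean: 1.3, sd: 7}
      pil: {mean: -2, sd: 24}
      both: {mean: -4, sd: 18}

  # CAP forward model: biphasic template latency and width (ms), linear
  # growth slope above threshold (uV/dB) and saturation amplitude (uV)
  cap:
    latency_ms: 2.5
    width_ms: 3
    slope_uv_per_db: 1
    saturation_uv: 60

  artifact_uv: 1        # phase-locked cochlear-microphonic amplitude (uV)
  noise_rms_uv: 3       # single-trial band-limited noise RMS (uV)
  n_averages: 128       # trials per average, phase alternating (even)
  sampling_rate: 25000  # Hz; 250000 reproduces the recording chain exactly,
                        # 25000 is sufficient for fast_mode (300-3000 Hz band)
  fast_mode: true       # synthesize the averaged trace directly
  seed: 20260901

detection:
  response_window: [0, 10]    # ms after stimulus onset
  reference_window: [34, 44]  # final 10 ms of the 49 ms epoch
  criterion_db: 3             # SNR criterion; 6 = stricter preset
  rule: contiguous            # or "global" (minimum passing level anywhere)

stats:
  alpha: 0.05
  ss_type: 2          # sums-of-squares type for the unbalanced ANOVA
  include_censored: true

output:
  dir: capshift-output
  log_level: info
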