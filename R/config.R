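#' Default pipeline configuration
#'
#' Returns the full configuration for a simulated ligament-severing CAP
#' study, with the study design used throughout the package: four severing
#' conditions (`baseline`, `amp` = anterior mallear process only, `pil` =
#' posterior incudal ligament only, `both`), 17 baseline ears of which 7 are
#' measured AMP-only, 7 PIL-only and 14 with both attachments severed, seven
#' air-conduction octave frequencies (500--32,000 Hz) and six bone-conduction
#' frequencies (500--16,000 Hz), and a descending 5 dB level grid per
#' frequency topped at the transducer's maximum output.
#'
#' Bone-conduction levels are kept on an internal axis where larger values
#' mean louder stimulation (internal level = minus the dB attenuation of the
#' transducer drive), so that "positive shift = worse hearing" holds for both
#' modalities. Conversion to dB attenuation happens only when threshold
#' tables are written to disk (see [write_threshold_table()]).
#'
#' @return A nested list with sections `simulation`, `detection`, `stats`
#'   and `output`. Every value can be overridden via [read_pipeline_config()]
#'   or by editing the returned list.
#' @seealso [read_pipeline_config()], [generate_study()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$simulation$frequencies$air
default_config <- function() {
  list(
    simulation = list(
      # ears per condition arm; amp/pil/both arms are subsets of the
      # baseline ears (amp = first 7, pil = next 7, both = first 14)
      n_ears = list(baseline = 17L, amp = 7L, pil = 7L, both = 14L),
      modalities = c("air", "bone"),
      frequencies = list(
        air  = c(500, 1000, 2000, 4000, 8000, 16000, 32000),
        bone = c(500, 1000, 2000, 4000, 8000, 16000)
      ),
      # stimulus levels descend from the per-frequency maximum output to the
      # floor in `level_step` dB steps
      level_floor = list(air = 0, bone = -80),
      level_step = 5,
      max_output = list(
        air = c("500" = 100, "1000" = 100, "2000" = 100, "4000" = 100,
                "8000" = 100, "16000" = 100, "32000" = 70),
        bone = c("500" = 0, "1000" = 0, "2000" = 0, "4000" = 0,
                 "8000" = 0, "16000" = 0)
      ),
      # per-frequency population mean of the baseline true threshold and
      # between-ear SD (dB); test_retest_sd is per measurement session
      baseline_mean = list(
        air  = c("500" = 35, "1000" = 25, "2000" = 20, "4000" = 15,
                 "8000" = 20, "16000" = 30, "32000" = 35),
        bone = c("500" = -30, "1000" = -35, "2000" = -40, "4000" = -40,
                 "8000" = -35, "16000" = -30)
      ),
      baseline_sd = 6,
      test_retest_sd = 3,
      # additive threshold elevation (dB, positive = worse) drawn per
      # (ear, frequency) measurement for each non-baseline condition
      condition_effects = list(
        air = list(
          amp  = c(mean = -1, sd = 16),
          pil  = c(mean = 5,  sd = 16),
          both = c(mean = 23, sd = 26)
        ),
        bone = list(
          amp  = c(mean = 1.3, sd = 7),
          pil  = c(mean = -2,  sd = 24),
          both = c(mean = -4,  sd = 18)
        )
      ),
      # CAP forward model: biphasic template at fixed latency, linear
      # growth above threshold with saturation
      cap = list(
        latency_ms = 2.5,
        width_ms = 3,
        slope_uv_per_db = 1,
        saturation_uv = 60
      ),
      artifact_uv = 1,     # stimulus-phase-locked (cochlear microphonic) amplitude
      noise_rms_uv = 3,    # single-trial band-limited noise RMS
      n_averages = 128L,
      sampling_rate = 250000,
      fast_mode = TRUE,    # synthesize averaged traces directly
      seed = NULL
    ),
    detection = list(
      response_window = c(0, 10),    # ms post stimulus onset
      reference_window = c(34, 44),  # final 10 ms of the 49 ms epoch
      criterion_db = 3,              # stricter preset: 6
      rule = "contiguous"
    ),
    stats = list(
      alpha = 0.05,
      ss_type = 2,
      include_censored = TRUE
    ),
    output = list(
      dir = "capshift-output",
      log_level = "info"
    )
  )
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML file mirroring the structure of [default_config()], merges
#' it over the defaults (any omitted field keeps its default), and validates
#' the result. A fully commented example ships with the package:
#' `system.file("extdata", "pipeline-config.yaml", package = "capshift")`.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    config <- merge_config(config, user)
  }
  validate_config(config)
  config
}

# recursive merge: user values override defaults, unknown keys rejected
merge_config <- function(base, user, path = "") {
  if (!is.list(user) || !is.list(base)) {
    return(user)
  }
  for (key in names(user)) {
    full <- paste0(path, "$", key)
    if (!key %in% names(base)) {
      stop("unknown configuration field: ", full, call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      value <- user[[key]]
      if (is.list(value)) value <- unlist(value)
      # keep names of per-frequency maps keyed by frequency
      if (!is.null(names(base[[key]])) && is.null(names(value)) &&
          length(value) == length(base[[key]])) {
        names(value) <- names(base[[key]])
      }
      base[[key]] <- value
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks every invariant the simulation and detection stages rely on
#' (positive group sizes, consistent frequency grids, strictly descending
#' 5 dB level grids, even averaging count, positive noise RMS, valid
#' detection windows) and fails with an informative message on the first
#' violation.
#'
#' @param config A configuration list shaped like [default_config()].
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  sim <- config$simulation
  if (is.null(sim)) stop("config has no 'simulation' section", call. = FALSE)

  n <- sim$n_ears
  for (arm in c("baseline", "amp", "pil", "both")) {
    if (is.null(n[[arm]]) || n[[arm]] < 1) {
      stop("non-positive group size for condition arm '", arm, "'",
           call. = FALSE)
    }
  }
  if (n$amp + n$pil > n$baseline || n$both > n$baseline) {
    stop("condition arms must fit inside the baseline group: need ",
         "amp + pil <= baseline and both <= baseline", call. = FALSE)
  }

  if (!all(sim$modalities %in% c("air", "bone"))) {
    stop("modalities must be a subset of c('air', 'bone')", call. = FALSE)
  }
  if (sim$level_step <= 0) stop("level_step must be positive", call. = FALSE)
  for (mod in sim$modalities) {
    freqs <- sim$frequencies[[mod]]
    if (length(freqs) == 0) {
      stop("empty frequency grid for modality '", mod, "'", call. = FALSE)
    }
    if (any(diff(freqs) <= 0)) {
      stop("frequency grid for '", mod, "' must be strictly increasing",
           call. = FALSE)
    }
    for (field in c("max_output", "baseline_mean")) {
      have <- names(sim[[field]][[mod]])
      if (!all(as.character(freqs) %in% have)) {
        stop(field, " for '", mod, "' must cover every grid frequency",
             call. = FALSE)
      }
    }
    for (f in freqs) {
      grid <- level_grid(sim, mod, f)
      if (length(grid) < 2 || any(diff(grid) != -sim$level_step)) {
        stop("level grid for ", mod, " at ", f, " Hz is not a descending ",
             sim$level_step, " dB grid", call. = FALSE)
      }
    }
    for (cond in c("amp", "pil", "both")) {
      eff <- sim$condition_effects[[mod]][[cond]]
      if (is.null(eff) || !all(c("mean", "sd") %in% names(eff)) ||
          !all(is.finite(eff)) || eff[["sd"]] < 0) {
        stop("condition_effects$", mod, "$", cond,
             " must supply finite mean and non-negative sd", call. = FALSE)
      }
    }
  }
  if (sim$noise_rms_uv <= 0) stop("noise_rms_uv must be > 0", call. = FALSE)
  if (sim$n_averages < 2 || sim$n_averages %% 2 != 0) {
    stop("n_averages must be even (alternating-phase pairing)", call. = FALSE)
  }
  if (sim$baseline_sd < 0 || sim$test_retest_sd < 0) {
    stop("baseline_sd and test_retest_sd must be non-negative", call. = FALSE)
  }
  # raw-trial mode synthesizes the stimulus waveform (artifact), so the
  # carrier must be well below Nyquist; fast mode only needs the 300-3000 Hz
  # recording band
  if (!sim$fast_mode &&
      sim$sampling_rate < 4 * max(unlist(sim$frequencies))) {
    stop("sampling_rate must be at least 4x the highest stimulus frequency ",
         "when fast_mode is off", call. = FALSE)
  }
  if (sim$sampling_rate < 12000) {
    stop("sampling_rate must cover the 300-3000 Hz recording band",
         call. = FALSE)
  }

  det <- config$detection
  window_config(response = det$response_window,
                reference = det$reference_window,
                criterion_db = det$criterion_db,
                rule = det$rule)

  st <- config$stats
  if (!is.null(st$alpha) && (st$alpha <= 0 || st$alpha >= 1)) {
    stop("stats$alpha must be in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

# descending stimulus level grid for one (modality, frequency) cell
level_grid <- function(sim, modality, frequency) {
  top <- max_output_db(sim, modality, frequency)
  seq(top, sim$level_floor[[modality]], by = -sim$level_step)
}

#' Maximum transducer output for a modality and frequency
#'
#' @param sim The `simulation` section of a configuration list.
#' @param modality `"air"` or `"bone"`.
#' @param frequency Stimulus frequency in Hz.
#' @return The output ceiling in dB (internal scale for bone).
#' @export
max_output_db <- function(sim, modality, frequency) {
  out <- sim$max_output[[modality]][[as.character(frequency)]]
  if (is.null(out)) {
    stop("no max_output entry for ", modality, " at ", frequency, " Hz",
         call. = FALSE)
  }
  out
}

study_conditions <- function() c("baseline", "amp", "pil", "both")
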