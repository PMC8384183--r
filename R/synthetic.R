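#' Draw per-ear ground truth for a simulated severing study
#'
#' Draws the latent state of every measurement in the study design: each
#' ear's stable baseline true threshold per frequency and modality
#' (population mean per frequency plus a between-ear normal deviation), the
#' additive condition elevation for each severing condition the ear is
#' measured in (zero for baseline, otherwise drawn per ear and frequency
#' from the configured normal), and a per-session test-retest deviation.
#' The measured true threshold of a session is the sum of the three terms.
#'
#' Condition arms are nested in the baseline group the way the study was
#' run: with the default sizes (17/7/7/14), ears 1--7 are measured AMP-only,
#' ears 8--14 PIL-only, and ears 1--14 with both attachments severed; all 17
#' ears have baseline measurements.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_pipeline_config()]. `config$simulation$seed`, when non-`NULL`,
#'   seeds the draw.
#' @return A tibble with one row per measurement: `ear_id`, `condition`,
#'   `modality`, `frequency_hz`, `baseline_db`, `elevation_db`, `retest_db`,
#'   `true_db`, `max_output_db`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$simulation$seed <- 1
#' truth <- draw_ground_truth(cfg)
#' dplyr::count(truth, condition, modality)
draw_ground_truth <- function(config) {
  validate_config(config)
  sim <- config$simulation
  if (!is.null(sim$seed)) set.seed(sim$seed)
  draw_ground_truth_impl(sim)
}

# RNG-consuming core; callers are responsible for seeding
draw_ground_truth_impl <- function(sim) {
  ears <- sprintf("ear%02d", seq_len(sim$n_ears$baseline))
  arm <- list(
    baseline = ears,
    amp  = ears[seq_len(sim$n_ears$amp)],
    pil  = ears[sim$n_ears$amp + seq_len(sim$n_ears$pil)],
    both = ears[seq_len(sim$n_ears$both)]
  )

  # stable per-(ear, modality, frequency) baseline truths
  base_rows <- do.call(rbind, lapply(sim$modalities, function(mod) {
    expand.grid(ear_id = ears, frequency_hz = sim$frequencies[[mod]],
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE) |>
      transform(modality = mod)
  }))
  base_rows$baseline_db <-
    vapply(seq_len(nrow(base_rows)), function(i) {
      sim$baseline_mean[[base_rows$modality[i]]][[
        as.character(base_rows$frequency_hz[i])]]
    }, numeric(1)) +
    stats::rnorm(nrow(base_rows), 0, sim$baseline_sd)

  rows <- do.call(rbind, lapply(study_conditions(), function(cond) {
    do.call(rbind, lapply(sim$modalities, function(mod) {
      expand.grid(ear_id = arm[[cond]], frequency_hz = sim$frequencies[[mod]],
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE) |>
        transform(condition = cond, modality = mod)
    }))
  }))
  rows <- merge(rows, base_rows, by = c("ear_id", "modality", "frequency_hz"),
                sort = FALSE)
  # fixed row order so draws are reproducible regardless of merge internals
  rows <- rows[order(match(rows$condition, study_conditions()),
                     match(rows$modality, c("air", "bone")),
                     rows$ear_id, rows$frequency_hz), ]

  eff <- vapply(seq_len(nrow(rows)), function(i) {
    if (rows$condition[i] == "baseline") return(c(0, 0))
    e <- sim$condition_effects[[rows$modality[i]]][[rows$condition[i]]]
    c(e[["mean"]], e[["sd"]])
  }, numeric(2))
  rows$elevation_db <- ifelse(rows$condition == "baseline", 0,
                              stats::rnorm(nrow(rows), eff[1, ], eff[2, ]))
  rows$retest_db <- stats::rnorm(nrow(rows), 0, sim$test_retest_sd)
  rows$true_db <- rows$baseline_db + rows$elevation_db + rows$retest_db
  rows$max_output_db <- vapply(seq_len(nrow(rows)), function(i) {
    max_output_db(sim, rows$modality[i], rows$frequency_hz[i])
  }, numeric(1))

  tibble::as_tibble(rows[, c("ear_id", "condition", "modality",
                             "frequency_hz", "baseline_db", "elevation_db",
                             "retest_db", "true_db", "max_output_db")])
}

# biphasic (negative-then-positive) CAP template: one sine cycle of
# width_ms, peak amplitude 1, so peak-to-peak ~ 2
cap_template <- function(fs, latency_ms = 2.5, width_ms = 3) {
  w <- round(width_ms / 1000 * fs)
  t <- (seq_len(w) - 1) / w
  list(values = -sin(2 * pi * t),
       offset = floor(latency_ms / 1000 * fs))
}

# CAP peak amplitude (uV) for a stimulus level relative to true threshold
cap_amplitude <- function(level, true_db, cap) {
  min(cap$saturation_uv, max(0, cap$slope_uv_per_db * (level - true_db)))
}

# deterministic part of one epoch: CAP (+ optional phase-locked artifact)
epoch_deterministic <- function(frequency, level, true_db, sim, phase,
                                with_artifact) {
  fs <- sim$sampling_rate
  n <- round(49 / 1000 * fs)
  pre <- round(5 / 1000 * fs)
  x <- numeric(n)
  amp <- cap_amplitude(level, true_db, sim$cap)
  if (amp > 0) {
    tpl <- cap_template(fs, sim$cap$latency_ms, sim$cap$width_ms)
    idx <- pre + tpl$offset + seq_along(tpl$values)
    x[idx] <- x[idx] + amp * tpl$values
  }
  if (with_artifact && sim$artifact_uv != 0) {
    burst <- synth_tone_burst(frequency, fs, phase = phase)
    x[pre + seq_along(burst)] <- x[pre + seq_along(burst)] +
      sim$artifact_uv * burst
  }
  x
}

#' Synthesize a single CAP recording trial
#'
#' Forward model for one epoch: a biphasic CAP whose amplitude grows
#' linearly with dB above the ear's true threshold (clipped at zero below
#' threshold and at the saturation amplitude above), plus a stimulus-locked
#' artifact (cochlear microphonic) that is a scaled copy of the tone burst
#' and flips sign with stimulus phase, plus zero-mean Gaussian noise
#' band-limited to the recording band. The CAP does not invert with phase.
#'
#' @param frequency Stimulus frequency in Hz.
#' @param level Stimulus level in dB (SPL for air; internal dB for bone).
#' @param true_db The measurement's true threshold in the same units.
#' @param config Configuration list; the `simulation` section supplies the
#'   CAP, artifact and noise parameters.
#' @param modality `"air"` or `"bone"`; used to check the transducer range.
#' @param phase Stimulus phase, `0` or `pi`.
#' @return A [cap_trace()].
#' @export
synth_single_trial <- function(frequency, level, true_db, config,
                               modality = "air", phase = 0) {
  sim <- config$simulation
  if (!frequency %in% sim$frequencies[[modality]]) {
    stop("frequency ", frequency, " Hz is not in the ", modality,
         " grid", call. = FALSE)
  }
  top <- max_output_db(sim, modality, frequency)
  if (level > top || level < sim$level_floor[[modality]]) {
    stop("level ", level, " dB is outside the configured ", modality,
         " transducer range [", sim$level_floor[[modality]], ", ", top, "]",
         call. = FALSE)
  }
  fs <- sim$sampling_rate
  x <- epoch_deterministic(frequency, level, true_db, sim, phase,
                           with_artifact = TRUE)
  x <- x + band_limited_noise(length(x), fs, sim$noise_rms_uv)
  cap_trace(x, fs)
}

# one averaged epoch for a (level x cell); fast mode adds noise at
# rms/sqrt(n_averages) directly, raw mode averages alternating trials
synth_averaged_samples <- function(frequency, level, true_db, sim) {
  if (sim$fast_mode) {
    x <- epoch_deterministic(frequency, level, true_db, sim, 0,
                             with_artifact = FALSE)
    x + band_limited_noise(length(x), sim$sampling_rate,
                           sim$noise_rms_uv / sqrt(sim$n_averages))
  } else {
    trials <- lapply(seq_len(sim$n_averages), function(i) {
      phase <- if (i %% 2 == 1) 0 else pi
      x <- epoch_deterministic(frequency, level, true_db, sim, phase,
                               with_artifact = TRUE)
      x + band_limited_noise(length(x), sim$sampling_rate, sim$noise_rms_uv)
    })
    Reduce(`+`, trials) / length(trials)
  }
}

#' Construct a growth series
#'
#' A growth series holds the averaged traces of one study cell (one ear,
#' condition, modality and frequency) at every tested stimulus level, in
#' descending level order. It is the unit consumed by [detect_threshold()].
#'
#' @param traces Numeric matrix, one row per level (descending), one column
#'   per sample.
#' @param levels Descending vector of stimulus levels in dB.
#' @param fs Sampling rate in Hz.
#' @param ear_id,condition,modality,frequency_hz Cell identity.
#' @param max_output_db Transducer ceiling for this cell; used for
#'   no-response censoring.
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(traces, levels, fs, ear_id = NA_character_,
                          condition = NA_character_, modality = "air",
                          frequency_hz = NA_real_, max_output_db = max(levels)) {
  stopifnot(is.matrix(traces), nrow(traces) == length(levels))
  if (any(diff(levels) >= 0)) {
    stop("levels must be strictly decreasing", call. = FALSE)
  }
  rownames(traces) <- as.character(levels)
  structure(
    list(traces = traces, levels = levels, fs = fs, ear_id = ear_id,
         condition = condition, modality = modality,
         frequency_hz = frequency_hz, max_output_db = max_output_db),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf(
    "<growth_series> %s/%s %s %g Hz: %d levels (%g..%g dB), %d samples @ %g Hz\n",
    x$ear_id, x$condition, x$modality, x$frequency_hz, length(x$levels),
    max(x$levels), min(x$levels), ncol(x$traces), x$fs))
  invisible(x)
}

# growth series for one ground-truth row, averaged traces at every level
generate_growth_series <- function(truth_row, sim) {
  levels <- level_grid(sim, truth_row$modality, truth_row$frequency_hz)
  fs <- sim$sampling_rate
  n <- round(49 / 1000 * fs)
  if (sim$fast_mode) {
    # one long noise stream filtered once, then cut into epochs
    noise <- band_limited_noise(n * length(levels), fs,
                                sim$noise_rms_uv / sqrt(sim$n_averages))
    traces <- matrix(noise, nrow = length(levels), ncol = n, byrow = TRUE)
    for (i in seq_along(levels)) {
      traces[i, ] <- traces[i, ] +
        epoch_deterministic(truth_row$frequency_hz, levels[i],
                            truth_row$true_db, sim, 0, with_artifact = FALSE)
    }
  } else {
    traces <- t(vapply(levels, function(lv) {
      synth_averaged_samples(truth_row$frequency_hz, lv, truth_row$true_db,
                             sim)
    }, numeric(n)))
  }
  growth_series(traces, levels, fs, ear_id = truth_row$ear_id,
                condition = truth_row$condition,
                modality = truth_row$modality,
                frequency_hz = truth_row$frequency_hz,
                max_output_db = truth_row$max_output_db)
}

#' Generate a complete synthetic CAP study
#'
#' Runs the full forward model: draws ground truth with
#' [draw_ground_truth()], then synthesizes the averaged CAP recording of
#' every study cell at every stimulus level of its descending 5 dB grid.
#' With `fast_mode` (the default) the 128-trial alternating-phase average is
#' synthesized directly — the phase-locked artifact cancels exactly, and the
#' noise RMS is the single-trial RMS divided by `sqrt(n_averages)`;
#' otherwise raw trials are synthesized and averaged explicitly.
#'
#' @param config Configuration list; `config$simulation$seed` makes the
#'   study bit-reproducible.
#' @return An object of class `cap_study`: a list with `ground_truth` (the
#'   registry tibble), `series` (list of [growth_series()]) and `config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$simulation <- utils::modifyList(cfg$simulation, list(
#'   seed = 1, sampling_rate = 25000,
#'   n_ears = list(baseline = 3L, amp = 1L, pil = 1L, both = 2L),
#'   modalities = "air"))
#' study <- generate_study(cfg)
#' length(study$series)
generate_study <- function(config) {
  validate_config(config)
  sim <- config$simulation
  if (!is.null(sim$seed)) set.seed(sim$seed)
  truth <- draw_ground_truth_impl(sim)
  series <- lapply(seq_len(nrow(truth)), function(i) {
    generate_growth_series(truth[i, ], sim)
  })
  structure(list(ground_truth = truth, series = series, config = config),
            class = "cap_study")
}

#' @export
print.cap_study <- function(x, ...) {
  cat(sprintf("<cap_study> %d measurement cells, %d ears, modalities: %s\n",
              length(x$series),
              length(unique(x$ground_truth$ear_id)),
              paste(x$config$simulation$modalities, collapse = ", ")))
  invisible(x)
}

#' Simulate a threshold table without waveform synthesis
#'
#' Idealized end point of the pipeline for statistical work at scale: draws
#' ground truth and converts each measurement's true threshold directly to
#' the threshold the detector would report on a noise-free recording — the
#' lowest 5 dB grid level at or above the true value — with no-response
#' censoring at the transducer ceiling. Used for ANOVA calibration and
#' power studies where synthesizing waveforms for hundreds of replicate
#' studies would add nothing.
#'
#' @param config Configuration list.
#' @return A threshold table tibble (`ear_id`, `condition`, `modality`,
#'   `frequency_hz`, `threshold_db`, `censored`).
#' @export
simulate_threshold_table <- function(config) {
  truth <- draw_ground_truth(config)
  sim <- config$simulation
  step <- sim$level_step
  floor_db <- vapply(truth$modality, function(m) sim$level_floor[[m]],
                     numeric(1))
  censored <- truth$true_db > truth$max_output_db
  quantized <- truth$max_output_db -
    step * floor((truth$max_output_db - truth$true_db) / step)
  threshold <- ifelse(censored, truth$max_output_db,
                      pmax(floor_db, quantized))
  tibble::tibble(
    ear_id = truth$ear_id, condition = truth$condition,
    modality = truth$modality, frequency_hz = truth$frequency_hz,
    threshold_db = threshold, censored = censored
  )
}
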