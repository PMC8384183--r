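test_that("ground truth reproduces the study design and is seed-stable", {
  truth <- draw_ground_truth(desk_config(seed = 7))
  ears_per <- tapply(truth$ear_id, truth$condition,
                     function(x) length(unique(x)))
  expect_equal(ears_per[["baseline"]], 17)
  expect_equal(ears_per[["amp"]], 7)
  expect_equal(ears_per[["pil"]], 7)
  expect_equal(ears_per[["both"]], 14)

  # modality grids: 7 air frequencies, 6 bone
  expect_equal(length(unique(truth$frequency_hz[truth$modality == "air"])), 7)
  expect_equal(length(unique(truth$frequency_hz[truth$modality == "bone"])), 6)

  # baseline condition carries no elevation; all values finite
  expect_true(all(truth$elevation_db[truth$condition == "baseline"] == 0))
  expect_true(all(is.finite(truth$true_db)))

  # every (ear, condition, modality) covers its full frequency grid once
  key <- paste(truth$ear_id, truth$condition, truth$modality,
               truth$frequency_hz)
  expect_false(anyDuplicated(key) > 0)

  expect_identical(draw_ground_truth(desk_config(seed = 7)), truth)
})

test_that("degenerate effect distributions give exactly zero elevations", {
  cfg <- desk_config(seed = 2)
  for (mod in c("air", "bone")) {
    for (cond in c("amp", "pil", "both")) {
      cfg$simulation$condition_effects[[mod]][[cond]] <- c(mean = 0, sd = 0)
    }
  }
  truth <- draw_ground_truth(cfg)
  expect_true(all(truth$elevation_db == 0))
})

test_that("config validation rejects broken study designs", {
  cfg <- desk_config()
  cfg$simulation$n_ears$amp <- 0L
  expect_error(validate_config(cfg), "non-positive group size")

  cfg <- desk_config()
  cfg$simulation$n_ears$both <- 20L
  expect_error(validate_config(cfg), "baseline")

  cfg <- desk_config()
  cfg$simulation$n_averages <- 127L
  expect_error(validate_config(cfg), "even")

  cfg <- desk_config()
  cfg$simulation$noise_rms_uv <- 0
  expect_error(validate_config(cfg), "noise_rms_uv")

  cfg <- desk_config()
  cfg$simulation$frequencies$air <- numeric(0)
  expect_error(validate_config(cfg), "empty frequency grid")
})

test_that("single-trial forward model follows the CAP growth rule", {
  cfg <- desk_config()
  cfg$simulation$noise_rms_uv <- 0   # deterministic components only
  cfg$simulation$artifact_uv <- 0
  cfg$simulation$cap$slope_uv_per_db <- 0.5
  win <- window_config()

  # at threshold the CAP amplitude is exactly zero
  tr <- synth_single_trial(1000, 40, true_db = 40, cfg)
  expect_equal(peak_to_peak(tr, win$response), 0)

  # 10 dB above threshold at 0.5 uV/dB: peak-to-peak is the template's
  # peak-to-peak scaled to 5 uV amplitude
  tpl <- capshift:::cap_template(cfg$simulation$sampling_rate)
  expected_pp <- 5 * (max(tpl$values) - min(tpl$values))
  tr10 <- synth_single_trial(1000, 50, true_db = 40, cfg)
  expect_equal(peak_to_peak(tr10, win$response), expected_pp)

  # saturation caps the amplitude
  cfg$simulation$cap$saturation_uv <- 3
  tr_sat <- synth_single_trial(1000, 100, true_db = 10, cfg)
  expect_equal(peak_to_peak(tr_sat, win$response),
               3 * (max(tpl$values) - min(tpl$values)))

  # transducer range is enforced
  expect_error(synth_single_trial(32000, 75, true_db = 40, cfg),
               "transducer range")
  expect_error(synth_single_trial(700, 50, true_db = 40, cfg), "grid")
})

test_that("artifact-only trials at opposite phases are exact negatives", {
  cfg <- desk_config()
  cfg$simulation$noise_rms_uv <- 0
  # level below threshold: no CAP, artifact only
  a <- synth_single_trial(1000, 30, true_db = 80, cfg, phase = 0)
  b <- synth_single_trial(1000, 30, true_db = 80, cfg, phase = pi)
  expect_gt(max(abs(a$samples)), 0)
  expect_equal(b$samples, -a$samples, tolerance = 1e-12)
})

test_that("generated studies match the design and are bit-reproducible", {
  cfg <- tiny_config(seed = 11, modalities = c("air", "bone"))
  study <- generate_study(cfg)

  meta <- do.call(rbind, lapply(study$series, function(s) {
    data.frame(ear = s$ear_id, condition = s$condition, modality = s$modality,
               frequency = s$frequency_hz)
  }))
  per_ear_air <- with(subset(meta, modality == "air" & condition == "baseline"),
                      tapply(frequency, ear, length))
  per_ear_bone <- with(subset(meta, modality == "bone" & condition == "baseline"),
                       tapply(frequency, ear, length))
  expect_true(all(per_ear_air == 7))
  expect_true(all(per_ear_bone == 6))

  study2 <- generate_study(cfg)
  expect_identical(study2$ground_truth, study$ground_truth)
  expect_identical(study2$series[[5]]$traces, study$series[[5]]$traces)
})

test_that("fast-mode averaged noise RMS is the single-trial RMS over sqrt(n)", {
  cfg <- tiny_config(seed = 3)
  sim <- cfg$simulation
  sim$seed <- NULL
  set.seed(91)
  # sub-threshold cell: traces are pure averaged noise
  row <- list(ear_id = "x", condition = "baseline", modality = "air",
              frequency_hz = 1000, true_db = 1e6, max_output_db = 100)
  s <- capshift:::generate_growth_series(row, sim)
  rms <- sqrt(mean(s$traces^2))
  expect_equal(rms, sim$noise_rms_uv / sqrt(sim$n_averages), tolerance = 0.05)
})

test_that("noise-free growth is monotone in level", {
  cfg <- tiny_config()
  sim <- cfg$simulation
  sim$noise_rms_uv <- 1e-9
  row <- list(ear_id = "x", condition = "baseline", modality = "air",
              frequency_hz = 2000, true_db = 35, max_output_db = 100)
  s <- capshift:::generate_growth_series(row, sim)
  win <- window_config()
  pp <- vapply(seq_along(s$levels), function(i) {
    peak_to_peak(cap_trace(s$traces[i, ], s$fs), win$response)
  }, numeric(1))
  # levels descend, so peak-to-peak must be non-increasing down the rows
  expect_true(all(diff(pp) <= 1e-9))
})

test_that("raw-trial mode agrees with fast mode up to the noise floor", {
  cfg <- tiny_config(seed = 13)
  cfg$simulation$fast_mode <- FALSE
  cfg$simulation$n_averages <- 8L
  cfg$simulation$frequencies <- list(air = c(1000, 2000))
  cfg$simulation$max_output <- list(air = c("1000" = 60, "2000" = 60))
  cfg$simulation$baseline_mean <- list(air = c("1000" = 25, "2000" = 20))
  study <- generate_study(cfg)
  s <- study$series[[1]]
  truth <- study$ground_truth[1, ]
  # averaged raw trials contain the CAP plus reduced noise; the CAP at the
  # top level should dominate and match the deterministic component
  det <- capshift:::epoch_deterministic(truth$frequency_hz, s$levels[1],
                                        truth$true_db, cfg$simulation, 0,
                                        with_artifact = FALSE)
  resid <- s$traces[1, ] - det
  expect_lt(sqrt(mean(resid^2)),
            3 * cfg$simulation$noise_rms_uv / sqrt(8))
})
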