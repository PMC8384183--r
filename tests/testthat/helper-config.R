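# desk-scale configurations used across the suite

# full study design at a reduced sampling rate (fast mode needs only the
# 300-3000 Hz recording band)
desk_config <- function(seed = NULL, modalities = c("air", "bone")) {
  cfg <- default_config()
  cfg$simulation$sampling_rate <- 25000
  cfg$simulation$seed <- seed
  cfg$simulation$modalities <- modalities
  cfg
}

# minimal study: 3 baseline ears, one per single-severing arm, 2 both-severed
tiny_config <- function(seed = 1, modalities = "air") {
  cfg <- desk_config(seed, modalities)
  cfg$simulation$n_ears <- list(baseline = 3L, amp = 1L, pil = 1L, both = 2L)
  cfg
}

# a flat trace to build test signals on
flat_trace <- function(fs = 25000) cap_trace(numeric(round(0.049 * fs)), fs)

# threshold table built directly from vectors
make_table <- function(ear_id, condition, threshold_db, modality = "air",
                       frequency_hz = 1000, censored = FALSE) {
  tibble::tibble(ear_id = ear_id, condition = condition,
                 modality = modality, frequency_hz = frequency_hz,
                 threshold_db = threshold_db, censored = censored)
}
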