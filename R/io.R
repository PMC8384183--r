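threshold_columns <- c("ear_id", "condition", "modality", "frequency_hz",
                       "threshold_db", "censored")

#' Write and read threshold tables as CSV
#'
#' The on-disk schema has the six canonical columns `ear_id`, `condition`
#' (`baseline`/`amp`/`pil`/`both`), `modality` (`air`/`bone`),
#' `frequency_hz`, `threshold_db`, `censored` (0/1); extra columns are
#' preserved. Air thresholds are written in dB SPL as stored. Bone
#' thresholds are kept internally on a "higher = worse" axis and are
#' converted to dB attenuation (`attenuation = -internal`) on write and
#' back on read; the conversion is documented in a `#` comment line at the
#' top of the file. A write/read round trip restores the table exactly.
#'
#' @param table Threshold table tibble.
#' @param path CSV file path.
#' @return `write_threshold_table()` returns `path` invisibly;
#'   `read_threshold_table()` returns the tibble on the internal scale.
#' @export
write_threshold_table <- function(table, path) {
  check_threshold_table(table)
  out <- as.data.frame(table)
  bone <- out$modality == "bone"
  out$threshold_db[bone] <- -out$threshold_db[bone]
  out$censored <- as.integer(out$censored)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(
    "# CAP threshold table; air thresholds in dB SPL;",
    "bone thresholds in dB attenuation (internal level = -attenuation)"),
    con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  missing <- setdiff(threshold_columns, names(raw))
  if (length(missing) > 0) {
    stop("threshold table file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$threshold_db)) {
    stop("threshold_db column contains non-numeric values", call. = FALSE)
  }
  key <- paste(raw$ear_id, raw$condition, raw$modality, raw$frequency_hz)
  if (anyDuplicated(key)) {
    stop("duplicate (ear, condition, modality, frequency) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  bone <- raw$modality == "bone"
  raw$threshold_db[bone] <- -raw$threshold_db[bone]
  raw$censored <- as.logical(raw$censored)
  tibble::as_tibble(raw)
}

#' Write the ground-truth registry of a study
#'
#' @param truth Ground-truth tibble from [draw_ground_truth()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' Write and read a study dataset container
#'
#' The container is a directory holding one columnar text trace file per
#' (cell, level) under `traces/`, a `manifest.csv` indexing them, and the
#' ground-truth registry as `ground_truth.csv`. Intended for small studies
#' and for handing data between the `simulate` and `detect` pipeline
#' stages; desk-scale analyses normally stay in memory.
#'
#' @param study A `cap_study` from [generate_study()].
#' @param dir Directory to create.
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns
#'   a `cap_study` (without the generating config's seed state).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cap_study"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(study$series), function(i) {
    s <- study$series[[i]]
    files <- sprintf("traces/s%04d_L%03d.txt", i, seq_along(s$levels))
    for (j in seq_along(s$levels)) {
      write_trace(cap_trace(s$traces[j, ], s$fs), file.path(dir, files[j]))
    }
    data.frame(series = i, ear_id = s$ear_id, condition = s$condition,
               modality = s$modality, frequency_hz = s$frequency_hz,
               level_db = s$levels, max_output_db = s$max_output_db,
               file = files)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_ground_truth(study$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  truth <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "ground_truth.csv"),
                    stringsAsFactors = FALSE))
  series <- lapply(split(manifest, manifest$series), function(m) {
    m <- m[order(-m$level_db), ]
    traces <- do.call(rbind, lapply(m$file, function(f) {
      read_trace(file.path(dir, f))$samples
    }))
    fs <- read_trace(file.path(dir, m$file[1]))$fs
    growth_series(traces, m$level_db, fs, ear_id = m$ear_id[1],
                  condition = m$condition[1], modality = m$modality[1],
                  frequency_hz = m$frequency_hz[1],
                  max_output_db = m$max_output_db[1])
  })
  structure(list(ground_truth = truth, series = unname(series),
                 config = NULL),
            class = "cap_study")
}

#' Write the tables of a statistical report
#'
#' Writes `summary.csv`, `anova.csv` and `tukey.csv` for one modality's
#' [stats_report()].
#'
#' @param report A `stats_report`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix (e.g. the modality).
#' @return The directory, invisibly.
#' @export
write_stats_report <- function(report, dir, prefix = report$modality) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(name) file.path(dir, paste0(prefix, "_", name))
  utils::write.csv(as.data.frame(report$summary), path("summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$anova), path("anova.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$tukey$pairs), path("tukey.csv"),
                   row.names = FALSE)
  invisible(dir)
}
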