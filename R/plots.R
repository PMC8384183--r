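#' Plot threshold-shift panels
#'
#' One panel per severing condition: individual-ear shift curves in grey
#' and the pooled mean with a +/- 1 SD ribbon in black, against a log2
#' frequency axis — the standard presentation of conductive-loss data.
#'
#' @param shifts Shift table from [build_shift_table()].
#' @param modality `"air"` or `"bone"`.
#' @return A ggplot object.
#' @export
plot_shift_panels <- function(shifts, modality = "air") {
  dat <- dplyr::filter(shifts, .data$modality == !!modality)
  if (nrow(dat) == 0) stop("no shifts for modality '", modality, "'",
                           call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(dat, .data$condition, .data$frequency_hz),
    mean_db = mean(.data$shift_db), sd_db = stats::sd(.data$shift_db),
    .groups = "drop"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frequency_hz)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$shift_db,
                                    group = .data$ear_id),
                       colour = "grey70") +
    ggplot2::geom_ribbon(
      data = dplyr::filter(means, !is.na(.data$sd_db)),
      ggplot2::aes(ymin = .data$mean_db - .data$sd_db,
                   ymax = .data$mean_db + .data$sd_db),
      alpha = 0.2) +
    ggplot2::geom_line(data = means, ggplot2::aes(y = .data$mean_db),
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(dat$frequency_hz),
                                labels = function(x) x / 1000) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Frequency (kHz)",
                  y = "Threshold shift re baseline (dB)",
                  title = paste(modality, "conduction threshold shifts")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative threshold curves
#'
#' Per-condition step curves of the percentage of ears at or below
#' threshold versus stimulus level, one panel per frequency.
#'
#' @param curves Output of [cumulative_curves()].
#' @return A ggplot object.
#' @export
plot_cumulative_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$level_db, y = .data$pct,
                               colour = .data$condition)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~frequency_hz, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Stimulus level (dB)",
                  y = "Ears at/below threshold (%)",
                  colour = "Condition") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
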