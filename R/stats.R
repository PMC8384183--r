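check_threshold_table <- function(thresholds) {
  needed <- c("ear_id", "condition", "modality", "frequency_hz",
              "threshold_db", "censored")
  missing <- setdiff(needed, names(thresholds))
  if (length(missing) > 0) {
    stop("threshold table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(thresholds)
}

#' Build the threshold-shift table
#'
#' Differences each non-baseline condition threshold against the same
#' ear/modality/frequency baseline threshold: `shift = condition -
#' baseline`, positive meaning hearing got worse (for both modalities,
#' thanks to the internal bone level convention). Censored measurements
#' enter at their substituted maximum-output value and are flagged.
#'
#' @param thresholds Threshold table tibble (see [detect_study()]).
#' @return A tibble with `ear_id`, `modality`, `frequency_hz`, `condition`,
#'   `shift_db`, `either_censored`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   ear_id = "ear01", condition = c("baseline", "both"), modality = "air",
#'   frequency_hz = 1000, threshold_db = c(30, 55), censored = FALSE)
#' build_shift_table(tab)
build_shift_table <- function(thresholds) {
  check_threshold_table(thresholds)
  base <- dplyr::filter(thresholds, .data$condition == "baseline")
  cond <- dplyr::filter(thresholds, .data$condition != "baseline")
  if (nrow(cond) == 0) {
    stop("threshold table has no non-baseline conditions", call. = FALSE)
  }
  joined <- dplyr::left_join(
    cond, dplyr::select(base, "ear_id", "modality", "frequency_hz",
                        baseline_db = "threshold_db",
                        baseline_censored = "censored"),
    by = c("ear_id", "modality", "frequency_hz")
  )
  if (anyNA(joined$baseline_db)) {
    bad <- dplyr::filter(joined, is.na(.data$baseline_db))
    stop("missing baseline threshold for ",
         paste(unique(paste(bad$ear_id, bad$modality, bad$frequency_hz)),
               collapse = "; "), call. = FALSE)
  }
  dplyr::transmute(
    joined,
    ear_id = .data$ear_id, modality = .data$modality,
    frequency_hz = .data$frequency_hz, condition = .data$condition,
    shift_db = .data$threshold_db - .data$baseline_db,
    either_censored = .data$censored | .data$baseline_censored
  )
}

#' Summarize threshold shifts per condition
#'
#' Pooled arithmetic mean and sample SD of the shifts over all (ear,
#' frequency) measurements, the summary the study reports per condition
#' (e.g. "23 dB +/- 26 dB with both attachments severed").
#'
#' @param shifts A shift table from [build_shift_table()].
#' @param modality,condition Optional filters; by default all present
#'   combinations are summarized.
#' @return A tibble with `modality`, `condition`, `mean_db`, `sd_db`, `n`.
#' @export
summarize_shifts <- function(shifts, modality = NULL, condition = NULL) {
  if (!is.null(modality)) {
    shifts <- dplyr::filter(shifts, .data$modality %in% !!modality)
  }
  if (!is.null(condition)) {
    shifts <- dplyr::filter(shifts, .data$condition %in% !!condition)
  }
  if (nrow(shifts) < 2) {
    stop("need at least two shift measurements to summarize", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(shifts, .data$modality, .data$condition),
    mean_db = mean(.data$shift_db),
    sd_db = stats::sd(.data$shift_db),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Two-way ANOVA on CAP thresholds
#'
#' Fixed-effects ANOVA of raw thresholds on severing condition and
#' frequency (both as factors) with their interaction, using Type-II sums
#' of squares for the unbalanced design. Baseline is one of the condition
#' levels, so censored max-output substitutions and baseline cells enter
#' exactly as measured. Cohen's f is derived from partial eta squared:
#' `f = sqrt(SS_effect / SS_residual)`.
#'
#' If all observations are identical there is no variance to partition;
#' by convention F is reported as 0 and p as 1. If frequency has a single
#' level the model reduces to a one-way ANOVA on condition.
#'
#' @param thresholds Threshold table tibble.
#' @param modality `"air"` or `"bone"`; analysed separately.
#' @param ss_type Sum-of-squares type passed to [car::Anova()].
#' @return A tibble with one row per term (`condition`, `frequency`,
#'   `condition:frequency`): `df`, `sum_sq`, `f`, `p`, `cohens_f`.
#' @export
threshold_anova <- function(thresholds, modality = "air", ss_type = 2) {
  check_threshold_table(thresholds)
  dat <- dplyr::filter(thresholds, .data$modality == !!modality)
  if (nrow(dat) == 0) stop("no rows for modality '", modality, "'",
                           call. = FALSE)
  dat$condition <- factor(dat$condition)
  dat$frequency <- factor(dat$frequency_hz)
  if (nlevels(dat$condition) < 2) {
    stop("ANOVA needs at least two condition levels", call. = FALSE)
  }
  single_freq <- nlevels(dat$frequency) < 2
  form <- if (single_freq) threshold_db ~ condition
          else threshold_db ~ condition * frequency
  fit <- stats::lm(form, data = dat)
  if (stats::df.residual(fit) < 1) {
    stop("degenerate design: no residual degrees of freedom", call. = FALSE)
  }

  ss_res <- sum(stats::residuals(fit)^2)
  if (stats::var(dat$threshold_db) == 0) {
    # no variance to partition: report F = 0, p = 1 by convention
    terms <- if (single_freq) "condition"
             else c("condition", "frequency", "condition:frequency")
    dfs <- c(nlevels(dat$condition) - 1, nlevels(dat$frequency) - 1,
             (nlevels(dat$condition) - 1) * (nlevels(dat$frequency) - 1))
    out <- tibble::tibble(term = terms, df = dfs[seq_along(terms)],
                          sum_sq = 0, f = 0, p = 1, cohens_f = 0)
    attr(out, "residual_df") <- stats::df.residual(fit)
    attr(out, "residual_ms") <- 0
    return(out)
  }
  tab <- car::Anova(fit, type = ss_type)
  terms <- setdiff(rownames(tab), "Residuals")
  out <- tibble::tibble(
    term = terms,
    df = tab[terms, "Df"],
    sum_sq = tab[terms, "Sum Sq"],
    f = tab[terms, "F value"],
    p = tab[terms, "Pr(>F)"],
    cohens_f = sqrt(pmax(0, tab[terms, "Sum Sq"]) / ss_res)
  )
  attr(out, "residual_df") <- stats::df.residual(fit)
  attr(out, "residual_ms") <- ss_res / stats::df.residual(fit)
  out
}

#' Tukey-Kramer pairwise comparisons over condition-by-frequency cells
#'
#' Studentized-range pairwise tests generalized to unequal cell sizes.
#' Every pair of condition x frequency cells (means `m_i`, sizes `n_i`) is
#' compared with
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`,
#' where MSE is the residual mean square of the cell-means model, and the
#' adjusted p-value comes from the studentized-range distribution with the
#' number of cells and the residual degrees of freedom. Self-pairs carry
#' p = 1 by convention.
#'
#' @param thresholds Threshold table tibble.
#' @param modality `"air"` or `"bone"`.
#' @param by `"cell"` (default) compares condition x frequency cells;
#'   `"condition"` pools frequencies and compares conditions only.
#' @return A list with `p` and `q` (symmetric matrices over cells) and
#'   `pairs`, a tidy tibble of the upper triangle with cell means, sizes,
#'   `q` and `p_adj`.
#' @export
tukey_kramer <- function(thresholds, modality = "air",
                         by = c("cell", "condition")) {
  check_threshold_table(thresholds)
  by <- match.arg(by)
  dat <- dplyr::filter(thresholds, .data$modality == !!modality)
  if (nrow(dat) == 0) stop("no rows for modality '", modality, "'",
                           call. = FALSE)
  dat$cell <- if (by == "cell") {
    interaction(dat$condition, dat$frequency_hz, sep = "@", drop = TRUE)
  } else {
    factor(dat$condition)
  }
  k <- nlevels(dat$cell)
  if (k < 2) stop("need at least two cells to compare", call. = FALSE)
  sizes <- table(dat$cell)
  if (any(sizes == 0)) stop("empty cell in the design", call. = FALSE)
  means <- tapply(dat$threshold_db, dat$cell, mean)

  fit <- stats::lm(threshold_db ~ cell, data = dat)
  df_res <- stats::df.residual(fit)
  if (df_res < 1) stop("no residual degrees of freedom for MSE",
                       call. = FALSE)
  mse <- sum(stats::residuals(fit)^2) / df_res

  q <- matrix(0, k, k, dimnames = list(names(means), names(means)))
  p <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
      qij <- if (se == 0) 0 else abs(means[i] - means[j]) / se
      q[i, j] <- q[j, i] <- qij
      pij <- if (qij == 0) 1
             else stats::ptukey(qij, nmeans = k, df = df_res,
                                lower.tail = FALSE)
      p[i, j] <- p[j, i] <- pij
    }
  }
  pairs <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    do.call(rbind, lapply((i + 1):k, function(j) {
      data.frame(cell_a = names(means)[i], cell_b = names(means)[j],
                 mean_a = unname(means[i]), mean_b = unname(means[j]),
                 n_a = as.integer(sizes[i]), n_b = as.integer(sizes[j]),
                 q = q[i, j], p_adj = p[i, j])
    }))
  }))
  list(p = p, q = q, pairs = tibble::as_tibble(pairs),
       mse = mse, df = df_res, k = k)
}

#' Cumulative threshold curves
#'
#' Per-condition empirical cumulative distributions of thresholds: the
#' percentage of ears in each group whose CAP threshold is at or below
#' (i.e. reached at or before) a given stimulus level. The curves are
#' right-continuous step functions on the level grid. Censored ears carry
#' the substituted maximum-output value, so they count as having reached
#' threshold only at that level.
#'
#' @param thresholds Threshold table tibble.
#' @param modality `"air"` or `"bone"`.
#' @param frequency Optional frequency in Hz; `NULL` evaluates every
#'   frequency present.
#' @param levels Optional evaluation grid; defaults to the 5 dB grid
#'   spanning the observed thresholds.
#' @return A tibble with `modality`, `frequency_hz`, `condition`,
#'   `level_db`, `pct` (0--100, non-decreasing in level within a curve).
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   ear_id = sprintf("ear%02d", 1:4), condition = "baseline",
#'   modality = "air", frequency_hz = 1000,
#'   threshold_db = c(20, 30, 30, 40), censored = FALSE)
#' curves <- cumulative_curves(tab, "air", 1000)
#' curves$pct[curves$level_db == 30]  # 75
cumulative_curves <- function(thresholds, modality = "air",
                              frequency = NULL, levels = NULL) {
  check_threshold_table(thresholds)
  dat <- dplyr::filter(thresholds, .data$modality == !!modality)
  if (!is.null(frequency)) {
    dat <- dplyr::filter(dat, .data$frequency_hz %in% !!frequency)
  }
  if (nrow(dat) == 0) stop("no thresholds selected", call. = FALSE)
  if (is.null(levels)) {
    rng <- range(dat$threshold_db)
    levels <- seq(5 * floor(rng[1] / 5), 5 * ceiling(rng[2] / 5), by = 5)
  }
  grid <- tidyr::expand_grid(
    dplyr::distinct(dat, .data$frequency_hz, .data$condition),
    level_db = levels
  )
  out <- dplyr::group_by(
    dplyr::left_join(grid, dat, by = c("frequency_hz", "condition"),
                     relationship = "many-to-many"),
    .data$frequency_hz, .data$condition, .data$level_db
  )
  out <- dplyr::summarise(
    out, pct = 100 * mean(.data$threshold_db <= .data$level_db),
    .groups = "drop"
  )
  dplyr::arrange(
    tibble::add_column(out, modality = modality, .before = 1),
    .data$frequency_hz, .data$condition, .data$level_db
  )
}

#' Full statistical report for one modality
#'
#' Bundles the per-condition shift summaries, the two-way ANOVA with
#' Cohen's f, and the Tukey-Kramer pairwise matrix.
#'
#' @param thresholds Threshold table tibble.
#' @param modality `"air"` or `"bone"`.
#' @param ss_type Sum-of-squares type for the ANOVA.
#' @return A list of class `stats_report` with `modality`, `summary`,
#'   `anova`, `tukey`.
#' @export
stats_report <- function(thresholds, modality = "air", ss_type = 2) {
  shifts <- build_shift_table(thresholds)
  structure(
    list(
      modality = modality,
      summary = summarize_shifts(shifts, modality = modality),
      anova = threshold_anova(thresholds, modality, ss_type = ss_type),
      tukey = tukey_kramer(thresholds, modality)
    ),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> modality:", x$modality, "\n\nShift summaries:\n")
  print(x$summary)
  cat("\nANOVA (Type II):\n")
  print(x$anova)
  cat("\nTukey-Kramer:", nrow(x$tukey$pairs), "cell pairs, MSE =",
      signif(x$tukey$mse, 4), "on", x$tukey$df, "df\n")
  invisible(x)
}
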