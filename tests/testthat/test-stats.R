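test_that("shift table differences condition against baseline per cell", {
  tab <- make_table(
    ear_id = rep("ear01", 3),
    condition = c("baseline", "both", "amp"),
    threshold_db = c(30, 55, 70),
    censored = c(FALSE, FALSE, TRUE)
  )
  sh <- build_shift_table(tab)
  expect_equal(sh$shift_db[sh$condition == "both"], 25)
  # censored condition measurement: substituted value used, flag propagated
  expect_equal(sh$shift_db[sh$condition == "amp"], 40)
  expect_true(sh$either_censored[sh$condition == "amp"])
  expect_false(sh$either_censored[sh$condition == "both"])

  # identical tables difference to zero
  same <- make_table(rep(c("e1", "e2"), each = 2),
                     rep(c("baseline", "both"), 2), rep(50, 4))
  expect_true(all(build_shift_table(same)$shift_db == 0))

  # missing baseline is an error naming the cell
  nobase <- make_table("e1", "both", 60)
  expect_error(build_shift_table(nobase), "missing baseline")
})

test_that("shift summaries pool ears and frequencies", {
  tab <- make_table(
    ear_id = rep(c("e1", "e2"), each = 2),
    condition = rep(c("baseline", "both"), 2),
    threshold_db = c(30, 50, 30, 56)
  )
  s <- summarize_shifts(build_shift_table(tab))
  expect_equal(s$mean_db, 23)
  expect_equal(s$sd_db, sd(c(20, 26)))  # ~4.243
  expect_equal(s$n, 2L)

  const <- make_table(rep(c("e1", "e2"), each = 2),
                      rep(c("baseline", "both"), 2), c(10, 17, 25, 32))
  s2 <- summarize_shifts(build_shift_table(const))
  expect_equal(s2$mean_db, 7)
  expect_equal(s2$sd_db, 0)
})

test_that("ANOVA on identical observations reports F = 0, p = 1 by convention", {
  tab <- make_table(
    ear_id = rep(sprintf("e%d", 1:4), 2),
    condition = rep(c("baseline", "both"), each = 4),
    threshold_db = 40,
    frequency_hz = rep(c(1000, 2000), 4)
  )
  a <- threshold_anova(tab, "air")
  expect_true(all(a$f == 0))
  expect_true(all(a$p == 1))
  expect_true(all(a$cohens_f == 0))
})

test_that("with one frequency and two balanced groups F equals t squared", {
  set.seed(41)
  x <- rnorm(8, 30, 5)
  y <- rnorm(8, 45, 5)
  tab <- make_table(sprintf("e%02d", 1:16),
                    rep(c("baseline", "both"), each = 8),
                    c(x, y))
  a <- threshold_anova(tab, "air")
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(a$f[a$term == "condition"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$term == "condition"], tt$p.value, tolerance = 1e-10)

  # Cohen's f from partial eta squared: f^2 = SS_effect / SS_residual
  ss_res <- attr(a, "residual_ms") * attr(a, "residual_df")
  expect_equal(a$cohens_f, sqrt(a$sum_sq / ss_res))
})

test_that("sums of squares decompose exactly on a balanced design", {
  set.seed(43)
  tab <- make_table(
    ear_id = rep(sprintf("e%02d", 1:12), times = 2),
    condition = rep(rep(c("baseline", "amp", "both"), each = 4), 2),
    threshold_db = rnorm(24, 30, 8),
    frequency_hz = rep(c(1000, 4000), each = 12)
  )
  a <- threshold_anova(tab, "air")
  fit_ss <- sum(a$sum_sq)
  total_ss <- sum((tab$threshold_db - mean(tab$threshold_db))^2)
  ss_res <- attr(a, "residual_ms") * attr(a, "residual_df")
  expect_equal(fit_ss + ss_res, total_ss, tolerance = 1e-8)
})

test_that("Tukey-Kramer reduces to the pooled t test for two cells", {
  set.seed(47)
  x <- rnorm(6, 20, 4)
  y <- rnorm(6, 28, 4)
  tab <- make_table(sprintf("e%02d", 1:12),
                    rep(c("baseline", "both"), each = 6), c(x, y))
  tk <- tukey_kramer(tab, "air")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$pairs$q, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  # for k = 2 the studentized-range p equals the two-sided t p
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("identical cell means give adjusted p of 1 and self-pairs are 1", {
  tab <- make_table(
    ear_id = sprintf("e%02d", 1:12),
    condition = rep(c("baseline", "amp", "both"), each = 4),
    threshold_db = rep(c(10, 20, 30, 40), times = 3)
  )
  tk <- tukey_kramer(tab, "air")
  expect_true(all(abs(tk$p - 1) < 1e-10))
  expect_true(all(diag(tk$p) == 1))
  expect_equal(tk$p, t(tk$p))
})

test_that("Tukey-Kramer matrix permutes with cell relabelling", {
  set.seed(53)
  tab <- make_table(
    ear_id = sprintf("e%02d", 1:18),
    condition = rep(c("baseline", "amp", "both"), each = 6),
    threshold_db = rnorm(18, 30, 10)
  )
  tk1 <- tukey_kramer(tab, "air", by = "condition")
  relabel <- c(baseline = "both", amp = "baseline", both = "amp")
  tab2 <- tab
  tab2$condition <- unname(relabel[tab$condition])
  tk2 <- tukey_kramer(tab2, "air", by = "condition")
  perm <- unname(relabel[rownames(tk1$p)])
  expect_equal(tk2$p[perm, perm], `dimnames<-`(tk1$p, list(perm, perm)),
               tolerance = 1e-12)
})

test_that("cumulative curves step through the expected percentages", {
  tab <- make_table(sprintf("e%d", 1:4), "baseline", c(20, 30, 30, 40))
  cc <- cumulative_curves(tab, "air", 1000, levels = seq(15, 45, by = 5))
  expect_equal(cc$pct[cc$level_db == 30], 75)
  expect_equal(cc$pct[cc$level_db == 45], 100)  # above the maximum threshold
  expect_equal(cc$pct[cc$level_db == 15], 0)    # below the minimum

  # monotone non-decreasing from 0 to 100 within every curve
  study_tab <- simulate_threshold_table(desk_config(seed = 59,
                                                    modalities = "air"))
  curves <- cumulative_curves(study_tab, "air")
  by_curve <- split(curves, list(curves$condition, curves$frequency_hz),
                    drop = TRUE)
  expect_true(all(vapply(by_curve, function(d) {
    all(diff(d$pct[order(d$level_db)]) >= 0)
  }, logical(1))))
})

test_that("the paper-scale severing effect is detected with near certainty", {
  rejections <- vapply(1:5, function(i) {
    tab <- simulate_threshold_table(desk_config(seed = 600 + i,
                                                modalities = "air"))
    a <- threshold_anova(tab, "air")
    a$p[a$term == "condition"] < 0.05
  }, logical(1))
  expect_true(all(rejections))
})

test_that("stats_report bundles summaries, ANOVA and post hoc for a modality", {
  tab <- simulate_threshold_table(desk_config(seed = 61, modalities = "air"))
  rep <- stats_report(tab, "air")
  expect_s3_class(rep, "stats_report")
  expect_equal(nrow(rep$summary), 3)
  expect_true(all(c("condition", "frequency", "condition:frequency")
                  %in% rep$anova$term))
  expect_equal(rep$tukey$k, 28)  # 4 conditions x 7 frequencies
  expect_error(threshold_anova(make_table("e1", "baseline", 30), "air"),
               "two condition levels")
})
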