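mk_table <- function(values_by_cell) {
  rows <- NULL
  for (nm in names(values_by_cell)) {
    parts <- strsplit(nm, "_")[[1]]
    v <- values_by_cell[[nm]]
    rows <- rbind(rows, data.frame(
      specimen_id = paste0(nm, "_", seq_along(v)), group = parts[1],
      time_weeks = as.numeric(parts[2]), metric = "m", value = v))
  }
  class(rows) <- c("outcome_table", "data.frame")
  rows
}

test_that("constant outcomes give F ~ 0 and p ~ 1 for every effect", {
  tab <- mk_table(list(SCI_1 = rep(5, 3), SHAM_1 = rep(5, 3),
                       SCI_2 = rep(5, 3), SHAM_2 = rep(5, 3)))
  an <- two_way_anova(tab, "m")
  expect_equal(an$F, rep(0, 3))
  expect_equal(an$p, rep(1, 3))
})

test_that("type II sums of squares match a direct projection oracle", {
  set.seed(3)
  tab <- mk_table(list(SCI_1 = rnorm(4, 10), SHAM_1 = rnorm(4, 12),
                       SCI_2 = rnorm(4, 11), SHAM_2 = rnorm(4, 13)))
  an <- two_way_anova(tab, "m")
  # balanced design: type II == classic sequential decomposition
  d <- tab
  d$group <- factor(d$group); d$time <- factor(d$time_weeks)
  y <- d$value
  gm <- mean(y)
  ss_group <- sum(tapply(y, d$group, function(v) length(v) *
                                       (mean(v) - gm)^2))
  ss_time <- sum(tapply(y, d$time, function(v) length(v) *
                                      (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(d$group, d$time), mean)
  ss_cells <- sum(table(interaction(d$group, d$time)) * (cellm - gm)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_res <- sum((y - ave(y, interaction(d$group, d$time)))^2)
  fit <- lm(value ~ group * time, data = d)
  an2 <- car::Anova(fit, type = 2)
  expect_equal(an2["group", "Sum Sq"], ss_group, tolerance = 1e-10)
  expect_equal(an2["time", "Sum Sq"], ss_time, tolerance = 1e-10)
  expect_equal(an2["group:time", "Sum Sq"], ss_int, tolerance = 1e-10)
  # and the total decomposes exactly on the balanced design
  expect_equal(ss_group + ss_time + ss_int + ss_res,
               sum((y - gm)^2), tolerance = 1e-10)
  # the reported F agree with the oracle ratios
  expect_equal(an$F[an$effect == "group"],
               (ss_group / 1) / (ss_res / an$df_resid[1]),
               tolerance = 1e-10)
})

test_that("a pure group shift inflates only the group effect", {
  set.seed(9)
  base <- list(SCI_1 = rnorm(5, 10, 0.5), SHAM_1 = rnorm(5, 10, 0.5),
               SCI_2 = rnorm(5, 10, 0.5), SHAM_2 = rnorm(5, 10, 0.5))
  an0 <- two_way_anova(mk_table(base), "m")
  shifted <- base
  shifted$SCI_1 <- shifted$SCI_1 + 5
  shifted$SCI_2 <- shifted$SCI_2 + 5
  an1 <- two_way_anova(mk_table(shifted), "m")
  expect_gt(an1$F[an1$effect == "group"], 10 * an0$F[an0$effect == "group"])
  expect_lt(an1$p[an1$effect == "group"], 0.001)
  expect_gt(an1$p[an1$effect == "time"], 0.05)
})

test_that("empty design cells are reported by name", {
  tab <- mk_table(list(SCI_1 = rnorm(3), SHAM_2 = rnorm(3)))
  expect_error(two_way_anova(tab, "m"), "empty design cells")
})

test_that("Tukey HSD matches the studentized-range oracle", {
  set.seed(21)
  tab <- mk_table(list(SCI_1 = rnorm(6, 10), SHAM_1 = rnorm(6, 11),
                       Ctrl_1 = rnorm(6, 12)))
  tk <- tukey_hsd(tab, "m", factor = "group")
  expect_equal(nrow(tk), 3)
  # oracle: q statistic against ptukey with the one-way MSE
  d <- tab; d$group <- factor(d$group)
  mse <- sum(tapply(d$value, d$group,
                    function(v) sum((v - mean(v))^2))) / (18 - 3)
  means <- tapply(d$value, d$group, mean)
  for (r in seq_len(nrow(tk))) {
    lv <- strsplit(tk$comparison[r], "-")[[1]]
    q <- abs(means[lv[1]] - means[lv[2]]) / sqrt(mse / 6)
    p_or <- 1 - ptukey(q, nmeans = 3, df = 15)
    expect_lt(abs(tk$p_adj[r] - p_or), 1e-3)
  }
  # adjusted p never below the unadjusted pairwise p
  for (r in seq_len(nrow(tk))) {
    lv <- strsplit(tk$comparison[r], "-")[[1]]
    tt <- t.test(d$value[d$group == lv[1]], d$value[d$group == lv[2]],
                 var.equal = TRUE)
    expect_gte(tk$p_adj[r] + 1e-9, tt$p.value * 0.999)
  }
  expect_error(tukey_hsd(mk_table(list(SCI_1 = rnorm(4))), "m", "group"),
               "2 levels")
})

test_that("equal group means give Tukey p -> 1", {
  tab <- mk_table(list(SCI_1 = c(1, 2, 3, 4), SHAM_1 = c(2, 3, 1, 4),
                       Ctrl_1 = c(4, 1, 3, 2)))
  tk <- tukey_hsd(tab, "m", "group")
  expect_true(all(tk$p_adj > 0.95))
})

test_that("targeted t-tests use pooled variance and the hand formula", {
  tab <- mk_table(list(SCI_1 = c(1, 2, 3), SHAM_1 = c(2, 3, 4)))
  tt <- targeted_t_tests(tab, "m", times = 1)
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  # identical samples: t = 0, p = 1, percent difference 0
  tab2 <- mk_table(list(SCI_2 = c(5, 6, 7), SHAM_2 = c(5, 6, 7)))
  tt2 <- targeted_t_tests(tab2, "m", times = 2)
  expect_equal(tt2$t, 0)
  expect_equal(tt2$p, 1)
  expect_equal(tt2$percent_difference, 0)
})

test_that("exactly three targeted comparisons are emitted per metric", {
  cells <- list()
  for (tw in c(1, 2, 4)) {
    cells[[paste0("SCI_", tw)]] <- rnorm(8, 10)
    cells[[paste0("SHAM_", tw)]] <- rnorm(6, 12)
  }
  tt <- targeted_t_tests(mk_table(cells), "m")
  expect_equal(nrow(tt), 3)
  expect_equal(tt$time_weeks, c(1, 2, 4))
  expect_true(all(is.finite(tt$p)))
})

test_that("percent difference is invariant to unit rescaling", {
  set.seed(2)
  cells <- list(SCI_4 = rnorm(8, 5), SHAM_4 = rnorm(6, 10))
  t1 <- targeted_t_tests(mk_table(cells), "m", times = 4)
  cells2 <- lapply(cells, function(v) v * 1000)
  t2 <- targeted_t_tests(mk_table(cells2), "m", times = 4)
  expect_equal(t1$percent_difference, t2$percent_difference,
               tolerance = 1e-9)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("cohort_report has one row per metric and time point", {
  set.seed(4)
  res <- NULL
  for (tw in c(1, 2, 4)) for (g in c("SCI", "SHAM"))
    res <- rbind(res, data.frame(
      specimen_id = paste0(g, tw, "_", 1:4), group = g, time_weeks = tw,
      BV_TV = rnorm(4, 0.2), Tb_Th_mm = rnorm(4, 0.08)))
  rep <- cohort_report(res, metrics = c("BV_TV", "Tb_Th_mm"))
  expect_equal(nrow(rep), 2 * 3)
  expect_true(all(c("mean_sci", "sd_sham", "percent_difference", "stars")
                  %in% names(rep)))
})

test_that("time0 handling switches between exclusion and replication", {
  set.seed(6)
  cells <- list(Time0_0 = rnorm(6, 10),
                SCI_1 = rnorm(8, 9), SHAM_1 = rnorm(6, 10),
                SCI_2 = rnorm(8, 8), SHAM_2 = rnorm(6, 10))
  an_ex <- two_way_anova(mk_table(cells), "m", time0 = "exclude")
  an_rep <- two_way_anova(mk_table(cells), "m", time0 = "replicate")
  expect_equal(nrow(an_ex), 3)
  expect_equal(nrow(an_rep), 3)
  # replication adds a third group level
  expect_equal(an_rep$df[an_rep$effect == "group"], 2)
  expect_equal(an_ex$df[an_ex$effect == "group"], 1)
})
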