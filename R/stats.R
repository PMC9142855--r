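# Group-comparison layer: factorial ANOVA with Tukey post hoc and the
# a priori SCI-vs-SHAM t-tests at matched time points.

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `""`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Assemble an outcome table
#'
#' Long-format table of scalar outcomes: one value per specimen and
#' metric, with group (`Time0`, `SCI`, `SHAM`) and time in weeks.
#'
#' @param specimen_id,group,time_weeks,metric,value equal-length vectors.
#' @return data.frame of class `outcome_table`.
#' @export
outcome_table <- function(specimen_id, group, time_weeks, metric, value) {
  d <- data.frame(specimen_id = as.character(specimen_id),
                  group = as.character(group),
                  time_weeks = as.numeric(time_weeks),
                  metric = as.character(metric),
                  value = as.numeric(value))
  if (anyDuplicated(d[c("specimen_id", "metric")]))
    stop("more than one value per specimen x metric")
  class(d) <- c("outcome_table", "data.frame")
  d
}

# wide results (one metric per column) -> long outcome rows for one metric
metric_long <- function(results, metric) {
  if (inherits(results, "outcome_table") ||
      all(c("metric", "value") %in% names(results))) {
    d <- results[results$metric == metric, , drop = FALSE]
  } else {
    if (!metric %in% names(results))
      stop("metric '", metric, "' not found in results")
    d <- data.frame(specimen_id = results$specimen_id,
                    group = results$group,
                    time_weeks = results$time_weeks,
                    metric = metric,
                    value = results[[metric]])
  }
  d[is.finite(d$value), , drop = FALSE]
}

#' Two-way factorial ANOVA (group x time)
#'
#' Fits `value ~ group * time` with both factors categorical and reports
#' Type II sums of squares, appropriate for the unbalanced SCI/SHAM
#' layout. Baseline animals (`Time0`) have no post-surgery time, so by
#' default they are excluded from the factorial model; with
#' `time0 = "replicate"` they are instead carried into every time level
#' as a common reference.
#'
#' @param table an [outcome_table()] or a wide results data.frame.
#' @param metric metric name.
#' @param time0 `"exclude"` (default) or `"replicate"`.
#' @return data.frame with one row per effect (`group`, `time`,
#'   `group:time`): `F`, `df`, `df_resid`, `p`.
#' @export
two_way_anova <- function(table, metric, time0 = c("exclude", "replicate")) {
  time0 <- match.arg(time0)
  d <- metric_long(table, metric)
  is0 <- d$group == "Time0"
  if (time0 == "exclude") {
    d <- d[!is0, , drop = FALSE]
  } else if (any(is0)) {
    reps <- do.call(rbind, lapply(sort(unique(d$time_weeks[!is0])),
                                  function(t) {
                                    r <- d[is0, , drop = FALSE]
                                    r$time_weeks <- t
                                    r
                                  }))
    d <- rbind(d[!is0, , drop = FALSE], reps)
  }
  d$group <- factor(d$group)
  d$time <- factor(d$time_weeks)
  cells <- table(d$group, d$time)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("%s x %s weeks", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "))
  }
  effects <- c("group", "time", "group:time")
  if (stats::var(d$value) == 0) {
    return(data.frame(effect = effects, F = 0,
                      df = c(nlevels(d$group) - 1, nlevels(d$time) - 1,
                             (nlevels(d$group) - 1) * (nlevels(d$time) - 1)),
                      df_resid = nrow(d) - nlevels(d$group) * nlevels(d$time),
                      p = 1))
  }
  fit <- stats::lm(value ~ group * time, data = d)
  an <- car::Anova(fit, type = 2)
  rows <- match(c("group", "time", "group:time"), rownames(an))
  data.frame(effect = effects,
             F = an[rows, "F value"],
             df = an[rows, "Df"],
             df_resid = an["Residuals", "Df"],
             p = an[rows, "Pr(>F)"])
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences among the levels of one factor with
#' studentized-range adjusted p-values, using the residual variance of the
#' `group * time` factorial fit.
#'
#' @param table an [outcome_table()] or wide results data.frame.
#' @param metric metric name.
#' @param factor `"group"` or `"time"`.
#' @param time0 passed to the factorial layout as in [two_way_anova()].
#' @return data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(table, metric, factor = c("group", "time"),
                      time0 = c("exclude", "replicate")) {
  factor <- match.arg(factor)
  time0 <- match.arg(time0)
  d <- metric_long(table, metric)
  if (time0 == "exclude") d <- d[d$group != "Time0", , drop = FALSE]
  d$group <- base::factor(d$group)
  d$time <- base::factor(d$time_weeks)
  which_var <- if (factor == "group") "group" else "time"
  if (nlevels(d[[which_var]]) < 2)
    stop("Tukey HSD needs at least 2 levels of ", which_var)
  form <- if (nlevels(d$group) > 1 && nlevels(d$time) > 1)
    value ~ group * time else stats::as.formula(paste("value ~", which_var))
  fit <- stats::aov(form, data = d)
  tk <- stats::TukeyHSD(fit, which = which_var)[[which_var]]
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Targeted SCI vs SHAM t-tests at matched time points
#'
#' The a priori comparisons: at each post-surgery time point, a pooled-
#' variance (Student's) two-sided t-test of SCI against SHAM, with the
#' percent difference `100 * (mean_SCI - mean_SHAM) / mean_SHAM`. No
#' multiplicity correction is applied across the time points.
#'
#' @param table an [outcome_table()] or wide results data.frame.
#' @param metric metric name.
#' @param times post-surgery time points, default `c(1, 2, 4)` weeks.
#' @return data.frame with one row per time point: means, `t`, `df`, `p`,
#'   `percent_difference`, `stars`. Cells with n < 2 are skipped with a
#'   warning.
#' @export
targeted_t_tests <- function(table, metric, times = c(1, 2, 4)) {
  d <- metric_long(table, metric)
  out <- lapply(times, function(tw) {
    a <- d$value[d$group == "SCI" & d$time_weeks == tw]
    b <- d$value[d$group == "SHAM" & d$time_weeks == tw]
    row <- data.frame(time_weeks = tw, n_sci = length(a), n_sham = length(b),
                      mean_sci = mean(a), mean_sham = mean(b),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      percent_difference = 100 * (mean(a) - mean(b)) / mean(b),
                      stars = "")
    if (length(a) < 2 || length(b) < 2) {
      warning("fewer than 2 specimens in a cell at week ", tw,
              "; test skipped")
      return(row)
    }
    if (stats::sd(c(a, b)) == 0) {
      row$t <- 0; row$df <- length(a) + length(b) - 2; row$p <- 1
      row$percent_difference <- 0
      return(row)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p <- tt$p.value
    row$stars <- p_stars(tt$p.value)
    row
  })
  do.call(rbind, out)
}

#' Effect summary of a cohort's pipeline results
#'
#' Per metric and post-surgery time point: SCI and SHAM group means and
#' SDs, percent difference, Student's t and significance stars. One row
#' per metric x time point.
#'
#' @param results wide results data.frame (as returned by
#'   [run_pipeline()]) with `specimen_id`, `group`, `time_weeks` and
#'   metric columns.
#' @param metrics metric column names; defaults to all numeric metric
#'   columns present.
#' @param times post-surgery time points.
#' @return data.frame effect summary.
#' @export
cohort_report <- function(results, metrics = NULL, times = c(1, 2, 4)) {
  if (is.null(metrics)) {
    reserved <- c("specimen_id", "group", "time_weeks", "region")
    metrics <- setdiff(names(results)[vapply(results, is.numeric,
                                             logical(1))],
                       c(reserved, "time_weeks"))
  }
  rows <- lapply(metrics, function(m) {
    d <- metric_long(results, m)
    do.call(rbind, lapply(times, function(tw) {
      a <- d$value[d$group == "SCI" & d$time_weeks == tw]
      b <- d$value[d$group == "SHAM" & d$time_weeks == tw]
      tt <- if (length(a) >= 2 && length(b) >= 2 &&
                stats::sd(c(a, b)) > 0)
        stats::t.test(a, b, var.equal = TRUE) else NULL
      data.frame(metric = m, time_weeks = tw,
                 mean_sci = mean(a), sd_sci = stats::sd(a),
                 mean_sham = mean(b), sd_sham = stats::sd(b),
                 percent_difference =
                   100 * (mean(a) - mean(b)) / mean(b),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 stars = if (is.null(tt)) "" else p_stars(tt$p.value))
    }))
  })
  do.call(rbind, rows)
}
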