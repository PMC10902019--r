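#' Paired sample of method-comparison values
#'
#' Convention throughout: `values_a` holds the TCD (measured) values and
#' `values_b` the CFD (simulated) values, so differences and Bland-Altman
#' biases are oriented TCD - CFD.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 3, finite).
#' @param ids optional participant identifiers.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(values_a, values_b, ids = NULL) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) != length(values_b))
    stop("values_a and values_b must have equal length")
  n <- length(values_a)
  if (n < 3L) stop("paired samples need n >= 3")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("paired values must all be finite")
  if (is.null(ids)) ids <- seq_len(n)
  structure(list(ids = ids, values_a = values_a, values_b = values_b, n = n),
            class = "paired_sample")
}

#' Paired t-test
#'
#' Two-sided Student t-test on the mean paired difference a - b:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with n - 1 degrees of freedom.
#'
#' @param s a [paired_sample()].
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(s) {
  if (!inherits(s, "paired_sample")) stop("s must be a paired_sample")
  d <- s$values_a - s$values_b
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("paired differences have zero variance (degenerate sample)")
  t <- mean(d) / (sd_d / sqrt(s$n))
  df <- s$n - 1L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = mean(d))
}

#' Pearson correlation with two-sided p-value
#'
#' \eqn{r} with the usual t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on
#' n - 2 degrees of freedom; `p = 0` at |r| = 1 exactly.
#'
#' @param s a [paired_sample()].
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(s) {
  if (!inherits(s, "paired_sample")) stop("s must be a paired_sample")
  if (stats::sd(s$values_a) == 0 || stats::sd(s$values_b) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(s$values_a, s$values_b)
  df <- s$n - 2L
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p, n = s$n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented a - b (TCD - CFD). Reports the bias (mean
#' difference), the SD of differences, 95% limits of agreement
#' (bias +/- 1.96 SD) and the proportional bias as the ordinary
#' least-squares slope of the differences on the pairwise means, with its
#' two-sided p-value.
#'
#' @param s a [paired_sample()]. When the analysis is of relative changes,
#'   `values_a`/`values_b` hold the per-participant percent changes and all
#'   outputs are in percentage points.
#' @param relative logical flag recording whether the inputs are relative
#'   changes (metadata only; the arithmetic is identical).
#' @param loa_multiplier multiplier for the limits of agreement (default 1.96).
#' @return an object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `proportional_bias_slope`, `proportional_bias_p`,
#'   `means`, `diffs`, `relative`.
#' @export
bland_altman <- function(s, relative = FALSE, loa_multiplier = 1.96) {
  if (!inherits(s, "paired_sample")) stop("s must be a paired_sample")
  d <- s$values_a - s$values_b
  m <- (s$values_a + s$values_b) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  if (stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    sl_p <- if (all(abs(stats::residuals(fit)) < 1e-12 * max(1, abs(slope))))
      0 else summary(fit)$coefficients[2, 4]
  } else {
    slope <- 0
    sl_p <- NA_real_
  }
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = bias - loa_multiplier * sd_d,
                 loa_high = bias + loa_multiplier * sd_d,
                 proportional_bias_slope = slope,
                 proportional_bias_p = sl_p,
                 means = m, diffs = d, relative = relative),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  u <- if (x$relative) "% points" else ""
  cat(sprintf("<bland_altman> bias (TCD-CFD) %.3f%s, LoA [%.3f, %.3f], slope %.4f (p %s)\n",
              x$bias, u, x$loa_low, x$loa_high, x$proportional_bias_slope,
              format.pval(x$proportional_bias_p, digits = 3)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = "pairwise mean", ylab = "difference (TCD - CFD)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the established W-statistic routine; sample size must
#' lie in [3, 5000].
#'
#' @param x numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

metric_names <- c("systolic", "time_averaged", "end_diastolic")

get_metric <- function(cohort, condition, source, metric) {
  vapply(cohort, function(p) unclass(p$conditions[[condition]][[source]])[[metric]],
         numeric(1))
}

get_tcbf <- function(cohort, condition) {
  vapply(cohort, function(p) p$conditions[[condition]]$tcbf, numeric(1))
}

safe_paired_t <- function(a, b) {
  s <- paired_sample(a, b)
  if (stats::sd(a - b) == 0)
    return(list(t = NA_real_, df = length(a) - 1L, p = NA_real_,
                mean_diff = mean(a - b), degenerate = TRUE))
  c(paired_t(s), degenerate = FALSE)
}

safe_corr <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(a)))
  pearson_corr(paired_sample(a, b))
}

#' Long-form metric table for a cohort
#'
#' @param cohort list of participants; each participant is a list with `id`
#'   and `conditions`, where `conditions[[name]]` holds `cfd` and `tcd`
#'   [extract_metrics()] results and a scalar `tcbf` (mL/min).
#' @return data frame `participant,condition,source,systolic_cm_s,
#'   time_avg_cm_s,end_diastolic_cm_s,tcbf_ml_min`.
#' @export
study_metric_table <- function(cohort) {
  rows <- list()
  for (p in cohort) for (cond in names(p$conditions)) for (src in c("CFD", "TCD")) {
    m <- unclass(p$conditions[[cond]][[tolower(src)]])
    rows[[length(rows) + 1L]] <- data.frame(
      participant = p$id, condition = cond, source = src,
      systolic_cm_s = m[["systolic"]], time_avg_cm_s = m[["time_averaged"]],
      end_diastolic_cm_s = m[["end_diastolic"]],
      tcbf_ml_min = p$conditions[[cond]]$tcbf)
  }
  do.call(rbind, rows)
}

#' Full CFD-vs-TCD study comparison tables
#'
#' Assembles the method-agreement analysis for a cohort in which every
#' participant has CFD-simulated and TCD-measured M1 velocity metrics plus
#' tCBF under a resting condition and one or more stimulus conditions:
#' \itemize{
#'   \item absolute metric distributions (mean +/- SD per source) with paired
#'     TCD-vs-CFD t-tests per condition and metric, plus Shapiro-Wilk
#'     normality p-values of the paired differences;
#'   \item within-source stimulus-vs-rest paired tests;
#'   \item absolute TCD-vs-CFD Pearson correlations;
#'   \item tCBF-vs-velocity correlations per source, absolute and
#'     relative-change;
#'   \item relative-change (stimulus vs rest) distributions, paired tests and
#'     TCD-vs-CFD correlations;
#'   \item Bland-Altman summaries (TCD - CFD), absolute and relative.
#' }
#' All tests are two-sided; significance flags use `alpha` (default 0.05)
#' with no multiple-testing correction by default (Holm optionally).
#'
#' @param cohort see [study_metric_table()]; at least 3 participants, each
#'   with the rest condition and every stimulus condition present.
#' @param rest name of the resting condition (default `"rest"`).
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"holm"`, applied within each table.
#' @return an object of class `cow_study`: a list of data frames
#'   `absolute_distributions`, `condition_response_tests`,
#'   `absolute_correlations`, `tcbf_correlations`,
#'   `tcbf_relative_correlations`, `relative_distributions`,
#'   `relative_correlations`, `bland_altman_absolute`,
#'   `bland_altman_relative`, plus `alpha` and `n_participants`.
#' @export
run_study <- function(cohort, rest = "rest", alpha = 0.05,
                      p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (length(cohort) < 3L) stop("run_study needs at least 3 participants")
  conds <- names(cohort[[1]]$conditions)
  for (p in cohort) {
    miss <- setdiff(conds, names(p$conditions))
    if (length(miss) > 0 || !(rest %in% names(p$conditions)))
      stop("participant ", p$id, " is missing condition(s): ",
           paste(c(miss, if (!(rest %in% names(p$conditions))) rest), collapse = ", "))
  }
  stimuli <- setdiff(conds, rest)

  abs_dist <- abs_corr <- ba_abs <- tcbf_corr <- NULL
  for (cond in conds) for (met in metric_names) {
    tcd <- get_metric(cohort, cond, "tcd", met)
    cfd <- get_metric(cohort, cond, "cfd", met)
    tt <- safe_paired_t(tcd, cfd)
    sw <- if (stats::sd(tcd - cfd) > 0) shapiro_wilk(tcd - cfd)$p else NA_real_
    abs_dist <- rbind(abs_dist, data.frame(
      condition = cond, metric = met,
      mean_cfd = mean(cfd), sd_cfd = stats::sd(cfd),
      mean_tcd = mean(tcd), sd_tcd = stats::sd(tcd),
      t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
      normality_p = sw))
    pc <- safe_corr(tcd, cfd)
    abs_corr <- rbind(abs_corr, data.frame(
      condition = cond, metric = met, r = pc$r, p = pc$p, n = pc$n))
    ba <- bland_altman(paired_sample(tcd, cfd))
    ba_abs <- rbind(ba_abs, data.frame(
      condition = cond, metric = met, bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      slope = ba$proportional_bias_slope, slope_p = ba$proportional_bias_p))
    tcbf <- get_tcbf(cohort, cond)
    for (src in c("cfd", "tcd")) {
      v <- get_metric(cohort, cond, src, met)
      pc2 <- safe_corr(tcbf, v)
      tcbf_corr <- rbind(tcbf_corr, data.frame(
        condition = cond, metric = met, source = toupper(src),
        r = pc2$r, p = pc2$p, n = pc2$n))
    }
  }

  resp_tests <- NULL
  for (src in c("cfd", "tcd")) for (stim in stimuli) for (met in metric_names) {
    v_rest <- get_metric(cohort, rest, src, met)
    v_stim <- get_metric(cohort, stim, src, met)
    tt <- safe_paired_t(v_stim, v_rest)
    resp_tests <- rbind(resp_tests, data.frame(
      source = toupper(src), stimulus = stim, metric = met,
      mean_rest = mean(v_rest), mean_stimulus = mean(v_stim),
      t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate))
  }

  rel_dist <- rel_corr <- ba_rel <- tcbf_rel_corr <- NULL
  for (stim in stimuli) {
    d_tcbf <- 100 * (get_tcbf(cohort, stim) - get_tcbf(cohort, rest)) /
      get_tcbf(cohort, rest)
    for (met in metric_names) {
      dl <- lapply(c(cfd = "cfd", tcd = "tcd"), function(src) {
        r0 <- get_metric(cohort, rest, src, met)
        r1 <- get_metric(cohort, stim, src, met)
        if (any(r0 <= 0)) stop("relative change requires positive rest metrics")
        100 * (r1 - r0) / r0
      })
      tt <- safe_paired_t(dl$tcd, dl$cfd)
      rel_dist <- rbind(rel_dist, data.frame(
        stimulus = stim, metric = met,
        mean_cfd = mean(dl$cfd), sd_cfd = stats::sd(dl$cfd),
        mean_tcd = mean(dl$tcd), sd_tcd = stats::sd(dl$tcd),
        t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate))
      pc <- safe_corr(dl$tcd, dl$cfd)
      rel_corr <- rbind(rel_corr, data.frame(
        stimulus = stim, metric = met, r = pc$r, p = pc$p, n = pc$n))
      ba <- bland_altman(paired_sample(dl$tcd, dl$cfd), relative = TRUE)
      ba_rel <- rbind(ba_rel, data.frame(
        stimulus = stim, metric = met, bias = ba$bias, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        slope = ba$proportional_bias_slope, slope_p = ba$proportional_bias_p))
      for (src in c("cfd", "tcd")) {
        pc2 <- safe_corr(d_tcbf, dl[[src]])
        tcbf_rel_corr <- rbind(tcbf_rel_corr, data.frame(
          stimulus = stim, metric = met, source = toupper(src),
          r = pc2$r, p = pc2$p, n = pc2$n))
      }
    }
  }

  adjust <- function(df) {
    if (p_adjust == "holm" && !is.null(df) && "p" %in% names(df))
      df$p <- stats::p.adjust(df$p, method = "holm")
    if (!is.null(df) && "p" %in% names(df)) df$significant <- !is.na(df$p) & df$p < alpha
    df
  }

  structure(list(
    absolute_distributions = adjust(abs_dist),
    condition_response_tests = adjust(resp_tests),
    absolute_correlations = adjust(abs_corr),
    tcbf_correlations = adjust(tcbf_corr),
    tcbf_relative_correlations = adjust(tcbf_rel_corr),
    relative_distributions = adjust(rel_dist),
    relative_correlations = adjust(rel_corr),
    bland_altman_absolute = ba_abs,
    bland_altman_relative = ba_rel,
    alpha = alpha, rest = rest, stimuli = stimuli,
    n_participants = length(cohort)),
    class = "cow_study")
}

#' @export
print.cow_study <- function(x, ...) {
  cat(sprintf("<cow_study> n = %d participants, rest = '%s', stimuli: %s (alpha = %g)\n",
              x$n_participants, x$rest, paste(x$stimuli, collapse = ", "), x$alpha))
  cat("\nAbsolute TCD-vs-CFD distributions (bias orientation TCD - CFD):\n")
  print(x$absolute_distributions, row.names = FALSE, digits = 4)
  cat("\nRelative-change TCD-vs-CFD correlations:\n")
  print(x$relative_correlations, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write all study tables to CSV plus a JSON summary
#'
#' @param study a `cow_study`.
#' @param dir output directory (created if needed).
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- names(study)[vapply(study, is.data.frame, logical(1))]
  for (nm in tabs)
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_participants = study$n_participants, alpha = study$alpha,
         rest = study$rest, stimuli = study$stimuli, tables = tabs),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
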