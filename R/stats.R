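# Cohort statistics: paired and variance-gated independent comparisons,
# correlation screens, noncentral-t sample-size calculation, summary tables.

test_result <- function(statistic, p_value, n, method, estimate,
                        note = NA_character_, levene_p = NA_real_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method, estimate = unname(estimate),
                 note = note, levene_p = levene_p),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g, estimate %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, x$estimate,
              paste(x$n, collapse = "/")))
  if (!is.na(x$levene_p))
    cat(sprintf("  Levene (mean-centred) p = %.4g\n", x$levene_p))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Paired comparison of pre/post measurements
#'
#' Two-sided paired t-test on subject-matched values. Zero-variance
#' differences are degenerate for the t statistic: identical vectors return
#' statistic 0 and p = 1; a constant nonzero shift is reported with p at the
#' machine floor and a note, rather than NaN.
#'
#' @param values_pre,values_post numeric vectors of equal length >= 3,
#'   matched by subject.
#' @return a `test_result` (estimate = mean post-pre difference).
#' @export
paired_comparison <- function(values_pre, values_post) {
  if (length(values_pre) != length(values_post))
    stop("pre and post vectors must have equal length")
  ok <- is.finite(values_pre) & is.finite(values_post)
  pre <- values_pre[ok]; post <- values_post[ok]
  if (length(pre) < 3) stop("need at least 3 matched pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(test_result(0, 1, length(d), "paired-t", 0,
                         note = "all differences zero"))
    return(test_result(sign(mean(d)) * Inf, .Machine$double.xmin, length(d),
                       "paired-t", mean(d),
                       note = "zero-variance nonzero differences: p below machine floor"))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  test_result(tt$statistic, tt$p.value, length(d), "paired-t", mean(d))
}

#' Independent two-group comparison with a variance gate
#'
#' Levene's test (mean-centred, as in mainstream statistical software)
#' decides the variance assumption first: if its p-value exceeds 0.05 the
#' pooled-variance two-sample t-test is used; otherwise the unequal-variance
#' (Welch) test. The method label records which path was taken.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param levene_alpha gate level (default 0.05).
#' @return a `test_result` (estimate = mean(a) - mean(b)).
#' @export
independent_comparison <- function(group_a, group_b, levene_alpha = 0.05) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  lev_p <- if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) 1
           else car::leveneTest(y, g, center = mean)[1, "Pr(>F)"]
  equal_var <- lev_p > 0.05
  if (stats::sd(y) == 0)
    return(test_result(0, 1, c(length(group_a), length(group_b)),
                       "independent-t", 0, note = "all values identical",
                       levene_p = lev_p))
  tt <- stats::t.test(group_a, group_b, var.equal = equal_var)
  test_result(tt$statistic, tt$p.value,
              c(length(group_a), length(group_b)),
              if (equal_var) "independent-t" else "welch-t",
              mean(group_a) - mean(group_b), levene_p = lev_p)
}

#' Correlation screen across variable pairs
#'
#' Runs rank (Spearman) or linear (Pearson) correlation tests for each
#' requested pair of columns, with pairwise deletion of missing values.
#' Constant columns have no defined correlation and are flagged rather than
#' tested; so are pairs with fewer than 4 complete observations.
#'
#' @param table data frame.
#' @param pairs list of length-2 character vectors (column names), or a
#'   2-column character matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @return data frame with one row per pair: variables, coefficient, p-value,
#'   n used, method, and a flag column.
#' @export
correlation_screen <- function(table, pairs, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  rows <- lapply(pairs, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    if (is.null(x) || is.null(y)) stop("unknown column in pair: ",
                                       paste(pr, collapse = " vs "))
    ok <- is.finite(x) & is.finite(y)
    flag <- NA_character_
    est <- NA_real_; p <- NA_real_
    if (sum(ok) < 4) {
      flag <- "fewer than 4 complete pairs"
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      flag <- "constant column: correlation undefined"
    } else {
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method,
                        exact = if (method == "spearman") FALSE else NULL))
      est <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(x = pr[1], y = pr[2], estimate = est, p_value = p,
               n = sum(ok), method = method, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Exact power of the two-sided two-sample t-test at level alpha with n per
# group and standardised effect d, via the noncentral t distribution.
two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' Required sample size for a two-sample t-test
#'
#' Smallest integer n per group such that the two-sided two-sample t-test at
#' level `alpha` attains at least the target power against a standardised
#' mean difference (Cohen's d), using the exact noncentral-t power function
#' and a monotone integer search (power is increasing in n). The
#' large-sample normal approximation is reported alongside for reference.
#'
#' @param effect_size Cohen's d, > 0.
#' @param alpha two-sided significance level.
#' @param power target power, in (alpha, 1).
#' @return object of class `power_result`: `n_per_group`, `n_total`,
#'   `power_achieved`, `n_normal_approx`.
#' @examples
#' required_sample_size(0.5)  # about 64 per group
#' @export
required_sample_size <- function(effect_size, alpha = 0.05, power = 0.80) {
  if (!is.finite(effect_size) || effect_size <= 0)
    stop("effect size d = 0 requires an infinite sample: no finite n exists")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= alpha || power >= 1) stop("power must lie in (alpha, 1)")
  lo <- 2L
  if (two_sample_t_power(lo, effect_size, alpha) < power) {
    hi <- 4L
    while (two_sample_t_power(hi, effect_size, alpha) < power) {
      lo <- hi
      hi <- hi * 2L
      if (hi > 2^30) stop("required sample size exceeds the search bound")
    }
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (two_sample_t_power(mid, effect_size, alpha) < power) lo <- mid
      else hi <- mid
    }
    n <- hi
  } else n <- lo
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  structure(list(n_per_group = n, n_total = 2L * n,
                 power_achieved = two_sample_t_power(n, effect_size, alpha),
                 n_normal_approx = ceiling(2 * (z / effect_size)^2),
                 effect_size = effect_size, alpha = alpha, power = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test, d = %g, alpha = %g, power = %g:\n",
              x$effect_size, x$alpha, x$power))
  cat(sprintf("  n = %d per group (%d total); achieved power %.4f\n",
              x$n_per_group, x$n_total, x$power_achieved))
  cat(sprintf("  normal approximation: %d per group\n", x$n_normal_approx))
  invisible(x)
}

format_mean_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_character_)
  sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
}

#' Group-comparison summary table for a synthetic cohort
#'
#' Mirrors the three-column comparison layout of a pre/post exposure study
#' with a single-timepoint control group: per metric, mean (SD) for controls,
#' pre-exposure and post-exposure, with an independent (variance-gated)
#' t-test for each control contrast and a paired t-test for pre vs post.
#' Missing values are deleted pairwise and each cell's n is available in the
#' returned numeric columns. An optional Benjamini-Hochberg adjusted column
#' can be appended across each p-value column.
#'
#' @param table cohort data frame with columns `subject`, `group`
#'   (`"control"`/`"vaper"`), `timepoint` (`"single"`/`"pre"`/`"post"`) and
#'   the metric columns.
#' @param metrics character vector of metric column names.
#' @param adjust append Benjamini-Hochberg adjusted p-value columns
#'   (an extension: raw p-values remain the primary report).
#' @return data frame, one row per metric.
#' @export
build_summary_tables <- function(table,
                                 metrics = c("mean_sv", "rd_sv", "lci",
                                             "mean_q", "rd_q", "heart_rate"),
                                 adjust = FALSE) {
  stopifnot(all(c("subject", "group", "timepoint") %in% names(table)))
  metrics <- metrics[metrics %in% names(table)]
  if (length(metrics) == 0) stop("no requested metric columns present")
  ctrl <- table[table$group == "control", , drop = FALSE]
  pre <- table[table$group == "vaper" & table$timepoint == "pre", , drop = FALSE]
  post <- table[table$group == "vaper" & table$timepoint == "post", , drop = FALSE]
  if (nrow(ctrl) == 0 || nrow(pre) == 0 || nrow(post) == 0)
    stop("cohort must contain controls and pre/post vaper rows")
  post <- post[match(pre$subject, post$subject), , drop = FALSE]

  one <- function(m) {
    vc <- ctrl[[m]]; vpre <- pre[[m]]; vpost <- post[[m]]
    p_c_pre <- tryCatch(independent_comparison(vc, vpre)$p_value,
                        error = function(e) NA_real_)
    p_c_post <- tryCatch(independent_comparison(vc, vpost)$p_value,
                         error = function(e) NA_real_)
    p_prepost <- tryCatch(paired_comparison(vpre, vpost)$p_value,
                          error = function(e) NA_real_)
    data.frame(metric = m,
               control = format_mean_sd(vc),
               pre = format_mean_sd(vpre),
               post = format_mean_sd(vpost),
               control_mean = mean(vc[is.finite(vc)]),
               control_sd = stats::sd(vc[is.finite(vc)]),
               pre_mean = mean(vpre[is.finite(vpre)]),
               pre_sd = stats::sd(vpre[is.finite(vpre)]),
               post_mean = mean(vpost[is.finite(vpost)]),
               post_sd = stats::sd(vpost[is.finite(vpost)]),
               n_control = sum(is.finite(vc)),
               n_pre = sum(is.finite(vpre)),
               n_post = sum(is.finite(vpost)),
               p_control_vs_pre = p_c_pre,
               p_control_vs_post = p_c_post,
               p_pre_vs_post = p_prepost,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(metrics, one))
  if (adjust) {
    for (col in c("p_control_vs_pre", "p_control_vs_post", "p_pre_vs_post"))
      out[[paste0(col, "_bh")]] <- stats::p.adjust(out[[col]], method = "BH")
  }
  out
}
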