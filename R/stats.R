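#' Per-group summary statistics
#'
#' @param data Data frame with a value column and a grouping column.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor.
#' @return Tibble with one row per group: `label`, `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator).
#' @export
group_summary <- function(data, value, group) {
  data |>
    dplyr::group_by(label = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      .groups = "drop"
    )
}

new_anova_result <- function(f, df_between, df_within, mse, ss_between,
                             ss_within, groups) {
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_between, df_within,
                                            lower.tail = FALSE)
  structure(list(
    f_statistic = f, df_between = df_between, df_within = df_within,
    p_value = p, mse = mse, ss_between = ss_between, ss_within = ss_within,
    groups = groups,
    degenerate = is.infinite(f)
  ), class = "pq_anova")
}

#' One-way ANOVA on raw group samples
#'
#' Standard between/within sum-of-squares decomposition with the F statistic
#' on (k-1, N-k) degrees of freedom. Zero within-group variance with unequal
#' means yields an infinite F and p = 0, flagged as `degenerate`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `pq_anova` object; see [tidy.pq_anova()] and
#'   [glance.pq_anova()].
#' @examples
#' anova_oneway_raw(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
anova_oneway_raw <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  labels <- names(groups) %||% as.character(seq_along(groups))
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  n_tot <- sum(ns)
  k <- length(groups)
  grand <- sum(ns * means) / n_tot
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df_b <- k - 1
  df_w <- n_tot - k
  mse <- ss_w / df_w
  f <- if (mse <= .Machine$double.eps * max(1, ss_b)) {
    if (ss_b <= .Machine$double.eps) 0 else Inf
  } else {
    (ss_b / df_b) / mse
  }
  gs <- tibble::tibble(label = labels, n = ns, mean = means,
                       sd = vapply(groups, stats::sd, 1))
  new_anova_result(f, df_b, df_w, mse, ss_b, ss_w, gs)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the ANOVA table from per-group n, mean and sample SD alone:
#' the between sum of squares from the means around the weighted grand mean,
#' the within sum of squares as sum((n_i - 1) * sd_i^2). Algebraically
#' identical to [anova_oneway_raw()] when the summaries come from the raw
#' samples, and usable on published tables where raw data are unavailable.
#'
#' @param summary Data frame with columns `label`, `n`, `mean`, `sd`
#'   (sample SD); every `n` must be >= 2.
#' @return A `pq_anova` object.
#' @examples
#' anova_from_summary(data.frame(label = c("L", "M", "H"), n = c(5, 8, 8),
#'                               mean = c(0.14, 0.20, 0.26),
#'                               sd = c(0.03, 0.01, 0.01)))
#' @export
anova_from_summary <- function(summary) {
  stopifnot(all(c("label", "n", "mean", "sd") %in% names(summary)),
            nrow(summary) >= 2, all(summary$sd >= 0))
  if (any(summary$n < 2)) {
    stop_pq("every group needs n >= 2 for a summary-statistics ANOVA",
            "pq_invalid_summary")
  }
  ns <- summary$n; means <- summary$mean; sds <- summary$sd
  n_tot <- sum(ns); k <- nrow(summary)
  grand <- sum(ns * means) / n_tot
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((ns - 1) * sds^2)
  df_b <- k - 1; df_w <- n_tot - k
  mse <- ss_w / df_w
  f <- if (mse <= .Machine$double.eps * max(1, ss_b)) {
    if (ss_b <= .Machine$double.eps) 0 else Inf
  } else {
    (ss_b / df_b) / mse
  }
  gs <- tibble::tibble(label = summary$label, n = ns, mean = means, sd = sds)
  new_anova_result(f, df_b, df_w, mse, ss_b, ss_w, gs)
}

#' LSD post-hoc pairwise comparisons
#'
#' Fisher's least-significant-difference rule: unadjusted pairwise t tests
#' using the ANOVA pooled error variance. For each pair (i, j):
#' t = (m_i - m_j) / sqrt(MSE * (1/n_i + 1/n_j)), two-sided p on N - k
#' degrees of freedom. All k(k-1)/2 pairs are returned.
#'
#' @param summary Data frame with `label`, `n`, `mean` (an `sd` column is
#'   ignored), e.g. the `groups` element of a `pq_anova`.
#' @param mse Pooled mean squared error from the corresponding ANOVA.
#' @param df Error degrees of freedom (N - k).
#' @return Tibble: `group1`, `group2`, `mean_diff`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
lsd_pairwise <- function(summary, mse, df) {
  stopifnot(all(c("label", "n", "mean") %in% names(summary)), df >= 1)
  if (mse <= 0) stop_pq("mse must be positive", "pq_invalid_mse")
  k <- nrow(summary)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    diff <- summary$mean[i] - summary$mean[j]
    se <- sqrt(mse * (1 / summary$n[i] + 1 / summary$n[j]))
    t <- diff / se
    tibble::tibble(
      group1 = summary$label[i], group2 = summary$label[j],
      mean_diff = diff, t_statistic = t, df = df,
      p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    )
  })
}

#' Cohen's kappa for agreement between two grading systems
#'
#' Unweighted kappa on a square contingency table whose row/column order
#' encodes the grade correspondence (the diagonal is agreement):
#' kappa = (Po - Pe) / (1 - Pe) with Po the observed diagonal fraction and
#' Pe the chance agreement from the marginals. The interpretation bands are
#' "poor" below 0.40, "fair to good" from 0.40 up to (but excluding) 0.75,
#' and "excellent" from 0.75 to 1.
#'
#' @param table Square numeric matrix of counts (rows: first grading system,
#'   columns: second).
#' @return A `pq_kappa` object: `kappa`, `po`, `pe`, `category`, `n`,
#'   `table`.
#' @examples
#' m <- matrix(c(5, 0, 0, 3, 5, 0, 0, 1, 7), nrow = 3, byrow = TRUE)
#' cohens_kappa(m)
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    stop_pq("contingency table must be square", "pq_nonsquare_table")
  }
  stopifnot(all(table >= 0), sum(table) > 0)
  n <- sum(table)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    stop_pq("expected agreement is 1; kappa undefined", "pq_kappa_undefined")
  }
  kappa <- (po - pe) / (1 - pe)
  structure(list(
    kappa = kappa, po = po, pe = pe, category = kappa_category(kappa),
    n = n, table = table
  ), class = "pq_kappa")
}

kappa_category <- function(kappa) {
  if (kappa < 0.40) "poor" else if (kappa < 0.75) "fair to good" else "excellent"
}

#' Inter-rater intraclass correlation coefficient
#'
#' Two-way random effects, absolute agreement, single rater (ICC(2,1) in the
#' Shrout-Fleiss family), computed from the mean squares of the two-way
#' subjects x raters decomposition:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each); ordinal grades encoded numerically.
#' @return A `pq_icc` object: `icc`, `model`, mean squares, `n_subjects`,
#'   `n_raters`.
#' @export
icc_inter_rater <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2, !anyNA(ratings))
  if (stats::var(as.vector(ratings)) < .Machine$double.eps) {
    stop_pq("ratings have zero variance; ICC undefined", "pq_icc_undefined")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(
    icc = icc,
    model = "two-way random, absolute agreement, single rater",
    msr = msr, msc = msc, mse = mse, n_subjects = n, n_raters = k
  ), class = "pq_icc")
}

#' Tukey box-and-whisker summary
#'
#' Quartiles with whiskers at the furthest data points within 1.5 x IQR of
#' the quartiles; points beyond the whiskers are outliers. The default
#' quartile convention is the discontinuous empirical quantile (R type 2:
#' order statistics, averaged when the quartile falls exactly between two);
#' type-7 linear interpolation and Tukey hinges are available as switches.
#'
#' @param values Numeric vector (n >= 1).
#' @param quartile_method `"empirical"` (type-2 quantiles, default),
#'   `"interpolated"` (type-7 quantiles) or `"tukey"` (hinges).
#' @return One-row tibble: `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, and `outliers` (list column).
#' @export
boxplot_summary <- function(values, quartile_method = c("empirical",
                                                        "interpolated",
                                                        "tukey")) {
  quartile_method <- match.arg(quartile_method)
  stopifnot(length(values) >= 1, !anyNA(values))
  if (quartile_method == "tukey") {
    fn <- stats::fivenum(values)
    qs <- fn[2:4]
  } else {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                          type = if (quartile_method == "empirical") 2 else 7)
  }
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble::tibble(
    q1 = qs[1], median = qs[2], q3 = qs[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    n_outliers = sum(!inside),
    outliers = list(sort(values[!inside]))
  )
}

#' Pearson correlation with explicit degeneracy handling
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !anyNA(x), !anyNA(y))
  if (stats::sd(x) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps) {
    stop_pq("zero variance; correlation undefined", "pq_corr_undefined")
  }
  stats::cor(x, y)
}

#' Row-wise and marginal percentages of a contingency table
#'
#' Each cell as a percentage of its row total and each column total as a
#' percentage of the grand total, both rounded to one decimal place; rows
#' with zero total are flagged and their percentages undefined.
#'
#' @param table Numeric matrix of counts with optional dimnames.
#' @return List with `row_percent` (matrix, 1 d.p.), `marginal_percent`
#'   (named vector over columns, 1 d.p.), `zero_rows` (logical vector).
#' @export
contingency_percentages <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), sum(table) > 0)
  rt <- rowSums(table)
  zero <- rt == 0
  rp <- table / ifelse(rt == 0, NA_real_, rt) * 100
  list(
    row_percent = round(rp, 1),
    marginal_percent = round(colSums(table) / sum(table) * 100, 1),
    zero_rows = zero
  )
}

#' @export
print.pq_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %s, p = %s (MSE %.4g)\n",
    x$df_between, x$df_within,
    format(x$f_statistic, digits = 4), format.pval(x$p_value, digits = 3),
    x$mse
  ))
  invisible(x)
}

#' @export
print.pq_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (Po %.3f, Pe %.3f, n %d): %s\n",
              x$kappa, x$po, x$pe, x$n, x$category))
  invisible(x)
}

#' @export
print.pq_icc <- function(x, ...) {
  cat(sprintf("ICC = %.3f (%s; %d subjects, %d raters)\n",
              x$icc, x$model, x$n_subjects, x$n_raters))
  invisible(x)
}
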