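test_that("raw one-way ANOVA matches the base-R oracle and handles edge cases", {
  set.seed(1)
  g <- list(a = rnorm(6), b = rnorm(8, 0.5), c = rnorm(5, 1))
  res <- anova_oneway_raw(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  oracle <- stats::oneway.test(y ~ grp, df, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)

  same <- anova_oneway_raw(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- anova_oneway_raw(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(degen$f_statistic))
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
})

test_that("summary-statistics ANOVA is algebraically identical to the raw form", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(2:12, 1), rnorm(1), runif(1, 0.5, 2)))
    names(g) <- paste0("g", seq_len(k))
    raw <- anova_oneway_raw(g)
    summ <- data.frame(label = names(g), n = lengths(g),
                       mean = vapply(g, mean, 1), sd = vapply(g, sd, 1))
    from_sum <- anova_from_summary(summ)
    expect_lt(abs(from_sum$f_statistic - raw$f_statistic) /
                max(raw$f_statistic, 1e-12), 1e-10)
    expect_equal(from_sum$p_value, raw$p_value, tolerance = 1e-10)
  }
  expect_error(anova_from_summary(
    data.frame(label = c("a", "b"), n = c(1, 5), mean = c(0, 1),
               sd = c(0, 1))), class = "pq_invalid_summary")
})

test_that("with two groups the ANOVA F is the squared pooled t", {
  set.seed(2)
  x <- rnorm(9); y <- rnorm(11, 0.8)
  res <- anova_oneway_raw(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("LSD pairwise comparisons follow the pooled-variance t formula", {
  summ <- data.frame(label = c("a", "b"), n = c(2, 2), mean = c(0, 1))
  out <- lsd_pairwise(summ, mse = 1, df = 18)
  expect_equal(abs(out$t_statistic), 1)
  expect_equal(out$p_value, 2 * stats::pt(1, 18, lower.tail = FALSE))

  eqm <- lsd_pairwise(data.frame(label = c("a", "b"), n = c(4, 4),
                                 mean = c(2, 2)), mse = 1, df = 10)
  expect_equal(eqm$t_statistic, 0)
  expect_equal(eqm$p_value, 1)

  # symmetry in pair order and monotonicity in |mean difference|
  s3 <- data.frame(label = c("a", "b", "c"), n = c(5, 5, 5),
                   mean = c(0, 0.5, 2))
  out3 <- lsd_pairwise(s3, mse = 1, df = 12)
  rev3 <- lsd_pairwise(s3[3:1, ], mse = 1, df = 12)
  ab <- out3$p_value[out3$group1 == "a" & out3$group2 == "b"]
  ba <- rev3$p_value[rev3$group1 == "b" & rev3$group2 == "a"]
  expect_equal(ab, ba)
  expect_lt(out3$p_value[out3$group1 == "a" & out3$group2 == "c"], ab)

  expect_error(lsd_pairwise(s3, mse = 0, df = 12), class = "pq_invalid_mse")
})

test_that("Cohen's kappa reproduces hand values and invariances", {
  perfect <- diag(7, 3)
  expect_equal(cohens_kappa(perfect)$kappa, 1)

  indep <- matrix(1, 2, 2)
  expect_equal(cohens_kappa(indep)$kappa, 0)

  m <- matrix(c(5, 0, 0, 3, 5, 0, 0, 1, 7), nrow = 3, byrow = TRUE)
  k <- cohens_kappa(m)
  expect_equal(round(k$kappa, 3), 0.717)
  expect_identical(k$category, "fair to good")

  # simultaneous permutation of rows and columns leaves kappa unchanged
  p <- c(3, 1, 2)
  expect_equal(cohens_kappa(m[p, p])$kappa, k$kappa)

  # independent oracle
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:20) {
    t <- matrix(sample(0:9, 9, replace = TRUE), 3)
    if (sum(t) == 0 || sum(rowSums(t) * colSums(t)) == sum(t)^2) next
    expect_equal(cohens_kappa(t)$kappa,
                 e1071::classAgreement(t)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa rejects malformed or degenerate tables", {
  expect_error(cohens_kappa(matrix(1, 2, 3)), class = "pq_nonsquare_table")
  onecell <- matrix(c(5, 0, 0, 0), 2)
  expect_error(cohens_kappa(onecell), class = "pq_kappa_undefined")
})

test_that("kappa interpretation bands match the stated boundaries", {
  expect_identical(cohens_kappa(matrix(c(30, 20, 20, 30), 2))$category, "poor")
  fair <- pulleyquant:::kappa_category
  expect_identical(fair(0.39999), "poor")
  expect_identical(fair(0.40), "fair to good")
  expect_identical(fair(0.7499), "fair to good")
  expect_identical(fair(0.75), "excellent")
  expect_identical(fair(1), "excellent")
})

test_that("ICC(2,1) matches an aov-based mean-squares oracle", {
  ratings <- matrix(c(9, 2, 5, 8,
                      6, 1, 3, 2), ncol = 2)
  res <- icc_inter_rater(ratings)
  long <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(1:4, 2)),
    rater = factor(rep(1:2, each = 4))
  )
  ms <- summary(stats::aov(y ~ subject + rater, long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, oracle, tolerance = 1e-12)

  expect_equal(icc_inter_rater(cbind(1:5, 1:5))$icc, 1)

  set.seed(3)
  subj <- rnorm(30, sd = 0.5)
  noisy <- cbind(subj, subj + rnorm(30, sd = 10))
  expect_lt(abs(icc_inter_rater(noisy)$icc), 0.2)

  expect_error(icc_inter_rater(matrix(1, 4, 2)), class = "pq_icc_undefined")
})

test_that("boxplot summaries follow the box-and-whisker construction", {
  b <- boxplot_summary(1:7)
  expect_equal(c(b$q1, b$median, b$q3), c(2, 4, 6))
  expect_identical(b$n_outliers, 0L)

  const <- boxplot_summary(rep(3, 5))
  expect_equal(c(const$q1, const$median, const$q3), c(3, 3, 3))
  expect_identical(const$n_outliers, 0L)

  out <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_identical(out$outliers[[1]], 100)
  expect_equal(out$whisker_high, 4)

  # ordering invariant + every point inside whiskers or an outlier
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(sample(5:40, 1))
    s <- boxplot_summary(v)
    expect_true(s$whisker_low <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$whisker_high)
    inside <- v >= s$whisker_low & v <= s$whisker_high
    expect_identical(sort(v[!inside]), s$outliers[[1]])
  }

  # interpolated switch uses type-7 quantiles
  b7 <- boxplot_summary(1:7, quartile_method = "interpolated")
  expect_equal(c(b7$q1, b7$q3), c(2.5, 5.5))
})

test_that("pearson_corr handles exact and degenerate cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_corr(x, 2 * x + 1), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_error(pearson_corr(x, rep(2, 5)), class = "pq_corr_undefined")
})

test_that("contingency percentages reproduce row-wise and marginal shares", {
  m <- matrix(c(5, 0, 0, 3, 5, 0, 0, 1, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("L", "M", "H"), c("II", "III", "IV")))
  pct <- contingency_percentages(m)
  expect_equal(unname(pct$row_percent["M", ]), c(37.5, 62.5, 0))
  expect_equal(unname(pct$row_percent["L", ]), c(100, 0, 0))
  expect_equal(unname(pct$marginal_percent), c(38.1, 28.6, 33.3))

  z <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  pz <- contingency_percentages(z)
  expect_true(pz$zero_rows[1])
  expect_true(all(is.na(pz$row_percent[1, ])))
})

test_that("tidy and glance methods return well-formed tibbles", {
  an <- anova_from_summary(data.frame(label = c("L", "M", "H"),
                                      n = c(5, 8, 8),
                                      mean = c(0.14, 0.20, 0.26),
                                      sd = c(0.03, 0.01, 0.01)))
  td <- tidy(an)
  expect_identical(td$term, c("between", "within"))
  expect_equal(sum(td$df), 20)
  gl <- glance(an)
  expect_identical(nrow(gl), 1L)
  expect_lt(gl$p.value, 1e-4)

  k <- cohens_kappa(diag(5, 3))
  expect_equal(tidy(k)$kappa, 1)
  expect_equal(glance(k), tidy(k))

  icc <- icc_inter_rater(cbind(c(1, 2, 3), c(1, 2, 4)))
  expect_identical(nrow(tidy(icc)), 1L)
})
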