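#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ANOVA result
#'
#' @param x A `pq_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per stratum (`between`, `within`): `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#' @method tidy pq_anova
#' @export
tidy.pq_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$mse),
    statistic = c(x$f_statistic, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' One-row model summary of an ANOVA result
#'
#' @param x A `pq_anova` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df_between`, `df_within`,
#'   `p.value`, `mse`, `degenerate`.
#' @method glance pq_anova
#' @export
glance.pq_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic, df_between = x$df_between,
    df_within = x$df_within, p.value = x$p_value, mse = x$mse,
    degenerate = x$degenerate
  )
}

#' Tidy a Cohen's kappa result
#'
#' @param x A `pq_kappa` object.
#' @param ... Unused.
#' @return One-row tibble: `kappa`, `po`, `pe`, `category`, `n`.
#' @method tidy pq_kappa
#' @export
tidy.pq_kappa <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, po = x$po, pe = x$pe,
                 category = x$category, n = x$n)
}

#' @rdname tidy.pq_kappa
#' @method glance pq_kappa
#' @export
glance.pq_kappa <- function(x, ...) tidy.pq_kappa(x)

#' Tidy an ICC result
#'
#' @param x A `pq_icc` object.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `model`, `msr`, `msc`, `mse`,
#'   `n_subjects`, `n_raters`.
#' @method tidy pq_icc
#' @export
tidy.pq_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, model = x$model, msr = x$msr, msc = x$msc,
                 mse = x$mse, n_subjects = x$n_subjects,
                 n_raters = x$n_raters)
}

#' @rdname tidy.pq_icc
#' @method glance pq_icc
#' @export
glance.pq_icc <- function(x, ...) tidy.pq_icc(x)
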