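# Group statistics: mean +/- SD summaries, pooling of equal-sized subgroups
# into "Total" rows, one-way ANOVA in raw-data and summary-statistics forms,
# and Fisher LSD post hoc t tests.
#
# The summary-statistics forms matter because published tables report only
# mean +/- SD per cell: the pooled-SD identity reconstructs the sample SD of
# the union of two equal-sized subgroups exactly from their summaries, and
# the summary ANOVA recovers F from (n, mean, sd) alone.

#' Mean and sample SD of a vector
#'
#' @param values numeric vector, length >= 2.
#' @param units optional unit string carried along.
#' @return tibble: `n`, `mean`, `sd` (n-1 denominator), `units`.
#' @export
#' @examples
#' summarize_values(c(1, 2, 3)) # mean 2, sd 1
summarize_values <- function(values, units = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop_insufficient_data(sprintf(
      "Need at least 2 values for a mean +/- SD summary (got %d).", length(values)
    ))
  }
  tibble(n = length(values), mean = mean(values), sd = sd(values), units = units)
}

#' Pool two equal-sized subgroup summaries
#'
#' Reconstructs the summary of the union of two samples of equal size n from
#' their (mean, sd) pairs: combined mean is the average of the means, and
#' combined sd is the exact sample SD of the pooled values,
#' `sqrt(((n-1)(sa^2 + sb^2) + n((ma-m)^2 + (mb-m)^2)) / (2n-1))`.
#' This is how a "Total" row pooling two sacrifice-time subgroups is formed
#' from a published table.
#'
#' @param a,b one-row summaries (`n`, `mean`, `sd`) with `a$n == b$n`.
#' @return one-row tibble: pooled `n`, `mean`, `sd`.
#' @export
#' @examples
#' a <- tibble::tibble(n = 4, mean = 40.54, sd = 7.23)
#' b <- tibble::tibble(n = 4, mean = 32.68, sd = 8.73)
#' combine_subgroups(a, b) # 36.61 +/- 8.53
combine_subgroups <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$n != b$n) stop_unequal_subgroups(a$n, b$n)
  n <- a$n
  m <- (a$mean + b$mean) / 2
  ss <- (n - 1) * (a$sd^2 + b$sd^2) + n * ((a$mean - m)^2 + (b$mean - m)^2)
  pooled_sd <- sqrt(ss / (2 * n - 1))
  out <- tibble(n = 2L * as.integer(n), mean = m, sd = pooled_sd)
  if ("units" %in% names(a)) out$units <- a$units
  out
}

#' One-way ANOVA, from raw data or from summary statistics
#'
#' With a list of numeric vectors, fits the standard one-way decomposition
#' via `stats::aov()`. With a data frame of per-group summaries (`n`, `mean`,
#' `sd`), uses the closed forms `SSB = sum n_i (m_i - m)^2` and
#' `SSW = sum (n_i - 1) s_i^2`, which need no raw data. Both routes give the
#' same F to numerical precision.
#'
#' @param groups list of numeric vectors, or a data frame with columns `n`,
#'   `mean`, `sd` (one row per group).
#' @return object of class `perivasc_anova`: `F`, `df_between`, `df_within`,
#'   `p_value`, `mse_within`, plus sums of squares and the route used.
#' @export
#' @examples
#' anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
    if (nrow(groups) < 2) {
      stop_insufficient_data("ANOVA needs at least 2 groups.")
    }
    if (any(groups$n < 2)) {
      stop_insufficient_data("Every group needs n >= 2.")
    }
    n <- groups$n; m <- groups$mean; s <- groups$sd
    grand <- sum(n * m) / sum(n)
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum((n - 1) * s^2)
    dfb <- length(n) - 1
    dfw <- sum(n) - length(n)
    method <- "summary"
  } else {
    stopifnot(is.list(groups))
    if (length(groups) < 2) {
      stop_insufficient_data("ANOVA needs at least 2 groups.")
    }
    if (any(vapply(groups, length, 1L) < 2)) {
      stop_insufficient_data("Every group needs n >= 2.")
    }
    g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
    y <- unlist(groups, use.names = FALSE)
    fit <- stats::aov(y ~ g)
    tab <- summary(fit)[[1]]
    ssb <- tab["g", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
    dfb <- tab["g", "Df"]; dfw <- tab["Residuals", "Df"]
    method <- "raw"
  }
  # ssw of exactly-constant groups can surface as rounding dust from the
  # raw-route fit; treat anything below 1e-10 of the total as zero
  if (ssw <= 1e-10 * (ssb + ssw)) stop_degenerate_anova()
  msb <- ssb / dfb
  mse <- ssw / dfw
  f <- msb / mse
  structure(
    list(
      F = f, df_between = dfb, df_within = dfw,
      p_value = pf(f, dfb, dfw, lower.tail = FALSE),
      mse_within = mse, ss_between = ssb, ss_within = ssw, method = method
    ),
    class = "perivasc_anova"
  )
}

#' @export
print.perivasc_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA (%s route): F(%d, %d) = %.4f, p = %.4g, MSE = %.4f\n",
    x$method, x$df_between, x$df_within, x$F, x$p_value, x$mse_within
  ))
  invisible(x)
}

#' @export
tidy.perivasc_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$mse_within),
    statistic = c(x$F, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @export
glance.perivasc_anova <- function(x, ...) {
  tibble(
    statistic = x$F, df_between = x$df_between, df_within = x$df_within,
    p.value = x$p_value, mse_within = x$mse_within, method = x$method
  )
}

#' Fisher LSD post hoc t test between two groups
#'
#' `t = (ma - mb) / sqrt(MSE * (1/na + 1/nb))` with the ANOVA within-group
#' mean square and its degrees of freedom; two-sided p. By construction LSD
#' applies no multiplicity correction (`adjusted = "none"` in the output
#' flags this for downstream readers).
#'
#' @param a,b one-row group summaries (`n`, `mean`, `sd`).
#' @param anova the `perivasc_anova` fitted on the same groups.
#' @return one-row tibble: `estimate` (ma - mb), `t`, `df`, `p_value`,
#'   `adjusted`.
#' @export
lsd_t <- function(a, b, anova) {
  stopifnot(inherits(anova, "perivasc_anova"), nrow(a) == 1, nrow(b) == 1)
  if (anova$mse_within <= 0) stop_degenerate_anova()
  est <- a$mean - b$mean
  t <- est / sqrt(anova$mse_within * (1 / a$n + 1 / b$n))
  tibble(
    estimate = est, t = t, df = anova$df_within,
    p_value = 2 * pt(abs(t), anova$df_within, lower.tail = FALSE),
    adjusted = "none"
  )
}

#' All pairwise LSD comparisons for a summary table
#'
#' @param summaries data frame of per-group summaries with a `group` column
#'   plus `n`, `mean`, `sd`.
#' @param anova optional pre-fitted `perivasc_anova`; fitted from the
#'   summaries when omitted.
#' @return tibble with one row per unordered pair.
#' @export
lsd_pairwise <- function(summaries, anova = NULL) {
  stopifnot(is.data.frame(summaries), "group" %in% names(summaries))
  if (is.null(anova)) anova <- anova_oneway(summaries)
  k <- nrow(summaries)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    ia <- pairs[1, i]; ib <- pairs[2, i]
    res <- lsd_t(summaries[ia, ], summaries[ib, ], anova)
    tibble(
      group_a = summaries$group[ia], group_b = summaries$group[ib],
      estimate = res$estimate, t = res$t, df = res$df,
      p_value = res$p_value, adjusted = res$adjusted
    )
  })
}

#' Round half away from zero to a fixed number of decimals
#'
#' The rounding used for report tables (base `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_report <- function(x, digits = 2) {
  round_half_away(x * 10^digits) / 10^digits
}
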