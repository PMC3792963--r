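test_that("summaries use the n-1 sample SD and reject single values", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1); expect_equal(s$n, 3)
  expect_equal(summarize_values(rep(5, 4))$sd, 0)
  expect_error(summarize_values(7), class = "perivasc_insufficient_data")

  set.seed(2)
  x <- rnorm(1000)
  s2 <- summarize_values(x)
  # two-pass oracle
  expect_equal(s2$mean, sum(x) / 1000, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((x - mean(x))^2) / 999), tolerance = 1e-12)
})

test_that("equal-subgroup pooling has the closed form mean m, sd s*sqrt(6/7) at n = 4", {
  s <- 2.5
  out <- combine_subgroups(tibble::tibble(n = 4, mean = 10, sd = s),
                           tibble::tibble(n = 4, mean = 10, sd = s))
  expect_equal(out$mean, 10)
  expect_equal(out$sd, s * sqrt(6 / 7), tolerance = 1e-12)
  expect_equal(out$n, 8L)
  expect_error(
    combine_subgroups(tibble::tibble(n = 4, mean = 1, sd = 1),
                      tibble::tibble(n = 5, mean = 1, sd = 1)),
    class = "perivasc_unequal_subgroups"
  )
})

test_that("pooling subgroup summaries equals summarizing the pooled sample", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    A <- rnorm(n, sd = runif(1, 0.5, 4)); B <- rnorm(n, 3, 2)
    pooled <- combine_subgroups(summarize_values(A), summarize_values(B))
    direct <- summarize_values(c(A, B))
    expect_equal(pooled$mean, direct$mean, tolerance = 1e-12)
    expect_equal(pooled$sd, direct$sd, tolerance = 1e-12)
  }
})

test_that("ANOVA on permuted copies of one sample gives F = 0, p = 1", {
  fit <- anova_oneway(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
  expect_equal(fit$F, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1, tolerance = 1e-12)
})

test_that("raw-data and summary-statistics ANOVA agree to 1e-10", {
  set.seed(101)
  for (i in 1:10) {
    gs <- lapply(1:4, function(k) rnorm(sample(3:10, 1), mean = k / 3))
    raw <- anova_oneway(gs)
    summ <- anova_oneway(dplyr::bind_rows(lapply(gs, summarize_values)))
    expect_lt(abs(raw$F - summ$F), 1e-10)
    expect_lt(abs(raw$p_value - summ$p_value), 1e-10)
    expect_lt(abs(raw$mse_within - summ$mse_within), 1e-10)
  }
})

test_that("summary ANOVA on published group summaries matches the independent oracle", {
  # tumor diameters: 4 arms, n = 8, means and SDs as printed
  tab <- tibble::tibble(
    n = rep(8L, 4),
    mean = c(1.53, 1.58, 1.63, 1.49),
    sd = c(0.27, 0.30, 0.25, 0.20)
  )
  fit <- anova_oneway(tab)
  expect_equal(fit$F, oracle_summary_anova_F(tab$n, tab$mean, tab$sd),
               tolerance = 1e-12)
  expect_equal(fit$df_between, 3)
  expect_equal(fit$df_within, 28)
  expect_gt(fit$p_value, 0.05) # arms comparable at baseline
})

test_that("ANOVA degenerates are typed errors", {
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))),
               class = "perivasc_degenerate_anova")
  expect_error(anova_oneway(list(c(1, 2))), class = "perivasc_insufficient_data")
  expect_error(anova_oneway(list(c(1, 2), c(3))),
               class = "perivasc_insufficient_data")
})

test_that("LSD t matches the closed form and is antisymmetric", {
  fake <- structure(list(mse_within = 1, df_within = 2, F = 1,
                         df_between = 1, p_value = 0.5),
                    class = "perivasc_anova")
  a <- tibble::tibble(n = 2, mean = 3, sd = 1)
  b <- tibble::tibble(n = 2, mean = 1, sd = 1)
  res <- lsd_t(a, b, fake)
  expect_equal(res$t, 2)
  expect_equal(res$p_value, 2 * pt(2, 2, lower.tail = FALSE), tolerance = 1e-12)

  rev <- lsd_t(b, a, fake)
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p_value, res$p_value)

  same <- lsd_t(a, a, fake)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
})

test_that("LSD uses the pooled MSE across all groups, as a worked example", {
  set.seed(7)
  gs <- lapply(1:3, function(k) rnorm(6, mean = k))
  fit <- anova_oneway(gs)
  s <- dplyr::bind_rows(lapply(gs, summarize_values))
  res <- lsd_t(s[1, ], s[3, ], fit)
  t_manual <- (mean(gs[[1]]) - mean(gs[[3]])) /
    sqrt(fit$mse_within * (1 / 6 + 1 / 6))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, fit$df_within)

  allp <- lsd_pairwise(dplyr::mutate(s, group = 1:3), fit)
  expect_equal(nrow(allp), 3)
  expect_true(all(allp$adjusted == "none"))
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- anova_oneway(list(rnorm(5), rnorm(5, 1)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("between", "within"))
  expect_equal(td$statistic[1], fit$F)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$p.value, fit$p_value)
})

test_that("report rounding is half away from zero at 2 decimals", {
  # 0.125 is exactly representable: half rounds away from zero, not to even
  expect_equal(round_report(0.125), 0.13)
  expect_equal(round_report(-0.125), -0.13)
  expect_equal(round_report(1.004), 1.00)
  expect_equal(round_report(1.006), 1.01)
})
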