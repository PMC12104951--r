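# Group summaries, ANOVA with Tukey, BT~CCT regression, ratio independence.

toy_cohort <- function() {
  data.frame(
    subject_id = sprintf("S%02d", 1:9),
    group = rep(c("HC", "KC", "CD"), each = 3),
    age_y = c(40, 45, 50, 30, 32, 34, 65, 70, 72),
    sex = rep(c("F", "M", "F"), 3),
    bt_um = c(15.0, 15.5, 16.0, 14.0, 14.2, 14.4, 15.4, 15.8, 16.2),
    et_um = c(52, 53, 54, 48, 49, 50, 51, 52, 53),
    cct_um = c(530, 540, 550, 500, 505, 510, 555, 565, 575),
    kmax_d = c(43, 44, 45, 50, 52, 54, 45, 46, 47),
    stringsAsFactors = FALSE
  )
}

test_that("group summary matches hand-computed values on a toy table", {
  s <- group_summary(toy_cohort(), variables = "bt_um")
  hc <- s[s$group == "HC", ]
  expect_equal(hc$mean, 15.5)
  expect_equal(hc$sd, 0.5)
  expect_equal(hc$min, 15.0)
  expect_equal(hc$max, 16.0)
  expect_equal(hc$n, 3)
})

test_that("identical subjects give SD 0 and min = max = mean", {
  df <- toy_cohort()
  df$bt_um <- 15
  s <- group_summary(df, variables = "bt_um")
  expect_true(all(s$sd == 0))
  expect_true(all(s$min == 15 & s$max == 15 & s$mean == 15))
})

test_that("summary agrees with an independent streaming recomputation", {
  df <- toy_cohort()
  s <- group_summary(df)
  for (i in seq_len(nrow(s))) {
    x <- bowmetrics:::add_ratios(df)
    x <- x[x$group == s$group[i], s$variable[i]]
    # streaming (Welford) mean and variance
    m <- 0; m2 <- 0; n <- 0
    for (v in x) {
      n <- n + 1
      d <- v - m
      m <- m + d / n
      m2 <- m2 + d * (v - m)
    }
    expect_equal(s$mean[i], m)
    expect_equal(s$sd[i], sqrt(m2 / (n - 1)))
  }
})

test_that("empty or tiny groups are rejected", {
  df <- toy_cohort()[c(1, 4:9), ]
  expect_error(group_summary(df), "fewer than 2")
})

test_that("one-way ANOVA matches the hand-computed F on a worked example", {
  df <- data.frame(group = rep(c("A", "B", "C"), each = 3),
                   y = c(1, 2, 3, 4, 5, 6, 8, 9, 10))
  # independent arithmetic: SSB / SSW with 2 and 6 degrees of freedom
  gm <- mean(df$y)
  means <- tapply(df$y, df$group, mean)
  ssb <- 3 * sum((means - gm)^2)
  ssw <- sum((df$y - means[df$group])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- compare_groups(df, "y")
  expect_equal(res$anova_f, f_hand)
  expect_equal(nrow(res$tukey), 3)
  expect_false(res$degenerate)
})

test_that("zero within-group variance everywhere is flagged degenerate", {
  df <- data.frame(group = rep(c("A", "B"), each = 3), y = rep(c(1, 2), each = 3))
  res <- compare_groups(df, "y")
  expect_true(res$degenerate)
  expect_true(is.na(res$anova_p))
})

test_that("an exact linear relation gives R^2 = 1 and the true slope", {
  df <- toy_cohort()
  df$bt_um <- 0.03 * df$cct_um - 1
  fit <- suppressWarnings(fit_bt_cct(df))  # perfect fit upsets summary.lm
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.03)
  expect_equal(fit$intercept, -1)
})

test_that("independent BT and CCT give R^2 near zero at large n", {
  set.seed(8)
  df <- data.frame(bt_um = stats::rnorm(2000, 15, 2),
                   cct_um = stats::rnorm(2000, 540, 35))
  expect_lt(fit_bt_cct(df)$r_squared, 0.01)
})

test_that("R^2 equals the squared Pearson correlation (single covariate)", {
  set.seed(9)
  df <- data.frame(bt_um = stats::rnorm(40, 15, 2),
                   cct_um = stats::rnorm(40, 540, 35))
  df$bt_um <- df$bt_um + 0.01 * df$cct_um
  fit <- fit_bt_cct(df)
  expect_equal(fit$r_squared, stats::cor(df$bt_um, df$cct_um)^2,
               tolerance = 1e-12)
})

test_that("constant CCT is flagged singular", {
  df <- toy_cohort()
  df$cct_um <- 540
  expect_true(fit_bt_cct(df)$singular)
})

test_that("a constructed constant ratio is independent of every factor", {
  df <- toy_cohort()
  df$bt_um <- 0.03 * df$cct_um
  res <- ratio_analysis(df)
  expect_true(all(abs(res$group_ratio$mean - 0.03) < 1e-12))
  expect_true(all(res$factor_p > 0.05))
})

test_that("an injected age effect on the ratio is detected", {
  set.seed(10)
  df <- do.call(rbind, replicate(6, toy_cohort(), simplify = FALSE))
  df$bt_um <- df$cct_um * (0.02 + 0.0004 * df$age_y) +
    stats::rnorm(nrow(df), 0, 0.05)
  res <- ratio_analysis(df)
  expect_lt(res$factor_p[["age"]], 0.01)
})

test_that("records with non-positive CCT are rejected, Holm adjusts upward", {
  df <- toy_cohort()
  df$cct_um[1] <- -5
  res <- ratio_analysis(df, adjust = "holm")
  expect_equal(res$n_rejected, 1)
  expect_true(all(res$factor_p_adj >= res$factor_p, na.rm = TRUE))
})
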