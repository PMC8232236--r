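test_that("KS screen accepts normal samples and rejects uniform ones", {
  accept <- 0L
  for (seed in 1:100) {
    withr::local_seed(seed)
    if (ks_normality(rnorm(1e4))$p_value > 0.05) accept <- accept + 1L
  }
  expect_gte(accept, 94L)
  reject <- 0L
  for (seed in 1:100) {
    withr::local_seed(seed)
    if (ks_normality(runif(500))$p_value < 0.01) reject <- reject + 1L
  }
  expect_gte(reject, 95L)
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("one-way ANOVA matches pencil-and-paper sums of squares", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  res <- oneway_anova(df, v, g)
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$eta_squared, 13.5 / (13.5 + 4) , tolerance = 1e-10)
  # identical group means -> F = 0
  df0 <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(oneway_anova(df0, v, g)$statistic, 0)
  expect_error(oneway_anova(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
               "at least 2 values")
})

test_that("four groups of 64 connection observations give df (3, 252)", {
  withr::local_seed(5)
  df <- data.frame(v = rnorm(256), g = rep(letters[1:4], each = 64))
  res <- oneway_anova(df, v, g)
  expect_equal(res$df_between, 3)
  expect_equal(res$df_within, 252)
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  withr::local_seed(8)
  df <- data.frame(v = c(rnorm(15), rnorm(15, 0.5)),
                   g = rep(c("a", "b"), each = 15))
  res <- oneway_anova(df, v, g)
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("ANOVA p-values are uniform under the null", {
  pvals <- numeric(500)
  for (i in seq_len(500)) {
    withr::local_seed(i)
    df <- data.frame(v = rnorm(40), g = rep(letters[1:4], each = 10))
    pvals[i] <- oneway_anova(df, v, g)$p_value
  }
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("Tukey HSD rejects designed shifts and reduces to the t-test for 2 groups", {
  withr::local_seed(3)
  base <- rnorm(22 * 3)
  df <- data.frame(v = c(base, rnorm(22, mean = 10)),
                   g = rep(letters[1:4], each = 22))
  tk <- tukey_hsd(df, v, g)
  involving_d <- grepl("d", tk$contrast)
  expect_true(all(tk$reject[involving_d]))
  expect_false(any(tk$reject[!involving_d]))
  # all groups identical -> no rejections
  df0 <- data.frame(v = rep(rnorm(10), 4), g = rep(letters[1:4], each = 10))
  expect_false(any(tukey_hsd(df0, v, g)$reject))
  # two-group limit: adjusted p equals the two-sided pooled t-test p
  df2 <- df[df$g %in% c("a", "b"), ]
  tk2 <- tukey_hsd(df2, v, g)
  tt <- t.test(v ~ g, data = df2, var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey rejections are a subset of unadjusted pairwise t-test rejections", {
  withr::local_seed(11)
  df <- data.frame(v = c(rnorm(20), rnorm(20, 0.6), rnorm(20, 1.0)),
                   g = rep(letters[1:3], each = 20))
  tk <- tukey_hsd(df, v, g)
  praw <- with(df, pairwise.t.test(v, g, p.adjust.method = "none",
                                   pool.sd = TRUE))$p.value
  raw <- c(praw[1, 1], praw[2, 1], praw[2, 2]) < 0.05  # b-a, c-a, c-b
  expect_true(all(!tk$reject | raw))
})

test_that("Bonferroni thresholds follow alpha / m", {
  res <- bonferroni(c(0.009, 0.2, 0.04, 0.011, 0.5))
  expect_equal(res$threshold, rep(0.01, 5))
  expect_equal(res$reject, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bonferroni(0.04)$reject, TRUE)   # m = 1: raw test
  expect_false(any(bonferroni(rep(1, 10))$reject))
  expect_error(bonferroni(numeric(0)), "empty")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  df <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(pearson_corr(df, x, y)$r, 1)
  df2 <- data.frame(x = 1:10, y = -(1:10))
  res <- pearson_corr(df2, x, y)
  expect_equal(res$r, -1)
  expect_equal(res$n, 10L)
  expect_error(pearson_corr(data.frame(x = rep(1, 5), y = rnorm(5)), x, y),
               "constant")
  expect_error(pearson_corr(data.frame(x = 1:2, y = 2:3), x, y), "at least 3")
})

test_that("group summaries flag degenerate groups and zero spread", {
  conn <- tidyr::expand_grid(subject_id = c("a", "b"),
                             band = "alpha",
                             source = c("x", "y"), sink = c("x", "y"))
  conn <- conn[conn$source != conn$sink, ]
  conn$group <- ifelse(conn$subject_id == "a", "g1", "g2")
  conn$pdc <- 0.25
  expect_warning(out <- group_summary(conn, "alpha"), "single subject")
  expect_equal(out$mean, c(0.25, 0.25))
  expect_true(all(is.na(out$sd)))
  # equal tensors across subjects of one group -> sd 0
  conn2 <- rbind(conn, transform(conn, subject_id = paste0(subject_id, "2")))
  out2 <- group_summary(conn2, "alpha")
  expect_equal(out2$sd, c(0, 0))
})

test_that("connectivity ANOVA layouts expose the two observation units", {
  co <- tiny_cohort()
  cc <- cohort_connectivity(co)
  subj <- connectivity_anova(cc$connectivity, "delta", layout = "subject")
  expect_equal(subj$df_between, 3)
  expect_equal(subj$df_within, 12 - 4)
  conn <- connectivity_anova(cc$connectivity, "delta", layout = "connection")
  expect_equal(conn$df_within, 4 * 64 - 4)
  expect_equal(conn$n, 256L)
})
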