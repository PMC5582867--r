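test_that("identical groups give a null t-test result", {
  df <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("x", "y"), each = 3))
  out <- tidy(compare_two_groups(df, v, g, method = "t_test"))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
})

test_that("the Mann-Whitney test is exact for small samples", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  out <- tidy(compare_two_groups(df, v, g, method = "mann_whitney"))
  expect_equal(out$statistic, 0)     # U = 0
  expect_equal(out$p.value, 0.1)     # 2/20 of all rank assignments
})

test_that("exact Mann-Whitney p equals the full permutation enumeration", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      m <- sample(3:5, 1); n <- sample(3:5, 1)
      a <- round(rnorm(m, 0, 10), 6)
      b <- round(rnorm(n, 1, 10), 6)
      df <- data.frame(v = c(a, b), g = rep(c("a", "b"), c(m, n)))
      p_pkg <- tidy(compare_two_groups(df, v, g, method = "mann_whitney"))$p.value
      expect_equal(p_pkg, mw_permutation_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("group validation rejects degenerate inputs", {
  expect_error(compare_two_groups(data.frame(v = 1:3, g = c("a", "a", "a")),
                                  v, g), "two levels")
  expect_error(compare_two_groups(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")),
                                  v, g, method = "t_test"), "two observations")
})

test_that("the t-test holds its nominal type-I error rate under the null", {
  withr::with_seed(42, {
    n_sim <- 10000
    rejections <- vapply(seq_len(n_sim), function(i) {
      df <- data.frame(v = rnorm(12), g = rep(c("a", "b"), each = 6))
      tidy(compare_two_groups(df, v, g, method = "t_test"))$p.value < 0.05
    }, logical(1))
    expect_lt(abs(mean(rejections) - 0.05), 0.01)
  })
})

test_that("two-way ANOVA F statistics match the hand sums-of-squares decomposition", {
  df <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), r = 1:3)
  df$v <- c(3, 7, 5, 9, 4, 8, 6, 10, 2, 9, 4, 11)
  fit <- two_way_anova(df, v, a, b, posthoc = "none")
  out <- tidy(fit)
  oracle <- balanced_twoway_F(df$v, df$a, df$b)
  expect_equal(out$statistic[out$term == "f1"], unname(oracle["FA"]),
               tolerance = 1e-10)
  expect_equal(out$statistic[out$term == "f2"], unname(oracle["FB"]),
               tolerance = 1e-10)
  expect_equal(out$statistic[out$term == "f1:f2"], unname(oracle["FAB"]),
               tolerance = 1e-10)
})

test_that("null effects and additive constructions behave as expected", {
  # f1-level means exactly equal (the replicate effect is shared across f1
  # levels) -> F(f1) = 0, p = 1, with nonzero residual variance
  df <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), r = 1:4)
  rep_eff <- c(0.4, -0.1, 0.3, -0.6)
  df$v <- ifelse(df$b == "b1", 2, 5) + rep_eff[df$r]
  out <- tidy(two_way_anova(df, v, a, b, posthoc = "none"))
  expect_equal(out$statistic[out$term == "f1"], 0, tolerance = 1e-20)
  expect_equal(out$p.value[out$term == "f1"], 1, tolerance = 1e-12)
  # cell means exactly additive (replicates vary symmetrically within cells)
  # -> zero interaction sum of squares
  df2 <- expand.grid(a = c("a1", "a2", "a3"), b = c("b1", "b2"), r = 1:2)
  row_eff <- c(a1 = 0, a2 = 2, a3 = 5)
  col_eff <- c(b1 = 0, b2 = 3)
  df2$v <- row_eff[df2$a] + col_eff[df2$b] + ifelse(df2$r == 1, 0.5, -0.5)
  out2 <- tidy(two_way_anova(df2, v, a, b, posthoc = "none"))
  expect_lt(out2$sumsq[out2$term == "f1:f2"], 1e-20)
})

test_that("a single-level factor is rejected and one-way reduction matches hand computation", {
  df <- data.frame(v = rnorm(12), a = rep(c("x", "y", "z"), 4),
                   b = rep("only", 12))
  expect_error(two_way_anova(df, v, a, b), "two levels")
  fit <- two_way_anova(df, v, a, posthoc = "none")
  out <- tidy(fit)
  # hand one-way F
  gm <- mean(df$v)
  ssb <- sum(tapply(df$v, df$a, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum((df$v - ave(df$v, df$a))^2)
  F_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(out$statistic[out$term == "f1"], F_hand, tolerance = 1e-10)
})

test_that("post-hoc corrections return valid, ordered adjusted p-values", {
  withr::with_seed(44, {
    df <- data.frame(v = c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 4)),
                     a = rep(c("g1", "g2", "g3"), each = 6),
                     b = rep(c("u", "w"), 9))
    bon <- two_way_anova(df, v, a, b, posthoc = "bonferroni")$posthoc
    expect_true(all(bon$p.adj >= 0 & bon$p.adj <= 1))
    # the widest separation must be the most significant
    expect_equal(which.min(bon$p.adj), which.max(abs(bon$diff)))
    nk <- two_way_anova(df, v, a, b, posthoc = "newman_keuls")$posthoc
    expect_true(all(nk$p.adj >= 0 & nk$p.adj <= 1))
    # Newman-Keuls is never more conservative than Bonferroni here
    expect_true(all(nk$p.adj <= bon$p.adj + 1e-12))
  })
})
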