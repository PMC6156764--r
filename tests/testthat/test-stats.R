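test_that("proliferation rates follow the control / non-control definitions", {
  expect_equal(proliferation_rate(100, 20, 30, 8), 0.4)
  expect_equal(proliferation_rate(100, 0, 50, 0, is_control = TRUE), 0.5)
  expect_error(proliferation_rate(100, 0, 50, 0, condition = "a9"),
               "zero transfected cells in condition 'a9'")
})

test_that("condition summaries keep count invariants and rate definitions", {
  cells <- data.frame(
    condition = rep(c("ctrl", "a9"), each = 6),
    replicate = rep(c(1, 1, 1, 2, 2, 2), 2),
    transfected = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                    TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    proliferating = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                      TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  s <- summarize_conditions(cells, control_condition = "ctrl")
  expect_true(all(s$n_transfected_proliferating <=
                    pmin(s$n_transfected, s$n_proliferating)))
  expect_true(all(s$proliferation_rate >= 0 & s$proliferation_rate <= 1))
  ctrl1 <- s[s$condition == "ctrl" & s$replicate == 1, ]
  expect_equal(ctrl1$proliferation_rate,
               ctrl1$n_proliferating / ctrl1$n_total)
  a91 <- s[s$condition == "a9" & s$replicate == 1, ]
  expect_equal(a91$proliferation_rate,
               a91$n_transfected_proliferating / a91$n_transfected)
  # rates are invariant to cell order
  s2 <- summarize_conditions(cells[sample(nrow(cells)), ], "ctrl")
  expect_equal(s$proliferation_rate, s2$proliferation_rate)
})

test_that("identical groups show no significant pairs", {
  g <- list(a = c(0.5, 0.5, 0.5), b = c(0.5, 0.5, 0.5))
  # zero within- and between-group variance degenerates the F statistic;
  # add negligible jitter to keep the design estimable
  g$a <- g$a + c(-1e-9, 0, 1e-9); g$b <- g$b + c(-1e-9, 0, 1e-9)
  cmp <- compare_groups(g)
  expect_true(all(cmp$tukey$p_adj > 0.05))
  expect_true(all(cmp$tukey$stars == "ns"))
})

test_that("two balanced groups give F equal to the squared t statistic", {
  a <- c(0.42, 0.47, 0.44, 0.5)
  b <- c(0.31, 0.29, 0.35, 0.33)
  cmp <- compare_groups(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$anova_F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$anova_p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F matches the closed form from group means and SSE", {
  a <- c(0.50, 0.51, 0.49); b <- c(0.10, 0.11, 0.09)
  cmp <- compare_groups(list(a = a, b = b))
  grand <- mean(c(a, b))
  ss_between <- 3 * (mean(a) - grand)^2 + 3 * (mean(b) - grand)^2
  ss_within <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  f_oracle <- (ss_between / 1) / (ss_within / 4)
  expect_equal(cmp$anova_F, f_oracle, tolerance = 1e-10)
  expect_lt(cmp$tukey$p_adj, 0.001)
  expect_identical(cmp$tukey$stars, "***")
})

test_that("a failed Levene precheck blocks the ANOVA but keeps descriptives", {
  a <- c(0.500, 0.5001, 0.4999, 0.5000)
  b <- c(0.05, 0.95, 0.10, 0.90)
  cmp <- compare_groups(list(a = a, b = b))
  expect_false(cmp$levene_ok)
  expect_true(is.na(cmp$anova_p))
  expect_null(cmp$tukey)
  expect_equal(nrow(cmp$descriptives), 2)
})

test_that("group comparison validates its inputs", {
  expect_error(compare_groups(list(a = c(0.1, 0.2))), "at least 2 conditions")
  expect_error(compare_groups(list(a = c(0.1, 0.2), b = 0.3)),
               "at least 2 replicates")
})

test_that("the two-group test honours its conventions and extremes", {
  expect_equal(two_group_test(c(1, 1, 1), c(1, 1, 1)), 1)
  set.seed(13)
  a <- c(0, 0, 0) + rnorm(3, 0, 1e-6)
  b <- c(10, 10, 10) + rnorm(3, 0, 1e-6)
  expect_lt(two_group_test(a, b), 0.001)
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(19)
  a <- rnorm(10, 0.3, 0.1)
  b <- rnorm(10, 0.38, 0.1)
  p_t <- two_group_test(a, b)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  n_perm <- 1e5
  hits <- 0L
  set.seed(20)
  for (chunk in 1:100) {
    idx <- replicate(1000, sample.int(20, 10))
    m_a <- colMeans(matrix(pool[idx], nrow = 10))
    tot <- sum(pool)
    m_b <- (tot - m_a * 10) / 10
    hits <- hits + sum(abs(m_a - m_b) >= obs - 1e-12)
  }
  p_perm <- hits / (100 * 1000)
  expect_lt(abs(p_t - p_perm), 0.02)
})
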