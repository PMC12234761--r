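test_that("signed-rank test handles canonical cases", {
  expect_equal(wilcoxon_signed_rank(rep(0, 6))$p, 1)
  # five strictly positive differences: the two extreme sign patterns
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p, 1 / 16)
  # agrees with the tie-free distribution in wilcox.test
  set.seed(2)
  d <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("signed-rank exact p matches brute-force sign enumeration", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(c(0, 1, 2), 1))  # induces ties and zeros
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_signed_rank_p(d),
                 info = paste("dataset", i))
  }
})

test_that("large-sample signed-rank path matches wilcox.test", {
  set.seed(14)
  d <- rnorm(40)
  ours <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal approximation with tie correction")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("Kruskal-Wallis matches the hand-computed example and kruskal.test", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same, exact = FALSE)$statistic, 0)

  g <- list(c(1, 2), c(3, 4), c(5, 6))
  h <- kruskal_wallis(g, exact = FALSE)
  # ranks 1..6, rank sums 3, 7, 11: H = 12/42 * (9/2 + 49/2 + 121/2) - 21
  expect_equal(h$statistic, 12 / 42 * (9 + 49 + 121) / 2 - 21)
  ref <- stats::kruskal.test(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
  expect_equal(h$statistic, unname(ref$statistic))
  expect_equal(h$p, ref$p.value, tolerance = 1e-12)

  set.seed(15)
  x <- c(rnorm(8), rnorm(8, 1), rnorm(8))
  grp <- rep(1:3, each = 8)
  ours <- kruskal_wallis(split(x, grp), exact = FALSE)
  ref2 <- stats::kruskal.test(x, grp)
  expect_equal(ours$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref2$p.value, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis agrees with Mann-Whitney ordering", {
  set.seed(16)
  a <- rnorm(4)
  b <- rnorm(4, 0.5)
  kw <- kruskal_wallis(list(a, b), exact = TRUE)
  mw <- mann_whitney_u(a, b, exact = TRUE)
  expect_equal(kw$p, mw$p, tolerance = 1e-12)
})

test_that("Mann-Whitney handles canonical cases and the Bonferroni cap", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 3 * 3 / 2)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6), bonferroni_m = 6)$p_adjusted,
               min(1, 6 * 0.1))
  big <- mann_whitney_u(c(1, 2), c(1.5, 2.5), bonferroni_m = 50)
  expect_equal(big$p_adjusted, 1)

  # tie-free exact agrees with wilcox.test's exact distribution
  set.seed(17)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(mann_whitney_u(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Mann-Whitney exact p matches brute-force enumeration", {
  set.seed(18)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- round(rnorm(n1), 1); b <- round(rnorm(n2), 1)
    expect_equal(mann_whitney_u(a, b, exact = TRUE)$p,
                 oracle_mann_whitney_p(a, b), info = paste("dataset", i))
  }
})

test_that("Kruskal-Wallis exact p matches full permutation enumeration", {
  set.seed(19)
  for (i in 1:5) {
    sizes <- sample(2:3, 3, replace = TRUE)
    g <- lapply(sizes, function(n) round(rnorm(n), 1))
    expect_equal(kruskal_wallis(g, exact = TRUE)$p, oracle_kruskal_p(g),
                 tolerance = 1e-12, info = paste("dataset", i))
  }
})

test_that("summaries use type-7 quartiles and flag non-normal cells", {
  tab <- data.frame(setting = "s", outcome = "o", value = c(1, 2, 3, 4))
  s <- summarize_outcomes(tab)
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr, unname(diff(quantile(1:4, c(0.25, 0.75)))))
  tab8 <- data.frame(setting = "s", outcome = "o", value = 1:8)
  s8 <- summarize_outcomes(tab8)
  expect_equal(s8$iqr, 6.25 - 2.75)  # type-7 quartiles of 1..8
  one <- summarize_outcomes(data.frame(setting = "s", outcome = "o", value = 5))
  expect_equal(one$median, 5)
  expect_equal(one$iqr, 0)
  set.seed(20)
  skew <- data.frame(setting = "s", outcome = "o", value = rexp(100)^2)
  expect_true(summarize_outcomes(skew)$non_normal)
})
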