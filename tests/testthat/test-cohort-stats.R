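test_that("normality screen routes clean normal and skewed samples correctly", {
  normal_ok <- 0; skew_flag <- 0
  for (s in 1:100) {
    set.seed(s)
    if (ks_normality(rnorm(1000))$verdict == "normal") normal_ok <- normal_ok + 1
    if (ks_normality(rexp(1000))$verdict == "non-normal") skew_flag <- skew_flag + 1
  }
  expect_gte(normal_ok, 90)   # type-I error of the screen stays near nominal
  expect_gte(skew_flag, 95)   # strong skew is essentially always caught

  const <- ks_normality(rep(3.2, 50))
  expect_true(const$degenerate)
  expect_equal(const$verdict, "non-normal")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
})

test_that("two-group test matches textbook closed forms", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  got <- two_group_test(x, y, route = "t")
  # pooled-variance two-sample t computed by hand
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- abs(mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$p, 2 * pt(-t_hand, df = 6))

  same <- two_group_test(c(1, 2, 3), c(1, 2, 3), route = "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  sep <- two_group_test(c(10, 11, 12), c(1, 2, 3), route = "wilcox")
  expect_equal(sep$statistic, 0)  # fully separated: smaller U is zero
  # minimal attainable p for 3 vs 3 under the corrected normal approximation
  expect_lt(sep$p, 0.1)
  expect_lte(sep$p, suppressWarnings(
    wilcox.test(c(10, 11, 12), c(4, 2, 3), exact = FALSE)$p.value))

  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney U and ROC AUC obey AUC = U_favorable/(n1*n2)", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(12, 0.4); y <- rnorm(9)
    got <- two_group_test(x, y, route = "wilcox")
    auc <- attr(roc_curve(c(x, y), rep(c("CR", "non-CR"), c(12, 9))), "auc")
    u_fav <- 12 * 9 - got$statistic   # larger-group-favorable complement
    expect_equal(auc, u_fav / (12 * 9), tolerance = 1e-12)
  }
})

test_that("both comparison routes keep nominal type-I error", {
  set.seed(71)
  p_t <- p_w <- numeric(5000)
  for (i in 1:5000) {
    x <- rnorm(20); y <- rnorm(20)
    p_t[i] <- two_group_test(x, y, route = "t")$p
    p_w[i] <- two_group_test(x, y, route = "wilcox")$p
  }
  expect_gte(mean(p_t < 0.05), 0.03); expect_lte(mean(p_t < 0.05), 0.07)
  expect_gte(mean(p_w < 0.05), 0.03); expect_lte(mean(p_w < 0.05), 0.07)
})

test_that("chi-square reproduces the clinical characteristics statistics", {
  figo <- matrix(c(17, 18, 8, 10), nrow = 2)        # stage II vs III+IV
  hist <- matrix(c(33, 15, 2, 3), nrow = 2)         # squamous vs adeno
  node <- matrix(c(25, 11, 10, 7), nrow = 2)        # node positive vs negative
  expect_equal(round(chi_square_test(figo)$statistic, 2), 0.08)
  expect_equal(round(chi_square_test(hist)$statistic, 2), 1.67)
  expect_equal(round(chi_square_test(node)$statistic, 2), 0.58)
  expect_equal(chi_square_test(figo)$df, 1)
})

test_that("chi-square is invariant to transposition and row swaps", {
  set.seed(81)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), nrow = 2)
    ref <- chi_square_test(tab)$statistic
    expect_equal(chi_square_test(t(tab))$statistic, ref)
    expect_equal(chi_square_test(tab[2:1, ])$statistic, ref)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("ICC handles perfect agreement and independence", {
  x <- rnorm(30, 5)
  perfect <- icc_two_rater(cbind(x, x))
  expect_equal(perfect$icc, 1)

  set.seed(91)
  null <- icc_two_rater(cbind(rnorm(500), rnorm(500)))
  expect_lt(abs(null$icc), 0.1)

  expect_error(icc_two_rater(cbind(c(1, NA, 3, 4, 5), c(1, 2, 3, 4, 5))),
               "missing")
  expect_error(icc_two_rater(cbind(1:3, 1:3)), "5 subjects")
})

test_that("ICC(A,1) and its CI agree with an independent reference implementation", {
  set.seed(42)
  subj <- rnorm(20, 10, 2)
  r1 <- subj + rnorm(20, 0, 0.8)
  r2 <- subj + 0.3 + rnorm(20, 0, 0.8)
  got <- icc_two_rater(cbind(r1, r2), model = "A")
  # frozen reference: two-way random-effects absolute-agreement single
  # measures, cross-computed with an independent ANOVA-based implementation
  expect_equal(got$icc, 0.909579, tolerance = 1e-5)
  expect_equal(round(got$lower, 2), 0.78)
  expect_equal(round(got$upper, 2), 0.96)
  expect_lte(got$lower, got$icc); expect_gte(got$upper, got$icc)

  cons <- icc_two_rater(cbind(r1, r2), model = "C")
  expect_gt(cons$icc, got$icc)  # consistency ignores the rater offset
})

test_that("cohort-wide comparison table uses the conventional routing", {
  coh <- simulate_cohort(seed = 5)
  cmp <- compare_groups(coh)
  expect_equal(nrow(cmp), 18)
  expect_true(all(cmp$test[grepl("^(adc|d_fast|f_p)", cmp$parameter)] ==
                  "mann-whitney"))
  expect_true(all(cmp$test[grepl("^(d_slow|ddc|alpha)", cmp$parameter)] == "t"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  # U is reported on the smaller-of-the-two convention, bounded by n1*n2/2
  u_rows <- cmp$test == "mann-whitney"
  expect_true(all(cmp$statistic[u_rows] <= 35 * 18 / 2))
})
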