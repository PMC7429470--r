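toy_scores <- c(0.9, 0.8, 0.7, 0.75, 0.5, 0.4)
toy_labels <- rep(c("CR", "non-CR"), each = 3)

test_that("AUC equals brute-force pair counting, ties counted one half", {
  expect_equal(attr(roc_curve(toy_scores, toy_labels), "auc"), 8 / 9)
  set.seed(101)
  for (i in 1:15) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    scores <- sample(seq(0, 1, 0.1), n1 + n2, replace = TRUE)  # forces ties
    pos <- rep(c(TRUE, FALSE), c(n1, n2))
    oracle <- pair_count_auc(scores, pos)
    got <- attr(roc_curve(scores, ifelse(pos, "CR", "non-CR")), "auc")
    expect_equal(got, max(oracle, 1 - oracle), tolerance = 1e-12)
  }
})

test_that("ROC curve has the stated structure", {
  rc <- roc_curve(toy_scores, toy_labels)
  # sentinels present and curve monotone from (0,0) to (1,1)
  expect_true(all(is.infinite(range(rc$threshold))))
  expect_equal(c(min(rc$fpr), max(rc$fpr)), c(0, 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  # thresholds sit at midpoints between distinct scores
  expect_true(0.775 %in% rc$threshold)
  expect_error(roc_curve(1:5, rep("CR", 5)), "two classes")
})

test_that("AUC is invariant under monotone transforms and flips with polarity", {
  set.seed(111)
  scores <- rnorm(60); labs <- rep(c("CR", "non-CR"), 30)
  ref <- attr(roc_curve(scores, labs), "auc")
  expect_equal(attr(roc_curve(exp(scores), labs), "auc"), ref)
  expect_equal(attr(roc_curve(qnorm(pnorm(scores))^3, labs), "auc"), ref,
               tolerance = 1e-9)
  # reversing score polarity flips the underlying concordance; the reported
  # oriented AUC is preserved and the direction flag flips
  fl <- roc_curve(-scores, labs)
  expect_equal(attr(fl, "auc"), ref)
  expect_false(identical(attr(fl, "higher_is_positive"),
                         attr(roc_curve(scores, labs), "higher_is_positive")))
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(121)
  scores <- rnorm(2000)
  labs <- sample(rep(c("CR", "non-CR"), 1000))
  expect_lt(abs(attr(roc_curve(scores, labs), "auc") - 0.5), 0.05)
})

test_that("Youden cutoff equals the exhaustive scan and applies its tie-breaks", {
  yc <- youden_cutoff(roc_curve(toy_scores, toy_labels))
  expect_equal(yc$youden, 2 / 3)
  # two thresholds tie at J = 2/3; the rule prefers the higher sensitivity
  expect_equal(yc$sensitivity, 100)
  expect_equal(yc$specificity, 100 * 2 / 3)
  expect_equal(yc$threshold, 0.6)

  set.seed(131)
  for (i in 1:15) {
    scores <- sample(seq(0, 1, 0.05), 30, replace = TRUE)
    pos <- runif(30) < 0.5
    if (length(unique(pos)) < 2) next
    rc <- roc_curve(scores, ifelse(pos, "CR", "non-CR"))
    ws <- if (attr(rc, "higher_is_positive")) scores else -scores
    expect_equal(youden_cutoff(rc)$youden, scan_youden(ws, pos),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and perfect curves are flagged", {
  flat <- roc_curve(rep(1, 10), rep(c("CR", "non-CR"), 5))
  expect_true(youden_cutoff(flat)$degenerate)
  expect_equal(attr(flat, "auc"), 0.5)

  perf <- roc_curve(c(5, 6, 7, 1, 2, 3), toy_labels)
  expect_equal(attr(perf, "auc"), 1)
  expect_equal(youden_cutoff(perf)$youden, 1)
  ci <- suppressWarnings(auc_with_ci(c(5, 6, 7, 1, 2, 3), toy_labels))
  expect_equal(ci$upper, 1)
})

test_that("confidence intervals bracket the AUC under both methods", {
  set.seed(141)
  scores <- c(rnorm(35, 1.26, 0.16), rnorm(18, 1.00, 0.16))
  labs <- rep(c("CR", "non-CR"), c(35, 18))
  for (m in c("delong", "hanley")) {
    ci <- auc_with_ci(scores, labs, method = m)
    expect_lte(ci$lower, ci$auc)
    expect_gte(ci$upper, ci$auc)
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
  }
})

test_that("predictive values follow their confusion-matrix definitions", {
  perf <- predictive_values(toy_labels, toy_labels)
  expect_equal(unlist(perf[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100))

  labels <- rep(c("CR", "non-CR"), c(37, 16))
  predictions <- rep(c("CR", "non-CR", "CR", "non-CR"), c(31, 6, 4, 12))
  pv <- predictive_values(labels, predictions)
  expect_equal(pv$sensitivity, 83.78)
  expect_equal(pv$specificity, 75.00)
  expect_equal(pv$ppv, 88.57)
  expect_equal(pv$npv, 66.67)

  all_pos <- predictive_values(toy_labels, rep("CR", 6))
  expect_true(is.na(all_pos$npv))
  expect_equal(all_pos$sensitivity, 100)
})

test_that("the per-parameter ROC table is coherent", {
  coh <- simulate_cohort(seed = 9)
  tab <- roc_table(coh, c("adc_t1", "alpha_delta"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$auc >= 0.5 & tab$auc <= 1))
  expect_true(all(tab$ci_lower <= tab$auc & tab$ci_upper >= tab$auc))
  expect_true(all(tab$direction == "higher"))  # both markers rise with response
})
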