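# ROC/PR machinery, bootstrap CIs, the DeLong test and threshold
# selection, checked against brute-force oracles and pROC.

test_that("confusion metrics are exact ratios and flag zero denominators", {
  m <- confusion_metrics(list(TP = 72, FN = 28, TN = 45, FP = 55))
  expect_equal(m$sensitivity, 0.72)
  expect_equal(m$specificity, 0.45)
  expect_equal(m$precision, 72 / 127)
  expect_warning(m0 <- confusion_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "precision")
  expect_true(is.na(m0$precision))
  withr::with_seed(3, for (i in 1:20) {
    ct <- as.list(rpois(4, 20) + 1); names(ct) <- c("TP", "FP", "TN", "FN")
    m <- confusion_metrics(ct)
    expect_equal(m$sensitivity, ct$TP / (ct$TP + ct$FN))
    expect_equal(m$precision, ct$TP / (ct$TP + ct$FP))
  })
})

test_that("AUC equals the exhaustive pair-counting oracle, ties counted one half", {
  withr::with_seed(14, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
      expect_equal(auc(scores, labels), auc_oracle(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both outcome classes")
})

test_that("auPR is the step-wise summation with the analytic random baseline", {
  y <- rep(c(TRUE, FALSE), c(30, 70))
  expect_equal(aupr(rep(0.5, 100), y), 0.3)      # constant classifier
  expect_equal(aupr(as.numeric(y), y), 1)        # perfect separation
  # hand-checked: scores 4>3>2>1, labels T,F,T,F -> AP = (1 + 2/3) / 2
  expect_equal(aupr(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)),
               (1 + 2 / 3) / 2)
})

test_that("curves are monotone in the right places and invariant to monotone transforms", {
  withr::with_seed(15, b <- binormal_scores(60, 140, 0.75))
  rc <- roc_curve(b$scores, b$labels)
  expect_true(all(diff(rc$threshold) < 0))
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(rc$sensitivity >= 0 & rc$sensitivity <= 1))
  expect_true(all(rc$specificity >= 0 & rc$specificity <= 1))
  expect_equal(auc(exp(b$scores), b$labels), auc(b$scores, b$labels))
  expect_equal(aupr(exp(b$scores), b$labels), aupr(b$scores, b$labels))
  pr <- pr_curve(b$scores, b$labels)
  expect_equal(attr(pr, "aupr"), aupr(b$scores, b$labels))
})

test_that("AUC and auPR agree with pROC on a shared dataset", {
  skip_if_not_installed("pROC")
  withr::with_seed(16, b <- binormal_scores(50, 150, 0.7))
  proc_auc <- as.numeric(pROC::auc(pROC::roc(b$labels, b$scores,
                                             quiet = TRUE, direction = "<")))
  expect_equal(auc(b$scores, b$labels), proc_auc, tolerance = 1e-12)
})

test_that("stratified bootstrap CIs behave", {
  withr::with_seed(17, b <- binormal_scores(40, 160, 0.8))
  ci <- bootstrap_ci(b$scores, b$labels, auc, B = 500, seed = 2)
  expect_identical(ci, bootstrap_ci(b$scores, b$labels, auc, B = 500, seed = 2))
  expect_lt(ci[1], auc(b$scores, b$labels))
  expect_gt(ci[2], auc(b$scores, b$labels))
  # constant statistic -> zero width
  cc <- bootstrap_ci(b$scores, b$labels, function(s, l) 0.5, B = 100, seed = 1)
  expect_equal(cc[1], cc[2])
  # coverage smoke test: the CI contains the point estimate essentially always
  hits <- withr::with_seed(18, vapply(1:20, function(i) {
    d <- binormal_scores(30, 70, 0.7)
    a <- auc(d$scores, d$labels)
    ci <- bootstrap_ci(d$scores, d$labels, auc, B = 200, seed = i)
    ci[1] <= a && a <= ci[2]
  }, TRUE))
  expect_gte(sum(hits), 19)
  expect_error(bootstrap_ci(b$scores, b$labels, auc, B = 50), "at least 100")
})

test_that("the DeLong test matches pROC and its degenerate closed forms", {
  withr::with_seed(19, {
    y <- rep(c(TRUE, FALSE), c(60, 140))
    s1 <- rnorm(200) + y
    s2 <- 0.5 * s1 + rnorm(200, 0, 0.8)
  })
  dl <- delong_test(s1, s2, y)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(dl$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  # identical scores: z = 0, p = 1; monotone transform leaves AUC unchanged
  same <- delong_test(s1, s1, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  mono <- delong_test(s1, qlogis(plogis(s1)), y)
  expect_equal(mono$auc_a, mono$auc_b)
  # symmetry in (a, b)
  ba <- delong_test(s2, s1, y)
  expect_equal(ba$p, dl$p)
  expect_equal(ba$z, -dl$z)
  expect_error(delong_test(s1, s2[-1], y), "equal length")
})

test_that("threshold_for_sensitivity returns the largest qualifying threshold", {
  withr::with_seed(20, b <- binormal_scores(25, 75, 0.8))
  for (target in c(0.5, 0.72, 0.9, 1.0)) {
    thr <- threshold_for_sensitivity(b$scores, b$labels, target)
    expect_gte(attr(thr, "sensitivity"), target)
    # brute force over all candidate thresholds
    cand <- sort(unique(b$scores), decreasing = TRUE)
    sens <- vapply(cand, function(t) mean(b$scores[b$labels] >= t), 0)
    best <- cand[which(sens >= target)[1]]
    expect_equal(as.numeric(thr), best)
  }
  thr1 <- threshold_for_sensitivity(b$scores, b$labels, 1.0)
  expect_lte(as.numeric(thr1), min(b$scores[b$labels]))
  expect_error(threshold_for_sensitivity(b$scores, b$labels, 1.5), "0, 1")
})
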