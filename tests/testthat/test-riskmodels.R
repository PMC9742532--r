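# Score tables, imputation, learners, cross-validation, streamlining and
# explanation contracts.

test_that("score tables bin and sum points exactly", {
  tab <- toy_score_table()
  pop <- tibble::tibble(id = 1:3, age = c(55, 39, 61), bmi = c(25, 20, 30))
  out <- apply_score_table(tab, pop)
  expect_equal(out$score, c(2L + 2L, 0L, 4L + 2L))
  expect_equal(out$positive, c(TRUE, FALSE, TRUE))
  # cutoff 0 flags everyone
  tab0 <- score_table("all", tab$items, cutoff = 0L)
  expect_true(all(apply_score_table(tab0, pop)$positive))
})

test_that("score table application equals an independent per-row lookup oracle", {
  pop <- small_cohort(1000, seed = 21)
  tab <- toy_score_table()
  fast <- apply_score_table(tab, pop)
  slow <- vapply(seq_len(nrow(pop)), function(i) {
    s <- 0L
    for (it in tab$items) {
      v <- pop[[it$feature]][i]
      bin <- sum(v >= it$breaks) + 1L
      s <- s + it$points[bin]
    }
    s
  }, 0L)
  expect_equal(fast$score, slow)
  expect_equal(fast$positive, slow >= tab$cutoff)
})

test_that("categorical score items reject undeclared values", {
  tab <- score_table("cat", list(
    list(feature = "sex", categories = list(`0` = 0L, `1` = 2L))), cutoff = 1L)
  expect_equal(apply_score_table(tab, tibble::tibble(sex = c(1, 0)))$score,
               c(2L, 0L))
  expect_error(apply_score_table(tab, tibble::tibble(sex = 3)),
               "outside all declared categories")
})

test_that("score tables round-trip through JSON", {
  tab <- read_score_table(system.file("extdata", "ncdrs_placeholder.json",
                                      package = "dmscreen"))
  expect_s3_class(tab, "score_table")
  expect_equal(tab$cutoff, 25L)
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tab, path)
  back <- read_score_table(path)
  expect_equal(back$items, tab$items)
  expect_equal(back$cutoff, tab$cutoff)
})

test_that("imputation completes tables without leakage and beats median fill", {
  pop <- small_cohort(4000, seed = 17)
  sp <- split_dev_test(pop, 0.6, seed = 1)
  # mask one continuous feature MCAR at 10%, remembering the truth
  dev <- sp$dev; test <- sp$test
  withr::with_seed(2, {
    mask_dev <- runif(nrow(dev)) < 0.1
    mask_test <- runif(nrow(test)) < 0.1
  })
  truth_dev <- dev$wc[mask_dev]; truth_test <- test$wc[mask_test]
  dev$wc[mask_dev] <- NA; test$wc[mask_test] <- NA
  out <- impute_population(dev, test)
  expect_false(anyNA(out$dev$wc) || anyNA(out$test$wc))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  med_fill <- median(dev$wc, na.rm = TRUE)
  expect_lte(rmse(out$dev$wc[mask_dev], truth_dev),
             rmse(rep(med_fill, sum(mask_dev)), truth_dev))
  # leakage contract: test rows filled by dev-fitted models only -> the
  # imputed values must not change when the testing set changes
  out2 <- impute_population(dev, test[1:100, , drop = FALSE])
  expect_equal(out2$test$wc[mask_test[1:100]],
               out$test$wc[1:100][mask_test[1:100]])
  # complete tables pass through unchanged
  clean <- impute_population(sp$dev, sp$test)
  expect_equal(clean$dev, sp$dev)
})

test_that("columns with 20%+ missing data are dropped with a warning", {
  pop <- small_cohort(500, seed = 23)
  pop$sleep_duration[1:200] <- NA
  expect_warning(out <- impute_population(pop), "sleep_duration")
  expect_false("sleep_duration" %in% names(out$dev))
})

test_that("every learner separates two Gaussian blobs", {
  dat <- blob_data(400, sep = 3)
  holdout <- blob_data(200, sep = 3, seed = 100)
  for (lk in dmscreen:::learner_kinds()) {
    m <- fit_risk_model(dat, lk, c("f1", "f2", "f3"), seed = 1,
                        params = list(nrounds = 60))
    p <- predict_risk(m, holdout)
    expect_true(all(p >= 0 & p <= 1), info = lk)
    expect_gt(auc(p, holdout$dm_status), 0.95, label = paste("AUC of", lk))
  }
})

test_that("fits are seed-deterministic and reject degenerate inputs", {
  dat <- blob_data(300)
  for (lk in c("GRADIENT_BOOSTED_TREES", "RANDOM_FOREST", "NEURAL_NET")) {
    m1 <- fit_risk_model(dat, lk, c("f1", "f2"), seed = 5,
                         params = list(nrounds = 40))
    m2 <- fit_risk_model(dat, lk, c("f1", "f2"), seed = 5,
                         params = list(nrounds = 40))
    expect_identical(predict_risk(m1, dat), predict_risk(m2, dat), info = lk)
  }
  single <- dat[dat$dm_status, ]
  expect_error(fit_risk_model(single, "LOGISTIC", c("f1", "f2")),
               "single outcome class")
  expect_error(fit_risk_model(dat, "LOGISTIC", c("f1", "nope")), "nope")
  m <- fit_risk_model(dat, "LOGISTIC", c("f1", "f2"))
  expect_equal(m$base_rate, mean(dat$dm_status))
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  dat <- blob_data(2000, sep = 2, seed = 55)
  dat$dm_status <- withr::with_seed(56, sample(dat$dm_status))
  cv <- cross_validate(dat, "LOGISTIC", c("f1", "f2", "f3"), k = 5, seed = 3)
  expect_gt(cv$auc, 0.45)
  expect_lt(cv$auc, 0.55)
})

test_that("cross-validation folds partition the rows near-equally", {
  pop <- small_cohort(1000, seed = 3)
  cv <- cross_validate(pop, "LOGISTIC", c("age", "rpr", "sbp"), k = 5, seed = 1)
  expect_equal(sum(cv$folds$n), 1000L)
  expect_true(all(cv$folds$n == 200L))
  expect_false(anyNA(cv$oof))
  # clairvoyant scores give pooled AUC 1; constant scores give auPR = prevalence
  y <- pop$dm_status
  expect_equal(auc(as.numeric(y), y), 1)
  expect_equal(aupr(rep(0.3, length(y)), y), mean(y))
  expect_error(cross_validate(pop[1:3, ], "LOGISTIC", "age", k = 5), "k exceeds")
})

test_that("explanations are additive and convert to relative risks", {
  dat <- blob_data(400)
  for (lk in c("GRADIENT_BOOSTED_TREES", "LOGISTIC")) {
    m <- fit_risk_model(dat, lk, c("f1", "f2", "f3"), seed = 2,
                        params = list(nrounds = 60))
    e <- explain_risk(m, dat[1:80, ])
    p <- predict_risk(m, dat[1:80, ])
    tol <- if (lk == "LOGISTIC") 1e-6 else 2e-5  # tree backend is float32
    expect_lt(max(abs(e$logodds - qlogis(p))), tol)
    rr <- contributions_to_rr(e, "f1")
    expect_true(all((rr > 1) == (e$phi[, "f1"] > 0)))
  }
  # closed forms: phi = 0 -> RR 1; base 0, phi = log(3) -> RR 1.5
  e0 <- structure(list(base = 0, phi = matrix(c(0, log(3)), 2, 1,
                    dimnames = list(NULL, "x")), logodds = c(0, log(3))),
                  class = "risk_explanation")
  expect_equal(contributions_to_rr(e0, "x"), c(1, plogis(log(3)) / 0.5))
})

test_that("feature ranking finds the informative feature and orders ties lexicographically", {
  withr::with_seed(8, {
    dat <- tibble::tibble(
      b_noise = rnorm(600), a_noise = rnorm(600), signal = rnorm(600))
    dat$dm_status <- dat$signal + rnorm(600, 0, 0.5) > 0
  })
  m <- fit_risk_model(dat, "GRADIENT_BOOSTED_TREES",
                      c("b_noise", "a_noise", "signal"), seed = 1,
                      params = list(nrounds = 60))
  rk <- rank_features(m, dat)
  expect_equal(rk$feature[1], "signal")
  # rank order invariant to row order
  rk2 <- rank_features(m, dat[rev(seq_len(nrow(dat))), ])
  expect_equal(rk$feature, rk2$feature)
  # all-constant features: zero importance, lexicographic order
  cdat <- tibble::tibble(z = rep(1, 100), a = rep(2, 100),
                         dm_status = rep(c(TRUE, FALSE), 50))
  mc <- fit_risk_model(cdat, "GRADIENT_BOOSTED_TREES", c("z", "a"),
                       params = list(nrounds = 5))
  rkc <- rank_features(mc, cdat)
  expect_equal(rkc$feature, c("a", "z"))
  expect_equal(rkc$importance, c(0, 0))
  expect_error(rank_features(m, dat[0, ]), "no rows")
})

test_that("streamlining keeps the fewest features within tolerance of the best AUC", {
  withr::with_seed(12, {
    n <- 1200
    x_informative <- matrix(rnorm(n * 5), n)
    x_noise <- matrix(rnorm(n * 10), n)
    risk <- rowSums(x_informative)
    dat <- tibble::as_tibble(as.data.frame(cbind(x_informative, x_noise)))
    names(dat) <- c(paste0("inf", 1:5), paste0("noise", 1:10))
    dat$dm_status <- risk + rnorm(n, 0, 1) > 0
  })
  sl <- streamline(dat, "LOGISTIC", names(dat)[1:15], ks = c(5, 10, 15),
                   tolerance = 0.01, seed = 2)
  expect_equal(sl$chosen_k, 5)
  expect_setequal(sl$model$feature_list, paste0("inf", 1:5))
  expect_gte(sl$table$auc[sl$table$k == sl$chosen_k],
             max(sl$table$auc) - 0.01)
  # tolerance 0 picks the argmax
  sl0 <- streamline(dat, "LOGISTIC", names(dat)[1:15], ks = c(5, 10, 15),
                    tolerance = 0, seed = 2)
  expect_equal(sl0$table$auc[sl0$table$k == sl0$chosen_k], max(sl0$table$auc))
  expect_error(streamline(dat, "LOGISTIC", names(dat)[1:15], ks = numeric(0)),
               "non-empty")
})
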