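# Shared fixtures, built in code.

small_cohort <- function(n = 2000, seed = 42, missingness = 0) {
  sample_population(generator_config(n_participants = n, seed = seed,
                                     missingness_rate = missingness))
}

toy_score_table <- function() {
  score_table("toy", list(
    list(feature = "age", breaks = c(40, 60), points = c(0L, 2L, 4L)),
    list(feature = "bmi", breaks = 24, points = c(0L, 2L))
  ), cutoff = 4L)
}

# binormal scores with a given AUC: score ~ N(mu * label, 1),
# mu = sqrt(2) * qnorm(auc)
binormal_scores <- function(n_pos, n_neg, auc_target) {
  mu <- sqrt(2) * qnorm(auc_target)
  list(scores = c(rnorm(n_pos, mu), rnorm(n_neg)),
       labels = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

# exhaustive O(n^2) pair-counting AUC oracle (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# itemized per-person billing oracle for the economics module
ledger_oracle <- function(records, sched, horizon) {
  per_person <- vapply(strsplit(records$tests, ";"), function(tests) {
    tests <- tests[nzchar(tests)]
    sum(vapply(tests, function(t) sched$medical[[t]] + sched$nonmedical[[t]], 0))
  }, 0)
  fn <- sum(records$outcome == "FN")
  b <- sched$complication_per_dm_year[[as.character(horizon)]]
  list(detection = mean(per_person),
       prop_conf = mean(records$confirmatory_done),
       compl = c(low = fn * b[1] / nrow(records),
                 high = fn * b[2] / nrow(records)))
}

# two separable Gaussian blobs for learner sanity checks
blob_data <- function(n = 400, sep = 3, seed = 99) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), each = n / 2)
    tibble::tibble(
      f1 = rnorm(n) + sep * y, f2 = rnorm(n) + sep * y,
      f3 = rnorm(n), dm_status = y)
  })
}
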