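#!/usr/bin/env Rscript
# Model development: 60/40 split, development-trained imputation, a
# seven-learner cross-validated bake-off on the non-laboratory features,
# then top-k streamlining of the boosted-tree model (k in 5..25).

suppressMessages(library(dmscreen))

pop <- read_population("results/cohort.csv")
sp <- split_dev_test(pop, 0.6, seed = 101)
imp <- impute_population(sp$dev, sp$test)
write_population(imp$dev, "results/dev_imputed.csv")
write_population(imp$test, "results/test_imputed.csv")

features <- setdiff(names(imp$dev)[vapply(imp$dev, is.numeric, TRUE)],
                    c("id", "fpg", "p2hpg", "hba1c"))
cat(sprintf("development %d rows, testing %d rows, %d non-laboratory features\n",
            nrow(imp$dev), nrow(imp$test), length(features)))

bakeoff <- dplyr::bind_rows(lapply(
  c("LOGISTIC", "SVM", "RANDOM_FOREST", "KNN", "CENTROID_DISPLACEMENT_KNN",
    "NEURAL_NET", "GRADIENT_BOOSTED_TREES"),
  function(lk) {
    cv <- cross_validate(imp$dev, lk, features, k = 5, seed = 102)
    cat(sprintf("  %-28s cv AUC %.3f  auPR %.3f\n", lk, cv$auc, cv$aupr))
    tibble::tibble(learner = lk, auc = cv$auc, aupr = cv$aupr)
  }))
readr::write_csv(bakeoff, "results/bakeoff.csv", progress = FALSE)
best <- bakeoff$learner[which.max(bakeoff$auc)]
cat("best cross-validated learner:", best, "\n")

# streamline the winning learner to its top-k features
sl <- streamline(imp$dev, best, features, ks = c(5, 10, 15, 20, 25),
                 seed = 103)
cat(sprintf("streamlined model keeps the top %d features (cv AUC %.3f)\n",
            sl$chosen_k, sl$table$auc[sl$table$k == sl$chosen_k]))
readr::write_csv(sl$table, "results/model_selection.csv", progress = FALSE)
readr::write_csv(sl$ranking, "results/feature_ranking.csv", progress = FALSE)

# per-feature relative risks from the additive explanations (available for
# the logistic and boosted-tree backends)
if (sl$model$learner %in% c("LOGISTIC", "GRADIENT_BOOSTED_TREES")) {
  expl <- explain_risk(sl$model, imp$test)
  rr <- dplyr::bind_rows(lapply(sl$model$feature_list[1:5], function(f) {
    tibble::tibble(feature = f, value = imp$test[[f]],
                   rr = contributions_to_rr(expl, f))
  }))
  readr::write_csv(rr, "results/relative_risks.csv", progress = FALSE)
}
saveRDS(sl$model, "scratch/ml_model.rds")  # scratch: binary, not a deliverable
cat("wrote results/bakeoff.csv, model_selection.csv, feature_ranking.csv, relative_risks.csv\n")
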