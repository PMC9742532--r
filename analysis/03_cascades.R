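#!/usr/bin/env Rscript
# Screening cascades and their economics on the testing set. The
# questionnaire score (placeholder point values, published cutoff) anchors
# the matched sensitivity; the trainable model is thresholded to the same
# sensitivity. Four cascade families: risk model alone (confirm with OGTT),
# and FPG / 2hPG / HbA1c screen-first variants.

suppressMessages(library(dmscreen))

test <- read_population("results/test_imputed.csv")
dev <- read_population("results/dev_imputed.csv")
ml <- readRDS("scratch/ml_model.rds")
nc <- read_score_table(system.file("extdata", "ncdrs_placeholder.json",
                                   package = "dmscreen"))
sched <- cost_schedule()
thr_dx <- diagnostic_thresholds()

spec_nc <- cascade_spec("NCDRS", nc, screening_lab = "NONE")
sens_nc <- confusion_metrics(tally(run_cascade(test, spec_nc)))$sensitivity
cat(sprintf("questionnaire at cutoff %d: sensitivity %.3f\n", nc$cutoff, sens_nc))

thr_ml <- threshold_for_sensitivity(predict_risk(ml, test), test$dm_status, sens_nc)
spec_ml <- cascade_spec("ML", ml, decision_threshold = as.numeric(thr_ml),
                        screening_lab = "NONE")

specs <- list(spec_ml, spec_nc)
for (lab in c("FPG", "P2HPG", "HBA1C")) {
  labcol <- switch(lab, FPG = "fpg", P2HPG = "p2hpg", HBA1C = "hba1c")
  cut <- switch(lab, FPG = thr_dx$fpg_dm, P2HPG = thr_dx$p2hpg_dm,
                HBA1C = thr_dx$hba1c_dm)
  m <- fit_risk_model(dev[dev[[labcol]] < cut, ], ml$learner,
                      c(ml$feature_list, labcol), seed = 104)
  norm <- test[[labcol]] < cut
  thr <- as.numeric(threshold_for_sensitivity(
    predict_risk(m, test[norm, ]), test$dm_status[norm], sens_nc))
  specs <- c(specs, list(
    cascade_spec(paste0("ML+", lab), m, decision_threshold = thr,
                 screening_lab = lab),
    cascade_spec(paste0("NCDRS+", lab), nc, screening_lab = lab)))
}

econ <- dplyr::bind_rows(lapply(specs, function(sp) {
  rec <- run_cascade(test, sp)
  s <- summarize_economics(rec, sched)
  cat(sprintf("%-12s confirmatory %5.1f%%  detection %6.2f CNY  FN %3d  compl(15y) %.2f-%.2f\n",
              sp$name, 100 * s$prop_confirmatory, s$avg_detection_cost,
              s$fn_count,
              s$complication_cost_range$low[s$complication_cost_range$horizon == 15],
              s$complication_cost_range$high[s$complication_cost_range$horizon == 15]))
  tibble::tibble(strategy = sp$name, threshold = sp$decision_threshold,
                 n = s$n, prop_confirmatory = s$prop_confirmatory,
                 avg_detection_cost = s$avg_detection_cost,
                 fn_count = s$fn_count,
                 horizon = s$complication_cost_range$horizon,
                 compl_low = s$complication_cost_range$low,
                 compl_high = s$complication_cost_range$high)
}))
readr::write_csv(econ, "results/strategy_economics.csv", progress = FALSE)
cat("wrote results/strategy_economics.csv\n")
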