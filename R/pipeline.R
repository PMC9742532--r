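# Seeded end-to-end run: generate -> split -> impute -> streamline ->
# cascades -> economics -> matched comparisons, with every output written
# as CSV/JSON under an output directory. Identical configuration and seeds
# give byte-identical CSVs.

#' Configuration of an end-to-end pipeline run
#'
#' @param out_dir Output directory (created if absent).
#' @param generator A [generator_config()]; its `n_participants`, `seed`
#'   and `missingness_rate` define the cohort.
#' @param dev_fraction Development-set fraction (default 0.6).
#' @param learner Learner of the trainable models.
#' @param ks Streamlining candidate feature counts.
#' @param schedule A [cost_schedule()].
#' @param score_table_path JSON path of the questionnaire score; defaults
#'   to the packaged placeholder NCDRS-schema table.
#' @param horizons Complication-cost horizons (years).
#' @param params Learner hyperparameter overrides.
#' @param with_lab_models Also build the lab-screen cascades (FPG / 2hPG /
#'   HbA1c) and their comparators.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       generator = generator_config(missingness_rate = 0.05),
                       dev_fraction = 0.6,
                       learner = "GRADIENT_BOOSTED_TREES",
                       ks = c(5, 10, 15, 20, 25),
                       schedule = cost_schedule(),
                       score_table_path = system.file(
                         "extdata", "ncdrs_placeholder.json", package = "dmscreen"),
                       horizons = c(5, 10, 15, 20, 25),
                       params = list(),
                       with_lab_models = TRUE) {
  structure(list(out_dir = out_dir, generator = generator,
                 dev_fraction = dev_fraction, learner = learner, ks = ks,
                 schedule = schedule, score_table_path = score_table_path,
                 horizons = horizons, params = params,
                 with_lab_models = with_lab_models),
            class = "run_config")
}

model_feature_columns <- function(pop) {
  setdiff(names(pop)[vapply(pop, is.numeric, TRUE)],
          c("id", "fpg", "p2hpg", "hba1c"))
}

econ_rows <- function(summary, threshold) {
  tibble::tibble(
    strategy = summary$strategy,
    decision_threshold = threshold,
    n = summary$n,
    prop_confirmatory = summary$prop_confirmatory,
    avg_detection_cost = summary$avg_detection_cost,
    fn_count = summary$fn_count,
    horizon = summary$complication_cost_range$horizon,
    compl_low = summary$complication_cost_range$low,
    compl_high = summary$complication_cost_range$high)
}

#' Run the full screening-evaluation pipeline
#'
#' Generates a cohort, splits it 60/40, imputes missing features on the
#' development set, streamlines a trainable model to its top-k features,
#' builds the risk-model and questionnaire-score strategies (plus the
#' lab-screen variants when requested), evaluates each strategy's
#' economics on the testing set at the questionnaire's published-cutoff
#' sensitivity, and compares strategies at matched sensitivity and matched
#' detection cost.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects, summaries, and the
#'   paths of everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  if (file.exists(logf)) unlink(logf)
  gen <- config$generator
  log_event("INFO", "start", sprintf("seed=%d n=%d learner=%s",
                                     gen$seed, gen$n_participants,
                                     config$learner), logf)

  log_event("INFO", "generate", "sampling synthetic cohort", logf)
  pop <- sample_population(gen)
  pop <- inject_missingness(pop, gen$missingness_rate, seed = gen$seed + 1L)

  log_event("INFO", "split", sprintf("dev fraction %.2f", config$dev_fraction), logf)
  sp <- split_dev_test(pop, config$dev_fraction, seed = gen$seed + 2L)

  log_event("INFO", "impute", "development-trained imputation", logf)
  imp <- withCallingHandlers(
    impute_population(sp$dev, sp$test),
    warning = function(w) {
      log_event("WARNING", "impute", conditionMessage(w), logf)
      invokeRestart("muffleWarning")
    })
  dev <- imp$dev; test <- imp$test

  features <- model_feature_columns(dev)
  log_event("INFO", "streamline",
            sprintf("%d candidate features, ks %s", length(features),
                    paste(config$ks, collapse = ",")), logf)
  sl <- streamline(dev, config$learner, features, ks = config$ks,
                   seed = gen$seed + 3L, params = config$params)
  full_cv <- cross_validate(dev, config$learner, features,
                            seed = gen$seed + 3L, params = config$params)
  model_table <- dplyr::bind_rows(
    sl$table,
    tibble::tibble(k = length(features), auc = full_cv$auc, aupr = full_cv$aupr))

  nc <- read_score_table(config$score_table_path)
  log_event("INFO", "cascade", "building screening strategies", logf)

  # questionnaire at its published cutoff anchors the matched sensitivity
  spec_nc <- cascade_spec(paste0(nc$name), nc, screening_lab = "NONE")
  rec_nc <- run_cascade(test, spec_nc)
  sens_nc <- confusion_metrics(tally(rec_nc))$sensitivity

  ml_scores <- predict_risk(sl$model, test)
  thr_ml <- threshold_for_sensitivity(ml_scores, test$dm_status, sens_nc)
  spec_ml <- cascade_spec("ML", sl$model, decision_threshold = as.numeric(thr_ml),
                          screening_lab = "NONE")

  specs <- list(spec_ml, spec_nc)
  models <- list(ml = sl$model)
  if (config$with_lab_models) {
    for (lab in c("FPG", "P2HPG", "HBA1C")) {
      labcol <- lab_column(lab)
      thr_dx <- diagnostic_thresholds()
      cut <- switch(lab, FPG = thr_dx$fpg_dm, P2HPG = thr_dx$p2hpg_dm,
                    HBA1C = thr_dx$hba1c_dm)
      dev_norm <- dev[dev[[labcol]] < cut, , drop = FALSE]
      m <- fit_risk_model(dev_norm, config$learner,
                          c(sl$model$feature_list, labcol),
                          seed = gen$seed + 4L, params = config$params)
      models[[paste0("ml_", tolower(lab))]] <- m
      test_norm_scores <- predict_risk(m, test[test[[labcol]] < cut, , drop = FALSE])
      truth_norm <- test$dm_status[test[[labcol]] < cut]
      thr <- if (length(unique(truth_norm)) == 2) {
        as.numeric(threshold_for_sensitivity(test_norm_scores, truth_norm, sens_nc))
      } else stats::median(test_norm_scores)
      specs <- c(specs, list(
        cascade_spec(paste0("ML+", lab), m, decision_threshold = thr,
                     screening_lab = lab),
        cascade_spec(paste0(nc$name, "+", lab), nc, screening_lab = lab)))
    }
  }

  log_event("INFO", "economics", "per-strategy summaries", logf)
  econ <- dplyr::bind_rows(lapply(specs, function(sp_i) {
    rec <- run_cascade(test, sp_i)
    econ_rows(summarize_economics(rec, config$schedule, config$horizons),
              sp_i$decision_threshold)
  }))

  log_event("INFO", "compare", "matched-sensitivity and matched-cost comparison", logf)
  cmp_sens <- compare_at_matched(test, spec_nc, spec_ml, config$schedule,
                                 match = "SENSITIVITY")
  cmp_cost <- compare_at_matched(test, spec_nc, spec_ml, config$schedule,
                                 match = "DETECTION_COST")

  log_event("INFO", "report", "writing outputs", logf)
  paths <- list(
    population = file.path(config$out_dir, "population.csv"),
    table1 = file.path(config$out_dir, "descriptive_summary.csv"),
    models = file.path(config$out_dir, "model_selection.csv"),
    economics = file.path(config$out_dir, "strategy_economics.csv"),
    matched_sens = file.path(config$out_dir, "matched_sensitivity.csv"),
    matched_cost = file.path(config$out_dir, "matched_cost.csv"),
    curve_ml = file.path(config$out_dir, "curve_ml.csv"),
    curve_score = file.path(config$out_dir, "curve_score.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_population(pop, paths$population)
  readr::write_csv(descriptive_table(
    dplyr::select(test, -dplyr::any_of("subtype"))), paths$table1, progress = FALSE)
  readr::write_csv(model_table, paths$models, progress = FALSE)
  readr::write_csv(econ, paths$economics, progress = FALSE)
  readr::write_csv(cmp_sens$table, paths$matched_sens, progress = FALSE)
  readr::write_csv(cmp_cost$table, paths$matched_cost, progress = FALSE)
  readr::write_csv(cmp_sens$curves$b, paths$curve_ml, progress = FALSE)
  readr::write_csv(cmp_sens$curves$a, paths$curve_score, progress = FALSE)

  cfg_json <- jsonlite::serializeJSON(unclass(config$generator))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dmscreen")),
    seed = gen$seed,
    n_participants = gen$n_participants,
    dev_fraction = config$dev_fraction,
    learner = config$learner,
    chosen_k = sl$chosen_k,
    matched_sensitivity = sens_nc,
    generator_config_sha = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(as.character(cfg_json), f); f }))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_event("INFO", "done", "pipeline complete", logf)

  invisible(list(config = config, population = pop, dev = dev, test = test,
                 streamline = sl, model_table = model_table, specs = specs,
                 models = models, economics = econ,
                 comparison_sensitivity = cmp_sens,
                 comparison_cost = cmp_cost, paths = paths))
}
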