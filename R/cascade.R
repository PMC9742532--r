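# Diagnostic rules and the four screening-to-confirmation cascades.

#' Diagnostic thresholds for diabetes
#'
#' Diabetes is diagnosed when fasting plasma glucose (FPG) is at or above
#' `fpg_dm` or the 2-hour post-load glucose (2hPG) is at or above `p2hpg_dm`.
#' Values strictly below a threshold are "seemingly normal" for that analyte;
#' one threshold per analyte governs both the diagnostic and the
#' seemingly-normal role. HbA1c is never diagnostic here, but an HbA1c
#' screening step treats values at or above `hba1c_dm` as positive.
#'
#' @param fpg_dm Diagnostic FPG threshold, mmol/L.
#' @param p2hpg_dm Diagnostic 2hPG threshold, mmol/L.
#' @param hba1c_dm HbA1c screening threshold, percent.
#' @return An object of class `diagnostic_thresholds`.
#' @export
diagnostic_thresholds <- function(fpg_dm = 7.0, p2hpg_dm = 11.1, hba1c_dm = 6.5) {
  stopifnot(is.numeric(fpg_dm), is.numeric(p2hpg_dm), is.numeric(hba1c_dm))
  if (fpg_dm <= 0 || p2hpg_dm <= 0 || hba1c_dm <= 0) {
    stop("diagnostic thresholds must be positive", call. = FALSE)
  }
  structure(
    list(fpg_dm = fpg_dm, p2hpg_dm = p2hpg_dm, hba1c_dm = hba1c_dm),
    class = "diagnostic_thresholds"
  )
}

check_glucose <- function(fpg, p2hpg) {
  if (any(!is.finite(fpg)) || any(!is.finite(p2hpg))) {
    stop("glucose values must be finite", call. = FALSE)
  }
  if (any(fpg <= 0) || any(p2hpg <= 0)) {
    stop("glucose values must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Diagnose diabetes from an OGTT pair
#'
#' @param fpg Fasting plasma glucose, mmol/L (vectorised).
#' @param p2hpg 2-hour post-load plasma glucose, mmol/L (vectorised).
#' @param thresholds A [diagnostic_thresholds()] object.
#' @return Logical vector: `TRUE` where `fpg >= fpg_dm` or `p2hpg >= p2hpg_dm`.
#' @export
diagnose <- function(fpg, p2hpg, thresholds = diagnostic_thresholds()) {
  check_glucose(fpg, p2hpg)
  fpg >= thresholds$fpg_dm | p2hpg >= thresholds$p2hpg_dm
}

#' Glycemic subtype of a diagnosed (or undiagnosed) person
#'
#' Partitions the FPG x 2hPG plane into `NON_DM`, `ISOLATED_FASTING`
#' (diagnostic FPG only), `ISOLATED_POSTLOAD` (diagnostic 2hPG only, the
#' group missed by fasting-glucose-only screening) and `COMBINED`.
#'
#' @inheritParams diagnose
#' @return Factor with levels NON_DM, ISOLATED_FASTING, ISOLATED_POSTLOAD,
#'   COMBINED.
#' @export
dm_subtype <- function(fpg, p2hpg, thresholds = diagnostic_thresholds()) {
  check_glucose(fpg, p2hpg)
  hi_f <- fpg >= thresholds$fpg_dm
  hi_p <- p2hpg >= thresholds$p2hpg_dm
  out <- rep("NON_DM", length(fpg))
  out[hi_f & !hi_p] <- "ISOLATED_FASTING"
  out[!hi_f & hi_p] <- "ISOLATED_POSTLOAD"
  out[hi_f & hi_p] <- "COMBINED"
  factor(out, levels = subtype_levels())
}

subtype_levels <- function() {
  c("NON_DM", "ISOLATED_FASTING", "ISOLATED_POSTLOAD", "COMBINED")
}

#' Specify a screening cascade
#'
#' A cascade is one of four detection procedures:
#' * `screening_lab = "NONE"`: risk model on everyone; positives get a full
#'   OGTT as confirmatory test.
#' * `"FPG"`: everyone has an FPG test; diagnostic results end the trail
#'   (detected). Among seemingly-normal persons the risk model selects who
#'   receives the 2hPG confirmatory test (target: isolated post-load DM).
#' * `"P2HPG"`: symmetric, confirming with FPG (target: isolated fasting DM).
#' * `"HBA1C"`: HbA1c screen; at-or-above-threshold values count as detected,
#'   model-positives among the rest get a full OGTT.
#'
#' The confirmatory test never repeats the already-measured analyte.
#'
#' @param name Strategy label used in reports.
#' @param risk_model A fitted [fit_risk_model()] object or a [score_table()].
#' @param decision_threshold Screen-positive when the model risk (or table
#'   score) is at or above this value. Defaults to the table's cutoff for
#'   score tables; must be given for probabilistic models.
#' @param screening_lab One of "NONE", "FPG", "P2HPG", "HBA1C".
#' @return Object of class `cascade_spec`.
#' @export
cascade_spec <- function(name, risk_model, decision_threshold = NULL,
                         screening_lab = c("NONE", "FPG", "P2HPG", "HBA1C")) {
  screening_lab <- match.arg(screening_lab)
  if (is.null(decision_threshold)) {
    if (inherits(risk_model, "score_table")) {
      decision_threshold <- risk_model$cutoff
    } else {
      stop("decision_threshold is required for probabilistic risk models",
           call. = FALSE)
    }
  }
  confirmatory <- switch(screening_lab,
    NONE = "OGTT", FPG = "P2HPG", P2HPG = "FPG", HBA1C = "OGTT")
  target <- switch(screening_lab,
    NONE = "ANY_DM", FPG = "ISOLATED_POSTLOAD", P2HPG = "ISOLATED_FASTING",
    HBA1C = "ANY_DM")
  structure(
    list(name = name, screening_lab = screening_lab, risk_model = risk_model,
         decision_threshold = decision_threshold,
         confirmatory_test = confirmatory, target_condition = target),
    class = "cascade_spec"
  )
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("<cascade_spec> ", x$name, "\n", sep = "")
  cat("  screening lab:    ", x$screening_lab, "\n", sep = "")
  cat("  confirmatory test:", x$confirmatory_test, "\n")
  cat("  target condition: ", x$target_condition, "\n", sep = "")
  cat("  decision threshold:", format(x$decision_threshold), "\n")
  invisible(x)
}

# Scores from either a fitted risk model or a points table, on the rows
# given. Returns a numeric vector aligned with `pop` rows.
screen_scores <- function(risk_model, pop) {
  if (inherits(risk_model, "score_table")) {
    apply_score_table(risk_model, pop)$score
  } else if (inherits(risk_model, "risk_model")) {
    predict_risk(risk_model, pop)
  } else {
    stop("risk_model must be a 'risk_model' or 'score_table'", call. = FALSE)
  }
}

lab_column <- function(screening_lab) {
  switch(screening_lab, FPG = "fpg", P2HPG = "p2hpg", HBA1C = "hba1c",
         NONE = NULL)
}

#' Run a screening cascade over a population
#'
#' Walks every person through the cascade: (a) the screening lab test, if
#' any, ends the trail when its result is in the diagnostic range; (b)
#' otherwise the risk model decides screen positivity; (c) screen-positives
#' receive the confirmatory test and are detected when any observed analyte
#' is diagnostic. `truth` is the person's true diabetes status; persons
#' diagnosed by the screening lab itself count as detected true positives of
#' the whole strategy.
#'
#' @param pop A population table (see [sample_population()]); needs the lab
#'   columns the cascade uses and the model's features.
#' @param spec A [cascade_spec()].
#' @param thresholds A [diagnostic_thresholds()] object.
#' @return A tibble of detection records: `id`, `tests` (semicolon-joined
#'   trail), `screen_positive`, `lab_detected`, `confirmatory_done`,
#'   `detected`, `truth`, `outcome` (TP/FP/TN/FN).
#' @export
run_cascade <- function(pop, spec, thresholds = diagnostic_thresholds()) {
  stopifnot(inherits(spec, "cascade_spec"))
  n <- nrow(pop)
  if (n == 0L) stop("population is empty", call. = FALSE)
  lab <- spec$screening_lab
  labcol <- lab_column(lab)
  if (!is.null(labcol) && !labcol %in% names(pop)) {
    stop("population lacks required lab column '", labcol, "'", call. = FALSE)
  }
  if (!all(c("fpg", "p2hpg") %in% names(pop))) {
    stop("population lacks true lab columns fpg/p2hpg needed to adjudicate detection",
         call. = FALSE)
  }

  lab_detected <- switch(lab,
    NONE  = rep(FALSE, n),
    FPG   = pop$fpg >= thresholds$fpg_dm,
    P2HPG = pop$p2hpg >= thresholds$p2hpg_dm,
    HBA1C = pop$hba1c >= thresholds$hba1c_dm
  )

  # risk model is applied only to persons not already diagnosed by the screen
  scores <- rep(NA_real_, n)
  idx <- which(!lab_detected)
  if (length(idx) > 0L) {
    scores[idx] <- screen_scores(spec$risk_model, pop[idx, , drop = FALSE])
  }
  screen_positive <- !lab_detected & !is.na(scores) &
    scores >= spec$decision_threshold
  confirmatory_done <- screen_positive

  detected_by_confirm <- switch(lab,
    NONE  = confirmatory_done & diagnose(pop$fpg, pop$p2hpg, thresholds),
    FPG   = confirmatory_done & pop$p2hpg >= thresholds$p2hpg_dm,
    P2HPG = confirmatory_done & pop$fpg >= thresholds$fpg_dm,
    HBA1C = confirmatory_done & diagnose(pop$fpg, pop$p2hpg, thresholds)
  )
  detected <- lab_detected | detected_by_confirm

  screen_test <- switch(lab, NONE = NULL, FPG = "FPG", P2HPG = "P2HPG",
                        HBA1C = "HBA1C")
  trail <- character(n)
  if (!is.null(screen_test)) trail[] <- screen_test
  conf <- spec$confirmatory_test
  trail[confirmatory_done] <- if (is.null(screen_test)) conf else
    paste(screen_test, conf, sep = ";")

  # confusion outcomes are prediction-vs-truth: a flagged person (screen-lab
  # diagnostic or model-positive) is a positive call; flagged diabetics are
  # always confirmed by the trail (the confirmatory test measures the
  # analyte(s) that define their diabetes), so FN = unflagged diabetics =
  # undetected diabetics, while flagged non-diabetics are FPs who incur the
  # confirmatory-test cost without a diagnosis
  flagged <- lab_detected | screen_positive
  truth <- as.logical(pop$dm_status)
  outcome <- ifelse(flagged & truth, "TP",
             ifelse(flagged & !truth, "FP",
             ifelse(!flagged & truth, "FN", "TN")))

  tibble::tibble(
    id = pop$id,
    tests = trail,
    screen_positive = screen_positive,
    lab_detected = lab_detected,
    confirmatory_done = confirmatory_done,
    flagged = flagged,
    detected = detected,
    truth = truth,
    outcome = factor(outcome, levels = c("TP", "FP", "TN", "FN")),
    strategy = spec$name
  )
}

#' Confusion counts from detection records
#'
#' @param records Detection records from [run_cascade()].
#' @return Object of class `confusion_counts` with fields TP, FP, TN, FN, N.
#' @export
tally <- function(records) {
  if (nrow(records) == 0L) stop("no detection records to tally", call. = FALSE)
  tab <- table(records$outcome)
  out <- list(TP = as.integer(tab[["TP"]]), FP = as.integer(tab[["FP"]]),
              TN = as.integer(tab[["TN"]]), FN = as.integer(tab[["FN"]]))
  out$N <- out$TP + out$FP + out$TN + out$FN
  stopifnot(out$N == nrow(records))
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> N=%d  TP=%d FP=%d TN=%d FN=%d\n",
              x$N, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
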