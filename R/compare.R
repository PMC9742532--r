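# Threshold sweeps of a cascade's economics and matched-sensitivity /
# matched-cost comparison of two screening strategies.

#' Sweep a cascade's decision threshold
#'
#' Computes the whole-cascade operating point and economics at every
#' observed score cutpoint (plus an "flag nobody" point above the maximum).
#' The screening-lab result and the confirmatory-test outcome are fixed per
#' person, so the sweep only re-thresholds the model scores; equivalence
#' with a full [run_cascade()] per threshold is exercised in the test
#' suite.
#'
#' @param pop Testing-set population table.
#' @param spec A [cascade_spec()]; its `decision_threshold` is ignored.
#' @param schedule A [cost_schedule()].
#' @param horizons Complication-cost horizons (years) to tabulate.
#' @param thresholds Optional explicit threshold grid (default: all
#'   observed distinct scores).
#' @param thresholds_dx [diagnostic_thresholds()].
#' @return Tibble, one row per threshold (descending): operating point,
#'   `prop_confirmatory`, `avg_detection_cost`, `fn_count` and
#'   `compl_low_<h>` / `compl_high_<h>` per horizon.
#' @export
cascade_curve <- function(pop, spec, schedule = cost_schedule(),
                          horizons = 15, thresholds = NULL,
                          thresholds_dx = diagnostic_thresholds()) {
  n <- nrow(pop)
  lab <- spec$screening_lab
  lab_detected <- switch(lab,
    NONE  = rep(FALSE, n),
    FPG   = pop$fpg >= thresholds_dx$fpg_dm,
    P2HPG = pop$p2hpg >= thresholds_dx$p2hpg_dm,
    HBA1C = pop$hba1c >= thresholds_dx$hba1c_dm)
  scores <- rep(NA_real_, n)
  idx <- which(!lab_detected)
  scores[idx] <- screen_scores(spec$risk_model, pop[idx, , drop = FALSE])
  truth <- as.logical(pop$dm_status)

  screen_cost <- if (lab == "NONE") 0 else unit_cost(schedule, lab)
  conf_cost <- unit_cost(schedule, spec$confirmatory_test)
  n_pos_total <- sum(truth); n_neg_total <- n - n_pos_total
  base_tp <- sum(lab_detected & truth)
  base_fp <- sum(lab_detected & !truth)

  # screen-lab results are threshold-free, so the sweep reduces to a
  # cumulative count over model scores sorted descending
  s <- scores[idx]; y <- truth[idx]
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  if (is.null(thresholds)) {
    last <- if (length(s)) cumsum(rle(s)$lengths) else integer(0)
    thr <- c(if (length(s)) s[1] + 1 else Inf, s[last])
    n_positive <- c(0L, last)
    tp_model <- c(0, cumsum(y)[last])
  } else {
    thr <- sort(unique(thresholds), decreasing = TRUE)
    n_positive <- vapply(thr, function(t) sum(s >= t), 0L)
    tp_model <- vapply(thr, function(t) sum(y & s >= t), 0)
  }
  tp <- base_tp + tp_model
  fp <- base_fp + (n_positive - tp_model)
  fn <- n_pos_total - tp
  out <- tibble::tibble(
    threshold = thr,
    n_positive = as.integer(n_positive),
    sensitivity = tp / n_pos_total,
    specificity = 1 - fp / n_neg_total,
    prop_confirmatory = n_positive / n,
    avg_detection_cost = screen_cost + n_positive * conf_cost / n,
    fn_count = as.integer(fn))
  for (h in horizons) {
    b <- schedule$complication_per_dm_year[[as.character(h)]]
    if (is.null(b)) stop("unknown horizon ", h, call. = FALSE)
    out[[paste0("compl_low_", h)]] <- fn * b[1] / n
    out[[paste0("compl_high_", h)]] <- fn * b[2] / n
  }
  out
}

pick_at_sensitivity <- function(curve, v) {
  ok <- which(curve$sensitivity >= v)
  if (length(ok) == 0L) {
    stop(sprintf("target sensitivity %.3f unattainable; attainable [%.3f, %.3f]",
                 v, min(curve$sensitivity), max(curve$sensitivity)),
         call. = FALSE)
  }
  curve[ok[1], ]   # thresholds descend: first hit = fewest positives
}

pick_at_cost <- function(curve, v) {
  ok <- which(curve$avg_detection_cost <= v)
  if (length(ok) == 0L) {
    stop(sprintf("target cost %.2f unattainable; attainable [%.2f, %.2f]",
                 v, min(curve$avg_detection_cost), max(curve$avg_detection_cost)),
         call. = FALSE)
  }
  curve[ok[which.max(curve$sensitivity[ok])], ]
}

#' Compare two screening strategies at matched sensitivity or cost
#'
#' Sweeps both strategies' decision thresholds over all observed score
#' cutpoints and reports, at each matched sensitivity (or matched average
#' detection cost), both strategies' operating points and economics plus
#' the relative reduction `(a - b) / a` of strategy B relative to the
#' reference A. When both strategies share the same screening lab, the
#' paired DeLong test compares their model AUCs on the screen-normal
#' stratum.
#'
#' @param pop Testing-set population table.
#' @param spec_a Reference strategy ([cascade_spec()]).
#' @param spec_b Evaluated strategy.
#' @param schedule A [cost_schedule()].
#' @param match `"SENSITIVITY"` or `"DETECTION_COST"`.
#' @param values Matched values; default a 21-point grid over the common
#'   attainable range.
#' @param horizon Complication-cost horizon (years) in the table.
#' @param thresholds_dx [diagnostic_thresholds()].
#' @return Object of class `strategy_comparison`: `table` (one row per
#'   matched value), `delong`, `curves`, `match`.
#' @export
compare_at_matched <- function(pop, spec_a, spec_b,
                               schedule = cost_schedule(),
                               match = c("SENSITIVITY", "DETECTION_COST"),
                               values = NULL, horizon = 15,
                               thresholds_dx = diagnostic_thresholds()) {
  match <- match.arg(match)
  ca <- cascade_curve(pop, spec_a, schedule, horizon, thresholds_dx = thresholds_dx)
  cb <- cascade_curve(pop, spec_b, schedule, horizon, thresholds_dx = thresholds_dx)

  if (is.null(values)) {
    if (match == "SENSITIVITY") {
      lo <- max(min(ca$sensitivity), min(cb$sensitivity), 0.05)
      hi <- min(max(ca$sensitivity), max(cb$sensitivity), 0.95)
    } else {
      lo <- max(min(ca$avg_detection_cost), min(cb$avg_detection_cost))
      hi <- min(max(ca$avg_detection_cost), max(cb$avg_detection_cost))
    }
    values <- seq(lo, hi, length.out = 21)
  }

  cl <- paste0("compl_low_", horizon); ch <- paste0("compl_high_", horizon)
  rows <- lapply(values, function(v) {
    a <- if (match == "SENSITIVITY") pick_at_sensitivity(ca, v) else pick_at_cost(ca, v)
    b <- if (match == "SENSITIVITY") pick_at_sensitivity(cb, v) else pick_at_cost(cb, v)
    tibble::tibble(
      matched_value = v,
      a_threshold = a$threshold, b_threshold = b$threshold,
      a_sensitivity = a$sensitivity, b_sensitivity = b$sensitivity,
      a_specificity = a$specificity, b_specificity = b$specificity,
      a_prop_confirmatory = a$prop_confirmatory,
      b_prop_confirmatory = b$prop_confirmatory,
      a_detection_cost = a$avg_detection_cost,
      b_detection_cost = b$avg_detection_cost,
      a_compl_low = a[[cl]], a_compl_high = a[[ch]],
      b_compl_low = b[[cl]], b_compl_high = b[[ch]],
      rr_prop_confirmatory = ifelse(a$prop_confirmatory > 0,
        (a$prop_confirmatory - b$prop_confirmatory) / a$prop_confirmatory, NA),
      rr_detection_cost = ifelse(a$avg_detection_cost > 0,
        (a$avg_detection_cost - b$avg_detection_cost) / a$avg_detection_cost, NA),
      rr_compl_low = ifelse(a[[cl]] > 0, (a[[cl]] - b[[cl]]) / a[[cl]], NA),
      rr_compl_high = ifelse(a[[ch]] > 0, (a[[ch]] - b[[ch]]) / a[[ch]], NA),
      sensitivity_gain = b$sensitivity - a$sensitivity)
  })

  delong <- NULL
  if (spec_a$screening_lab == spec_b$screening_lab) {
    lab <- spec_a$screening_lab
    stratum <- switch(lab,
      NONE = rep(TRUE, nrow(pop)),
      FPG = pop$fpg < thresholds_dx$fpg_dm,
      P2HPG = pop$p2hpg < thresholds_dx$p2hpg_dm,
      HBA1C = pop$hba1c < thresholds_dx$hba1c_dm)
    sub <- pop[stratum, , drop = FALSE]
    truth <- as.logical(sub$dm_status)
    if (length(unique(truth)) == 2L) {
      sa <- screen_scores(spec_a$risk_model, sub)
      sb <- screen_scores(spec_b$risk_model, sub)
      delong <- delong_test(sa, sb, truth)
    }
  }

  structure(list(
    strategies = c(a = spec_a$name, b = spec_b$name),
    match = match, horizon = horizon,
    table = dplyr::bind_rows(rows),
    delong = delong,
    curves = list(a = ca, b = cb)
  ), class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison> ", x$strategies[["a"]], " (reference) vs ",
      x$strategies[["b"]], "\n", sep = "")
  cat("  matched on:", x$match, "at", nrow(x$table), "values\n")
  if (!is.null(x$delong)) {
    cat(sprintf("  DeLong: AUC %.3f vs %.3f, p = %.4g\n",
                x$delong$auc_a, x$delong$auc_b, x$delong$p))
  }
  md <- stats::median(x$table$rr_detection_cost, na.rm = TRUE)
  cat(sprintf("  median relative detection-cost reduction: %.1f%%\n", 100 * md))
  invisible(x)
}
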