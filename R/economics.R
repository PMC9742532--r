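# Health-economic evaluation of a screening strategy: proportion of
# participants requiring a confirmatory test, average detection cost per
# participant (medical + non-medical cost of every performed test), and
# the potential complication cost attributable to missed (false-negative)
# diabetics over 5-25 year horizons.

#' Cost schedule for screening and confirmatory tests
#'
#' Defaults are published Chinese prices (CNY): medical costs 9.89 (FPG),
#' 23.56 (2hPG), 33.45 (OGTT), 84.16 (HbA1c); non-medical (transport etc.)
#' 8.3, 27.5, 27.5, 8.3. Potential complication costs per diabetic per
#' year range from 341-567 CNY over 5 years up to 5258-9132 CNY over 25
#' years.
#'
#' @param medical,nonmedical Named numeric maps test -> CNY; names FPG,
#'   P2HPG, OGTT, HBA1C.
#' @param complication_per_dm_year Named list horizon (years, character) ->
#'   `c(low, high)` CNY per diabetic per year.
#' @return Object of class `cost_schedule`.
#' @export
cost_schedule <- function(
    medical = c(FPG = 9.89, P2HPG = 23.56, OGTT = 33.45, HBA1C = 84.16),
    nonmedical = c(FPG = 8.3, P2HPG = 27.5, OGTT = 27.5, HBA1C = 8.3),
    complication_per_dm_year = list(
      `5` = c(341, 567), `10` = c(1302, 2555), `15` = c(2802, 5611),
      `20` = c(4428, 8212), `25` = c(5258, 9132))) {
  if (any(medical < 0) || any(nonmedical < 0)) {
    stop("test costs must be non-negative", call. = FALSE)
  }
  for (h in names(complication_per_dm_year)) {
    b <- complication_per_dm_year[[h]]
    if (length(b) != 2L || b[1] > b[2] || any(b < 0)) {
      stop("complication bounds for horizon ", h,
           " must be non-negative with low <= high", call. = FALSE)
    }
  }
  hz <- as.numeric(names(complication_per_dm_year))
  if (is.unsorted(hz)) stop("horizons must be ascending", call. = FALSE)
  lows <- vapply(complication_per_dm_year, `[`, 0, 1)
  his <- vapply(complication_per_dm_year, `[`, 0, 2)
  if (is.unsorted(lows) || is.unsorted(his)) {
    stop("complication bounds must be non-decreasing in horizon", call. = FALSE)
  }
  structure(list(medical = medical, nonmedical = nonmedical,
                 complication_per_dm_year = complication_per_dm_year),
            class = "cost_schedule")
}

unit_cost <- function(schedule, test) {
  if (!test %in% names(schedule$medical) ||
      !test %in% names(schedule$nonmedical)) {
    stop("test '", test, "' is not priced in the cost schedule", call. = FALSE)
  }
  schedule$medical[[test]] + schedule$nonmedical[[test]]
}

trail_tests <- function(records) strsplit(records$tests, ";", fixed = TRUE)

#' Proportion of participants requiring a confirmatory test
#'
#' @param records Detection records from [run_cascade()].
#' @return Proportion in `[0, 1]`.
#' @export
proportion_confirmatory <- function(records) {
  if (nrow(records) == 0L) stop("no detection records", call. = FALSE)
  mean(records$confirmatory_done)
}

#' Average detection cost per participant
#'
#' Sums the (medical + non-medical) price of every test in every person's
#' trail and divides by the number of participants.
#'
#' @param records Detection records from [run_cascade()].
#' @param schedule A [cost_schedule()].
#' @return CNY per participant.
#' @export
detection_cost <- function(records, schedule = cost_schedule()) {
  if (nrow(records) == 0L) stop("no detection records", call. = FALSE)
  tests <- unlist(trail_tests(records))
  tests <- tests[nzchar(tests)]
  if (length(tests) == 0L) return(0)
  counts <- table(tests)
  total <- sum(vapply(names(counts),
                      function(t) unit_cost(schedule, t) * counts[[t]], 0))
  total / nrow(records)
}

#' Potential complication cost of missed cases
#'
#' False negatives accrue the horizon's per-diabetic-per-year complication
#' cost bounds; the totals are divided by the number of participants. No
#' discounting is applied.
#'
#' @inheritParams detection_cost
#' @param horizon Horizon in years; must be a key of the schedule.
#' @return Named numeric `c(low, high)`, CNY per participant per year.
#' @export
complication_cost <- function(records, schedule = cost_schedule(),
                              horizon = 15) {
  if (nrow(records) == 0L) stop("no detection records", call. = FALSE)
  key <- as.character(horizon)
  if (!key %in% names(schedule$complication_per_dm_year)) {
    stop("unknown horizon ", horizon, "; available: ",
         paste(names(schedule$complication_per_dm_year), collapse = ", "),
         call. = FALSE)
  }
  fn <- sum(records$outcome == "FN")
  bounds <- schedule$complication_per_dm_year[[key]]
  c(low = fn * bounds[1] / nrow(records),
    high = fn * bounds[2] / nrow(records))
}

#' Economic summary of one cascade run
#'
#' @inheritParams detection_cost
#' @param horizons Horizons (years) to evaluate.
#' @return Object of class `economic_summary`: `n`, `prop_confirmatory`,
#'   `avg_detection_cost`, `complication_cost_range` (tibble), `fn_count`.
#' @export
summarize_economics <- function(records, schedule = cost_schedule(),
                                horizons = c(5, 10, 15, 20, 25)) {
  cc <- lapply(horizons, function(h) {
    b <- complication_cost(records, schedule, h)
    tibble::tibble(horizon = h, low = b[["low"]], high = b[["high"]])
  })
  structure(list(
    n = nrow(records),
    strategy = records$strategy[1],
    prop_confirmatory = proportion_confirmatory(records),
    avg_detection_cost = detection_cost(records, schedule),
    complication_cost_range = dplyr::bind_rows(cc),
    fn_count = sum(records$outcome == "FN")
  ), class = "economic_summary")
}

#' @export
print.economic_summary <- function(x, ...) {
  cat("<economic_summary> ", x$strategy %||% "", "  (n=", x$n, ")\n", sep = "")
  cat(sprintf("  proportion requiring confirmatory test: %.2f%%\n",
              100 * x$prop_confirmatory))
  cat(sprintf("  average detection cost: %.2f CNY/participant\n",
              x$avg_detection_cost))
  cat(sprintf("  missed cases (FN): %d\n", x$fn_count))
  for (i in seq_len(nrow(x$complication_cost_range))) {
    r <- x$complication_cost_range[i, ]
    cat(sprintf("  complication cost %dy: %.2f-%.2f CNY/participant/year\n",
                r$horizon, r$low, r$high))
  }
  invisible(x)
}

#' Relative reduction of a quantity between two strategies
#'
#' `(a - b) / a`, computed from unrounded values: the fraction by which
#' strategy B undercuts strategy A.
#'
#' @param a Reference value (comparator strategy).
#' @param b Value of the evaluated strategy.
#' @return Proportion (can be negative when B exceeds A).
#' @export
relative_reduction <- function(a, b) {
  if (any(a == 0)) stop("reference value is zero", call. = FALSE)
  (a - b) / a
}
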