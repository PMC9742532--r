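# Development-set-trained iterative imputation. Missing cells are
# initialised at the development-set median (or mode for integer-coded
# categoricals) and then refined by per-column linear regressions on the
# other features, repeated for a few sweeps. All models are fitted on the
# development set only and applied as-is to the testing set, so testing
# values never influence any imputation.

impute_protected_cols <- function() {
  c("id", "fpg", "p2hpg", "hba1c", "dm_status", "subtype")
}

col_mode <- function(x) {
  ux <- unique(x[!is.na(x)])
  ux[which.max(tabulate(match(x, ux)))]
}

#' Impute missing feature values without leakage
#'
#' Columns with 20% or more missing cells in the development set are
#' dropped from both tables with a warning (mirroring the exclusion rule
#' for heavily missing features). The remaining features are completed by
#' iterative regression imputation trained on the development set.
#'
#' @param dev Development-set population table.
#' @param test Testing-set population table (same columns). Optional.
#' @param max_iter Number of refinement sweeps (default 3).
#' @return List with completed `dev`, `test`, and `dropped` column names.
#' @export
impute_population <- function(dev, test = NULL, max_iter = 3L) {
  feat_cols <- setdiff(names(dev), impute_protected_cols())
  feat_cols <- feat_cols[vapply(dev[feat_cols], is.numeric, TRUE)]

  miss_frac <- vapply(dev[feat_cols], function(x) mean(is.na(x)), 0)
  dropped <- feat_cols[miss_frac >= 0.2]
  if (length(dropped) > 0) {
    warning("dropping features with 20%+ missing data: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    dev <- dev[setdiff(names(dev), dropped)]
    if (!is.null(test)) test <- test[setdiff(names(test), dropped)]
    feat_cols <- setdiff(feat_cols, dropped)
  }

  incomplete <- feat_cols[vapply(dev[feat_cols], anyNA, TRUE)]
  if (!is.null(test)) {
    incomplete <- union(incomplete,
                        feat_cols[vapply(test[feat_cols], anyNA, TRUE)])
  }
  if (length(incomplete) == 0L) {
    return(list(dev = dev, test = test, dropped = dropped))
  }

  categorical <- feat_cols[vapply(dev[feat_cols], function(x) {
    length(unique(stats::na.omit(x))) <= 5
  }, TRUE)]
  centers <- lapply(feat_cols, function(cl) {
    x <- dev[[cl]]
    if (cl %in% categorical) col_mode(x) else stats::median(x, na.rm = TRUE)
  })
  names(centers) <- feat_cols

  fill_center <- function(tab) {
    for (cl in feat_cols) {
      tab[[cl]][is.na(tab[[cl]])] <- centers[[cl]]
    }
    tab
  }
  dev_na <- lapply(dev[feat_cols], is.na)
  test_na <- if (!is.null(test)) lapply(test[feat_cols], is.na) else NULL
  dev_f <- fill_center(dev)
  test_f <- if (!is.null(test)) fill_center(test) else NULL

  # iterative refinement of continuous columns: regress each incomplete
  # column on the others, fitted on originally-observed dev rows, predicted
  # into masked cells; integer-coded categoricals keep the dev mode
  for (iter in seq_len(max_iter)) {
    for (cl in setdiff(incomplete, categorical)) {
      preds <- setdiff(feat_cols, cl)
      obs <- !dev_na[[cl]]
      if (sum(obs) < length(preds) + 2L) next
      fit <- stats::lm(stats::reformulate(preds, response = cl),
                       data = dev_f[obs, c(cl, preds)])
      if (any(dev_na[[cl]])) {
        dev_f[[cl]][dev_na[[cl]]] <-
          stats::predict(fit, dev_f[dev_na[[cl]], preds, drop = FALSE])
      }
      if (!is.null(test_f) && any(test_na[[cl]])) {
        test_f[[cl]][test_na[[cl]]] <-
          stats::predict(fit, test_f[test_na[[cl]], preds, drop = FALSE])
      }
    }
  }
  list(dev = dev_f, test = test_f, dropped = dropped)
}
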