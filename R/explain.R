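# Per-feature additive contributions on the log-odds scale, feature
# ranking, top-k streamlining, and conversion of contributions to relative
# risks. Tree models use xgboost's built-in per-prediction contributions;
# logistic regression decomposes exactly; other learners fall back to
# (label-free) permutation importance for ranking only.

#' Additive per-feature explanation of model output
#'
#' For gradient-boosted trees and logistic regression, returns per-row
#' feature contributions `phi` on the log-odds scale plus a shared base
#' value, with `base + rowSums(phi)` equal to the model's log-odds output
#' (to double precision for logistic regression; to the tree backend's
#' single precision, about 1e-5, for boosted trees).
#'
#' @param model A [fit_risk_model()] object (GRADIENT_BOOSTED_TREES or
#'   LOGISTIC).
#' @param data Rows to explain.
#' @return Object of class `risk_explanation`: `base` (scalar log-odds),
#'   `phi` (rows x features matrix), `logodds` (= base + rowSums(phi)).
#' @export
explain_risk <- function(model, data) {
  stopifnot(inherits(model, "risk_model"))
  if (nrow(data) == 0L) stop("no rows to explain", call. = FALSE)
  x <- as.matrix(data[model$feature_list])
  storage.mode(x) <- "double"
  if (model$learner == "GRADIENT_BOOSTED_TREES") {
    dm <- xgboost::xgb.DMatrix(x, nthread = 1)
    pc <- stats::predict(model$fitted_state$fit, dm, predcontrib = TRUE)
    nb <- ncol(pc)
    phi <- pc[, -nb, drop = FALSE]
    colnames(phi) <- model$feature_list
    base <- pc[1, nb]
  } else if (model$learner == "LOGISTIC") {
    xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
    beta <- stats::coef(model$fitted_state$fit)
    phi <- sweep(xs, 2, beta[-1], "*")   # features are centred on dev means
    colnames(phi) <- model$feature_list
    base <- unname(beta[1])
  } else {
    stop("additive explanations are available for GRADIENT_BOOSTED_TREES ",
         "and LOGISTIC models only", call. = FALSE)
  }
  structure(list(base = base, phi = phi, logodds = base + rowSums(phi)),
            class = "risk_explanation")
}

#' Rank features by mean absolute contribution
#'
#' Models with additive explanations are ranked by the mean absolute
#' per-feature contribution over `data`; other learners by permutation
#' reliance (mean absolute change in predicted risk when the feature is
#' permuted). Ties break lexicographically by feature name.
#'
#' @param model A fitted [fit_risk_model()].
#' @param data Rows over which importance is averaged.
#' @param seed Seed of the permutation fallback.
#' @return Tibble with `feature` and `importance`, descending.
#' @export
rank_features <- function(model, data, seed = 1L) {
  stopifnot(inherits(model, "risk_model"))
  if (nrow(data) == 0L) stop("no rows to rank features on", call. = FALSE)
  if (model$learner %in% c("GRADIENT_BOOSTED_TREES", "LOGISTIC")) {
    imp <- colMeans(abs(explain_risk(model, data)$phi))
  } else {
    base_pred <- predict_risk(model, data)
    imp <- withr::with_seed(seed, vapply(model$feature_list, function(f) {
      perm <- data
      perm[[f]] <- sample(perm[[f]])
      mean(abs(predict_risk(model, perm) - base_pred))
    }, 0))
  }
  ord <- order(-imp, names(imp))
  tibble::tibble(feature = names(imp)[ord], importance = unname(imp)[ord])
}

#' Streamline a model to its top-k features
#'
#' Fits a reference model on all candidate features, ranks them, then
#' cross-validates one model per `k` restricted to the top-k features. The
#' chosen model is the one with the fewest features whose cross-validated
#' AUC is within `tolerance` of the best over all `k`.
#'
#' @inheritParams fit_risk_model
#' @param ks Candidate feature counts, ascending (default 5,10,15,20,25).
#' @param tolerance AUC slack accepted for using fewer features
#'   (default 0.005).
#' @param k_cv Cross-validation folds.
#' @return List: `chosen_k`, `model` (refit on dev with top-k features),
#'   `table` (per-k AUC/auPR tibble), `ranking`.
#' @export
streamline <- function(dev, learner = "GRADIENT_BOOSTED_TREES", features,
                       ks = c(5, 10, 15, 20, 25), tolerance = 0.005,
                       seed = 1L, outcome = "dm_status", params = list(),
                       k_cv = 5L) {
  if (length(ks) == 0L) stop("ks must be non-empty", call. = FALSE)
  if (is.unsorted(ks)) stop("ks must be ascending", call. = FALSE)
  ks <- pmin(ks, length(features))
  full <- fit_risk_model(dev, learner, features, seed = seed,
                         outcome = outcome, params = params)
  ranking <- rank_features(full, dev, seed = seed)
  per_k <- lapply(unique(ks), function(k) {
    top <- ranking$feature[seq_len(k)]
    cv <- cross_validate(dev, learner, top, k = k_cv, seed = seed,
                         outcome = outcome, params = params)
    tibble::tibble(k = k, auc = cv$auc, aupr = cv$aupr)
  })
  tab <- dplyr::bind_rows(per_k)
  chosen_k <- tab$k[which(tab$auc >= max(tab$auc) - tolerance)[1]]
  top <- ranking$feature[seq_len(chosen_k)]
  model <- fit_risk_model(dev, learner, top, seed = seed, outcome = outcome,
                          params = params)
  list(chosen_k = chosen_k, model = model, table = tab, ranking = ranking)
}

#' Convert a feature's contribution to a relative risk
#'
#' RR of the feature's observed value is the risk implied by the base
#' log-odds plus the feature's contribution, over the base risk:
#' `plogis(base + phi_f) / plogis(base)`. RR exceeds 1 exactly when the
#' contribution is positive.
#'
#' @param expl A [explain_risk()] object.
#' @param feature Feature name.
#' @return Numeric vector of per-row relative risks.
#' @export
contributions_to_rr <- function(expl, feature) {
  stopifnot(inherits(expl, "risk_explanation"))
  if (!feature %in% colnames(expl$phi)) {
    stop("feature '", feature, "' not in explanation", call. = FALSE)
  }
  phi <- expl$phi[, feature]
  if (any(!is.finite(phi)) || !is.finite(expl$base)) {
    stop("non-finite contribution", call. = FALSE)
  }
  stats::plogis(expl$base + phi) / stats::plogis(expl$base)
}
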