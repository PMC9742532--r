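# Trainable probabilistic classifiers behind a single risk-model surface.
# Seven learner kinds mirror a typical tabular-clinical bake-off: logistic
# regression, SVM, random forest, k-nearest neighbours, centroid-displacement
# kNN, a single-hidden-layer neural net, and gradient-boosted trees (the
# default). Hyperparameters are fixed sensible defaults; all fits are
# seed-deterministic and single-threaded.

learner_kinds <- function() {
  c("LOGISTIC", "SVM", "RANDOM_FOREST", "KNN", "CENTROID_DISPLACEMENT_KNN",
    "NEURAL_NET", "GRADIENT_BOOSTED_TREES")
}

#' Fit a probabilistic risk model
#'
#' @param dev Development-set table containing `features` and the outcome.
#' @param learner One of `learner_kinds()`.
#' @param features Character vector of feature column names (numeric).
#' @param seed Integer seed; identical seeds give identical fits.
#' @param outcome Name of the logical/0-1 outcome column (default
#'   `dm_status`).
#' @param params Optional named list overriding learner defaults
#'   (e.g. `nrounds`, `k`, `size`, `num.trees`, `cost`).
#' @return Object of class `risk_model` with `feature_list`, `learner`,
#'   `base_rate` (training prevalence) and opaque `fitted_state`.
#' @export
fit_risk_model <- function(dev, learner = "GRADIENT_BOOSTED_TREES", features,
                           seed = 1L, outcome = "dm_status", params = list()) {
  learner <- match.arg(learner, learner_kinds())
  missing_feats <- setdiff(features, names(dev))
  if (length(missing_feats) > 0) {
    stop("features absent from data: ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  if (!outcome %in% names(dev)) stop("outcome column '", outcome, "' absent",
                                     call. = FALSE)
  x <- as.matrix(dev[features])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain missing values; impute first", call. = FALSE)
  y <- as.integer(as.logical(dev[[outcome]]))
  if (length(unique(y)) < 2L) {
    stop("development set contains a single outcome class", call. = FALSE)
  }

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  state <- withr::with_seed(seed, switch(learner,
    LOGISTIC = {
      df <- data.frame(xs, .y = y, check.names = FALSE)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., family = stats::binomial(), data = df))
      list(fit = fit)
    },
    SVM = {
      cost <- params$cost %||% 1
      fit <- e1071::svm(xs, factor(y, levels = 0:1), kernel = "radial",
                        cost = cost, probability = TRUE)
      list(fit = fit)
    },
    RANDOM_FOREST = {
      num.trees <- params$num.trees %||% 300
      fit <- ranger::ranger(x = xs, y = factor(y, levels = 0:1),
                            probability = TRUE, num.trees = num.trees,
                            seed = seed, num.threads = 1)
      list(fit = fit)
    },
    KNN = {
      k <- params$k %||% 25L
      list(train_x = xs, train_y = y, k = k)
    },
    CENTROID_DISPLACEMENT_KNN = {
      # displacement of the class centroid when the query point joins the
      # class: ||x - mu_c|| / (n_c + 1); classify toward the class whose
      # centroid moves least, Platt-scaled to a probability
      mu0 <- colMeans(xs[y == 0, , drop = FALSE])
      mu1 <- colMeans(xs[y == 1, , drop = FALSE])
      n0 <- sum(y == 0); n1 <- sum(y == 1)
      s <- cd_score(xs, mu0, mu1, n0, n1)
      platt <- suppressWarnings(
        stats::glm(y ~ s, family = stats::binomial(),
                   data = data.frame(s = s, y = y)))
      list(mu0 = mu0, mu1 = mu1, n0 = n0, n1 = n1, platt = platt)
    },
    NEURAL_NET = {
      size <- params$size %||% 8L
      decay <- params$decay %||% 0.01
      fit <- nnet::nnet(xs, y, size = size, decay = decay, maxit = 300,
                        entropy = TRUE, trace = FALSE)
      list(fit = fit)
    },
    GRADIENT_BOOSTED_TREES = {
      nrounds <- params$nrounds %||% 150
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta %||% 0.1,
                      max_depth = params$max_depth %||% 4,
                      min_child_weight = params$min_child_weight %||% 5,
                      subsample = 1, colsample_bytree = 1, nthread = 1),
        data = dtrain, nrounds = nrounds, verbose = 0)
      list(fit = fit)
    }
  ))

  structure(
    list(learner = learner, feature_list = features, fitted_state = state,
         base_rate = mean(y), center = center, scale = scale_, seed = seed),
    class = "risk_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cd_score <- function(xs, mu0, mu1, n0, n1) {
  d0 <- sqrt(rowSums(sweep(xs, 2, mu0)^2)) / (n0 + 1)
  d1 <- sqrt(rowSums(sweep(xs, 2, mu1)^2)) / (n1 + 1)
  d0 - d1    # larger when closer to (cheaper displacement of) the DM class
}

#' Predict diabetes risk
#'
#' @param model A [fit_risk_model()] object.
#' @param newdata Table containing the model's features.
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "risk_model"))
  x <- as.matrix(newdata[model$feature_list])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("newdata contains missing feature values", call. = FALSE)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  st <- model$fitted_state
  p <- switch(model$learner,
    LOGISTIC = {
      df <- data.frame(xs, check.names = FALSE)
      as.numeric(stats::predict(st$fit, newdata = df, type = "response"))
    },
    SVM = {
      pr <- stats::predict(st$fit, xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RANDOM_FOREST = {
      stats::predict(st$fit, data = xs, num.threads = 1)$predictions[, "1"]
    },
    KNN = {
      k <- min(st$k, nrow(st$train_x))
      pr <- withr::with_seed(model$seed,
        class::knn(st$train_x, xs, factor(st$train_y, levels = 0:1),
                   k = k, prob = TRUE))
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    CENTROID_DISPLACEMENT_KNN = {
      s <- cd_score(xs, st$mu0, st$mu1, st$n0, st$n1)
      as.numeric(stats::predict(st$platt, newdata = data.frame(s = s),
                                type = "response"))
    },
    NEURAL_NET = as.numeric(stats::predict(st$fit, xs)),
    GRADIENT_BOOSTED_TREES = {
      dm <- xgboost::xgb.DMatrix(x, nthread = 1)
      as.numeric(stats::predict(st$fit, dm))
    }
  )
  p <- as.numeric(p)
  pmin(pmax(p, 0), 1)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", x$learner, "\n", sep = "")
  cat(sprintf("  %d features, training prevalence %.4f\n",
              length(x$feature_list), x$base_rate))
  invisible(x)
}

#' K-fold cross-validation of a learner
#'
#' Rows are partitioned into `k` near-equal folds by a seeded random
#' shuffle; each fold is predicted once by a model trained on the others.
#' Pooled AUC and auPR are computed on the out-of-fold predictions, with
#' stratified bootstrap confidence intervals.
#'
#' @inheritParams fit_risk_model
#' @param k Number of folds (default 5).
#' @param ci_boot Bootstrap replicates for the pooled CIs (0 to skip).
#' @return List: `folds` (tibble of per-fold AUC/auPR and sizes), `auc`,
#'   `aupr`, `auc_ci`, `aupr_ci`, `oof` (out-of-fold predictions).
#' @export
cross_validate <- function(dev, learner = "GRADIENT_BOOSTED_TREES", features,
                           k = 5L, seed = 1L, outcome = "dm_status",
                           params = list(), ci_boot = 0L) {
  n <- nrow(dev)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of rows", call. = FALSE)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  y <- as.logical(dev[[outcome]])
  oof <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i
    m <- fit_risk_model(dev[tr, , drop = FALSE], learner, features,
                        seed = seed + i, outcome = outcome, params = params)
    oof[!tr] <- predict_risk(m, dev[!tr, , drop = FALSE])
    per_fold[[i]] <- tibble::tibble(
      fold = i, n = sum(!tr),
      auc = if (length(unique(y[!tr])) == 2) auc(oof[!tr], y[!tr]) else NA_real_,
      aupr = if (length(unique(y[!tr])) == 2) aupr(oof[!tr], y[!tr]) else NA_real_)
  }
  out <- list(folds = dplyr::bind_rows(per_fold),
              auc = auc(oof, y), aupr = aupr(oof, y), oof = oof)
  if (ci_boot >= 100) {
    out$auc_ci <- bootstrap_ci(oof, y, auc, B = ci_boot, seed = seed)
    out$aupr_ci <- bootstrap_ci(oof, y, aupr, B = ci_boot, seed = seed)
  }
  out
}
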