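# Classification metrics: confusion ratios, ROC and precision-recall
# curves, stratified bootstrap CIs, the DeLong paired-AUC test, and
# threshold selection at a target sensitivity.

check_scores_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  labels
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' Exact ratios TP/(TP+FN), TN/(FP+TN) and TP/(TP+FP). A zero denominator
#' yields `NA` with a warning rather than a silent zero.
#'
#' @param counts A [tally()] object (or list with TP, FP, TN, FN).
#' @return Named list `sensitivity`, `specificity`, `precision`.
#' @export
confusion_metrics <- function(counts) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(
    sensitivity = ratio(counts$TP, counts$TP + counts$FN, "sensitivity"),
    specificity = ratio(counts$TN, counts$FP + counts$TN, "specificity"),
    precision = ratio(counts$TP, counts$TP + counts$FP, "precision")
  )
}

#' Area under the ROC curve (Mann-Whitney form, ties count one half)
#'
#' @param scores Numeric risk scores, higher = more positive.
#' @param labels Logical (or 0/1) true outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step-wise summation)
#'
#' Scores are processed in descending order in blocks of tied values;
#' each block contributes its gained true positives times the precision
#' after the block. A constant classifier gets auPR equal to prevalence.
#'
#' @inheritParams auc
#' @return auPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(rle(s)$lengths)   # end index of each tied-score block
  tp <- cumsum(y)[last]
  prec <- tp / last
  d_tp <- diff(c(0, tp))
  sum(d_tp * prec) / sum(labels)
}

#' ROC curve table
#'
#' One row per distinct threshold, descending, with the operating point
#' obtained by flagging `score >= threshold`.
#'
#' @inheritParams auc
#' @return Tibble: `threshold`, `sensitivity`, `specificity`, `precision`,
#'   with the AUC as attribute `"auc"`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  last <- cumsum(rle(s)$lengths)
  thr <- s[last]
  tp <- cumsum(y)[last]; fp <- last - tp
  n_pos <- sum(labels); n_neg <- sum(!labels)
  out <- tibble::tibble(
    threshold = thr,
    sensitivity = tp / n_pos,
    specificity = 1 - fp / n_neg,
    precision = tp / (tp + fp)
  )
  attr(out, "auc") <- auc(scores, labels)
  out
}

#' Precision-recall curve table
#'
#' @inheritParams auc
#' @return Tibble: `threshold`, `recall`, `precision`, with the step-wise
#'   auPR as attribute `"aupr"`.
#' @export
pr_curve <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  out <- tibble::tibble(threshold = rc$threshold, recall = rc$sensitivity,
                        precision = rc$precision)
  attr(out, "aupr") <- aupr(scores, labels)
  out
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (so every resample keeps
#' both classes) and takes the 2.5/97.5 percentiles of the statistic.
#'
#' @inheritParams auc
#' @param statistic Function of `(scores, labels)` returning a scalar.
#' @param B Number of resamples (at least 100).
#' @param seed Integer seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, statistic = auc, B = 2000L,
                         seed = 1L) {
  labels <- check_scores_labels(scores, labels)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  ip <- which(labels);ineg <- which(!labels)
  stats_b <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    statistic(scores[idx], labels[idx])
  }, 0))
  unname(stats::quantile(stats_b, c(0.025, 0.975), type = 7))
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half); and symmetrically for each negative.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n            # per positive
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m    # per negative
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two score vectors over the same persons using the
#' placement-value covariance estimator; two-sided p from the normal
#' approximation. Identical (or rank-identical) scores give z = 0, p = 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @inheritParams auc
#' @return List `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have equal length", call. = FALSE)
  }
  labels <- check_scores_labels(scores_a, labels)
  check_scores_labels(scores_b, labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  sigma <- s10 / m + s01 / n
  var_diff <- sigma[1, 1] + sigma[2, 2] - 2 * sigma[1, 2]
  d <- pa$theta - pb$theta
  if (var_diff <= .Machine$double.eps || abs(d) < .Machine$double.eps) {
    z <- if (abs(d) < sqrt(.Machine$double.eps)) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = pa$theta, auc_b = pb$theta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Threshold attaining a target sensitivity
#'
#' Returns the largest threshold (hence fewest screen-positives, hence the
#' highest specificity) whose sensitivity is at or above the target.
#'
#' @inheritParams auc
#' @param target_sens Target sensitivity in (0, 1].
#' @return The threshold, with attributes `"sensitivity"` and
#'   `"specificity"` of the attained operating point.
#' @export
threshold_for_sensitivity <- function(scores, labels, target_sens) {
  labels <- check_scores_labels(scores, labels)
  if (target_sens <= 0 || target_sens > 1) {
    stop("target sensitivity must be in (0, 1]", call. = FALSE)
  }
  rc <- roc_curve(scores, labels)
  ok <- which(rc$sensitivity >= target_sens)
  row <- rc[ok[1], ]   # thresholds descend; first hit is the largest
  out <- row$threshold
  attr(out, "sensitivity") <- row$sensitivity
  attr(out, "specificity") <- row$specificity
  out
}
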