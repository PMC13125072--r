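#' Confusion-table metrics
#'
#' Computes the threshold-dependent metric suite from the four confusion
#' counts: true-positive rate (recall/sensitivity), false-positive rate,
#' precision, recall, F1 (harmonic mean of precision and recall), accuracy,
#' and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#'
#' Zero-denominator conventions: precision and recall are 0 when their
#' denominator is 0; MCC is 0 when any factor of its denominator is 0 (e.g.
#' an all-one-class prediction vector).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `tp_rate`,
#'   `fp_rate`, `precision`, `recall`, `f1`, `accuracy`, `mcc`.
#' @examples
#' confusion_metrics(tp = 50, fp = 10, tn = 30, fn = 10)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("confusion counts must be non-negative numbers")
  }
  n <- tp + fp + tn + fn
  if (n <= 0) abort("at least one instance is required")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tp_rate = recall,
    fp_rate = safe_div(fp, fp + tn),
    precision = precision,
    recall = recall,
    f1 = f1,
    accuracy = (tp + tn) / n,
    mcc = mcc
  )
}

check_binary_labels <- function(truth_pos) {
  if (!any(truth_pos)) abort("no positive-class instances in `truth`")
  if (all(truth_pos)) abort("no negative-class instances in `truth`")
  invisible(TRUE)
}

# Score sweep shared by the ROC and PR constructions. Descending unique
# thresholds; ties grouped so tied scores move the operating point once.
score_sweep <- function(truth_pos, score) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  truth_pos <- truth_pos[ord]
  last_of_tie <- c(diff(score) != 0, TRUE)
  tibble::tibble(
    threshold = score[last_of_tie],
    tp = cumsum(truth_pos)[last_of_tie],
    fp = cumsum(!truth_pos)[last_of_tie]
  )
}

#' ROC and precision-recall curves
#'
#' `roc_points()` sweeps the decision threshold over the observed scores
#' (descending, with tied scores grouped) and reports the true-positive rate
#' against the false-positive rate; `pr_points()` reports precision against
#' recall over the same sweep. `roc_auc()` integrates the ROC curve by the
#' trapezoidal rule; `pr_auc()` uses rightward step interpolation (precision
#' is held at its value when recall increases), the convention that avoids
#' the optimistic linear interpolation of precision.
#'
#' @param data A data frame of scored instances.
#' @param truth Column holding the true class.
#' @param score Column holding the numeric score (larger = more positive).
#' @param positive Value of `truth` treated as the positive class.
#' @return `roc_points()`: a tibble with `threshold`, `tpr`, `fpr` (anchored
#'   at the (0, 0) origin); `pr_points()`: a tibble with `threshold`,
#'   `recall`, `precision`. The `_auc` variants return a single number.
#' @examples
#' d <- tibble::tibble(truth = c("a", "a", "b", "b"), s = c(0.9, 0.6, 0.4, 0.1))
#' roc_auc(d, truth, s, positive = "a")
#' @export
roc_points <- function(data, truth, score, positive = "SARS-risk") {
  truth_pos <- dplyr::pull(data, {{ truth }}) == positive
  s <- dplyr::pull(data, {{ score }})
  check_binary_labels(truth_pos)
  sw <- score_sweep(truth_pos, s)
  tibble::tibble(
    threshold = c(Inf, sw$threshold),
    tpr = c(0, sw$tp / sum(truth_pos)),
    fpr = c(0, sw$fp / sum(!truth_pos))
  )
}

#' @rdname roc_points
#' @export
roc_auc <- function(data, truth, score, positive = "SARS-risk") {
  pts <- roc_points(data, {{ truth }}, {{ score }}, positive)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' @rdname roc_points
#' @export
pr_points <- function(data, truth, score, positive = "SARS-risk") {
  truth_pos <- dplyr::pull(data, {{ truth }}) == positive
  s <- dplyr::pull(data, {{ score }})
  check_binary_labels(truth_pos)
  sw <- score_sweep(truth_pos, s)
  tibble::tibble(
    threshold = sw$threshold,
    recall = sw$tp / sum(truth_pos),
    precision = sw$tp / (sw$tp + sw$fp)
  )
}

#' @rdname roc_points
#' @export
pr_auc <- function(data, truth, score, positive = "SARS-risk") {
  pts <- pr_points(data, {{ truth }}, {{ score }}, positive)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Youden-index threshold selection
#'
#' Returns the decision threshold maximizing Youden's J = TPR - FPR over the
#' realized score values (predict positive when `score >= threshold`). Ties
#' are broken toward the lowest such threshold, favouring sensitivity.
#'
#' @inheritParams roc_points
#' @return A single threshold on the score scale.
#' @export
youden_threshold <- function(data, truth, score, positive = "SARS-risk") {
  truth_pos <- dplyr::pull(data, {{ truth }}) == positive
  s <- dplyr::pull(data, {{ score }})
  check_binary_labels(truth_pos)
  sw <- score_sweep(truth_pos, s)
  j <- sw$tp / sum(truth_pos) - sw$fp / sum(!truth_pos)
  best <- which(j == max(j))
  min(sw$threshold[best])
}

#' McNemar's paired test on discordant predictions
#'
#' Compares two classifiers evaluated on the same test instances through the
#' two discordant cells of their paired confusion table: `b` instances that
#' only the first classifier got right, `c` that only the second got right.
#' For `b + c < 25` an exact two-sided binomial test is used; otherwise the
#' continuity-corrected chi-square statistic \eqn{(|b-c|-1)^2/(b+c)} on one
#' degree of freedom.
#'
#' @param b,c Non-negative discordant-pair counts.
#' @return A one-row tibble with `statistic`, `p_value`, `method`, `b`, `c`.
#' @examples
#' mcnemar_test(b = 10, c = 2)
#' @export
mcnemar_test <- function(b, c) {
  b <- check_count(b, "b", min = 0)
  c <- check_count(c, "c", min = 0)
  n <- b + c
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, method = "exact binomial",
                          b = b, c = c))
  }
  if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    tibble::tibble(statistic = as.numeric(min(b, c)), p_value = p,
                   method = "exact binomial", b = b, c = c)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    tibble::tibble(statistic = stat,
                   p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                   method = "chi-square with continuity correction",
                   b = b, c = c)
  }
}

#' Map risk probabilities to alert levels
#'
#' Maps a predicted risk probability to the three-level alert scheme used by
#' the monitoring agents: low risk below the lower boundary, high risk above
#' the upper boundary, moderate in between. Both boundaries map to moderate.
#'
#' @param p Vector of probabilities in \[0, 1\].
#' @param boundaries Increasing pair of interior cut points, default
#'   `c(0.3, 0.6)`.
#' @return An ordered factor with levels `low < moderate < high`.
#' @examples
#' alert_level(c(0.1, 0.45, 0.61))
#' @export
alert_level <- function(p, boundaries = c(0.3, 0.6)) {
  if (length(boundaries) != 2 || !all(is.finite(boundaries)) ||
      boundaries[1] >= boundaries[2] ||
      boundaries[1] <= 0 || boundaries[2] >= 1) {
    abort("`boundaries` must be strictly increasing within (0, 1)")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  lev <- ifelse(p < boundaries[1], "low",
                ifelse(p > boundaries[2], "high", "moderate"))
  factor(lev, levels = c("low", "moderate", "high"), ordered = TRUE)
}
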