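test_that("confusion metrics match hand arithmetic", {
  m <- confusion_metrics(tp = 50, fp = 10, tn = 30, fn = 10)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 60)
  expect_equal(m$f1, 50 / 60)  # harmonic mean of two equal rates
  expect_equal(m$mcc, 1400 / 2400)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$tp_rate, 50 / 60)
  expect_equal(m$fp_rate, 10 / 40)
})

test_that("confusion metric edge conventions", {
  perfect <- confusion_metrics(tp = 7, fp = 0, tn = 5, fn = 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  all_pos <- confusion_metrics(tp = 6, fp = 4, tn = 0, fn = 0)
  expect_equal(all_pos$mcc, 0)  # degenerate denominator convention
  none_pred <- confusion_metrics(tp = 0, fp = 0, tn = 4, fn = 6)
  expect_equal(none_pred$precision, 0)
  expect_equal(none_pred$f1, 0)
})

test_that("metric suite equals brute-force recomputation on random vectors", {
  set.seed(11)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    if (tp + fp + tn + fn == 0) next
    m <- confusion_metrics(tp, fp, tn, fn)
    # independent elementwise recomputation
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    expect_equal(m$f1, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(m$mcc, if (den > 0) (tp * tn - fp * fn) / den else 0)
  }
})

test_that("MCC is invariant under jointly swapping classes and predictions", {
  set.seed(3)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + tn + fn == 0) next
    expect_equal(confusion_metrics(tp, fp, tn, fn)$mcc,
                 confusion_metrics(tn, fn, tp, fp)$mcc)
  }
})

test_that("ROC endpoints: perfect and inverted rankings", {
  d <- tibble::tibble(truth = rep(c("pos", "neg"), each = 5),
                      s = c(6:10, 1:5) / 10)
  expect_equal(roc_auc(d, truth, s, positive = "pos"), 1.0)
  d$s <- rev(d$s)
  expect_equal(roc_auc(d, truth, s, positive = "pos"), 0.0)
})

test_that("ROC-AUC equals the tie-aware Mann-Whitney statistic", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(6:50, 1)
    d <- tibble::tibble(
      truth = sample(c("pos", "neg"), n, replace = TRUE),
      s = sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    )
    if (length(unique(d$truth)) < 2) next
    auc <- roc_auc(d, truth, s, positive = "pos")
    pos <- d$s[d$truth == "pos"]; neg <- d$s[d$truth == "neg"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("PR-AUC uses step interpolation and hits 1 for perfect ranking", {
  d <- tibble::tibble(truth = rep(c("pos", "neg"), each = 3),
                      s = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(pr_auc(d, truth, s, positive = "pos"), 1.0)
  # hand case: scores 0.9(pos) 0.8(neg) 0.7(pos): recall steps 1/2 then 1,
  # precision 1 then 2/3
  d2 <- tibble::tibble(truth = c("pos", "neg", "pos"), s = c(0.9, 0.8, 0.7))
  expect_equal(pr_auc(d2, truth, s, positive = "pos"),
               0.5 * 1 + 0.5 * (2 / 3))
})

test_that("one-class inputs are rejected by curve functions", {
  d <- tibble::tibble(truth = rep("pos", 4), s = runif(4))
  expect_error(roc_auc(d, truth, s, positive = "pos"), "negative")
  expect_error(youden_threshold(d, truth, s, positive = "pos"), "negative")
})

test_that("Youden threshold maximizes TPR - FPR, verified by exhaustive sweep", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    d <- tibble::tibble(truth = sample(c("pos", "neg"), n, replace = TRUE),
                        s = round(runif(n), 2))
    if (length(unique(d$truth)) < 2) next
    thr <- youden_threshold(d, truth, s, positive = "pos")
    j_at <- function(t) {
      pred <- d$s >= t
      tp <- sum(pred & d$truth == "pos"); fn <- sum(!pred & d$truth == "pos")
      fp <- sum(pred & d$truth == "neg"); tn <- sum(!pred & d$truth == "neg")
      tp / (tp + fn) - fp / (fp + tn)
    }
    best <- max(vapply(unique(d$s), j_at, numeric(1)))
    expect_equal(j_at(thr), best)
    # ties resolved toward the lowest qualifying threshold
    cands <- unique(d$s)[vapply(unique(d$s), j_at, numeric(1)) == best]
    expect_equal(thr, min(cands))
  }
})

test_that("Youden threshold separates perfectly separated scores", {
  d <- tibble::tibble(truth = rep(c("pos", "neg"), each = 4),
                      s = c(0.9, 0.8, 0.75, 0.7, 0.3, 0.2, 0.15, 0.1))
  thr <- youden_threshold(d, truth, s, positive = "pos")
  expect_equal(thr, 0.7)  # the lowest positive score
  # degenerate constant scores: J = 0 at the single candidate
  dc <- tibble::tibble(truth = c("pos", "neg"), s = c(0.5, 0.5))
  expect_equal(youden_threshold(dc, truth, s, positive = "pos"), 0.5)
})

test_that("McNemar: exact binomial for few discordant pairs, chi-square beyond", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(1, 0)$p_value, 1)  # two-sided exact, n = 1
  expect_equal(mcnemar_test(0, 0)$statistic, 0)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  big <- mcnemar_test(20, 10)
  expect_equal(big$statistic, (abs(20 - 10) - 1)^2 / 30)
  expect_equal(big$p_value, pchisq(big$statistic, 1, lower.tail = FALSE))
  # hand arithmetic case: b=10, c=2 has 12 discordant pairs -> exact;
  # its continuity-corrected chi-square value would be 49/12
  expect_equal((abs(10 - 2) - 1)^2 / 12, 49 / 12)
  ex <- mcnemar_test(10, 2)
  expect_equal(ex$method, "exact binomial")
  expect_equal(ex$p_value, min(1, 2 * pbinom(2, 12, 0.5)))
  # exact and corrected chi-square agree in rough magnitude there
  expect_lt(abs(ex$p_value - pchisq(49 / 12, 1, lower.tail = FALSE)), 0.03)
})

test_that("alert levels map probabilities with inclusive moderate boundaries", {
  expect_equal(as.character(alert_level(c(0.1, 0.45, 0.61))),
               c("low", "moderate", "high"))
  expect_equal(as.character(alert_level(c(0.30, 0.60))),
               c("moderate", "moderate"))
  expect_equal(as.character(alert_level(0, boundaries = c(0.2, 0.8))), "low")
  expect_error(alert_level(1.2), "\\[0, 1\\]")
  expect_error(alert_level(0.5, boundaries = c(0.7, 0.3)), "increasing")
})
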