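classifier_registry <- function() {
  list(
    gaussian_nb = fit_gaussian_nb,
    multinomial_nb = fit_multinomial_nb,
    decision_table = fit_decision_table,
    logistic = fit_logistic,
    smo = fit_smo
  )
}

#' Repeated stratified benchmark of the classifier suite
#'
#' Runs the full evaluation protocol on a preprocessed cohort: for each
#' repeat, a stratified 70/30 train-test split at the *patient* level (all
#' records of a patient fall on one side, preserving the Normal/SARS-risk
#' mix), each requested classifier fitted on the training records, and
#' record-level positive-class probabilities aggregated into one score per
#' patient (mean by default). The classification threshold is selected by
#' Youden's index on the training patients, then threshold metrics
#' (TP-rate, FP-rate, precision, recall, F1, accuracy, MCC) are computed on
#' the test patients alongside threshold-free ROC-AUC and PR-AUC. Metrics
#' are reported per repeat and as mean +/- sample SD; a designated pair of
#' classifiers is compared by McNemar's test on their matched test
#' predictions in every repeat. Train and test patient sets are disjoint by
#' construction in every repeat.
#'
#' @param cohort A preprocessed cohort tibble ([preprocess_cohort()]).
#' @param models Character vector of classifier names among
#'   `"gaussian_nb"`, `"multinomial_nb"`, `"decision_table"`, `"logistic"`,
#'   `"smo"`.
#' @param n_repeats Number of repeated splits (>= 1; with 1, SDs are
#'   omitted with a warning).
#' @param seed Master seed; each repeat derives its own split stream.
#' @param train_frac Training fraction of patients per class.
#' @param positive Positive class label.
#' @param aggregate Patient-score aggregation of record probabilities:
#'   `"mean"` (default) or `"max"`.
#' @param mcnemar_pair Length-2 character vector naming the compared models.
#' @param model_args Named list of extra arguments per model, e.g.
#'   `list(smo = list(max_train = 2000))`.
#' @return A `vw_benchmark` object with elements `metrics` (per repeat x
#'   model), `summary` (mean/sd per model x metric), `mcnemar` (per
#'   repeat), and the run settings.
#' @export
run_benchmark <- function(cohort,
                          models = c("gaussian_nb", "multinomial_nb",
                                     "decision_table", "logistic", "smo"),
                          n_repeats = 10, seed = 1, train_frac = 0.7,
                          positive = "SARS-risk",
                          aggregate = c("mean", "max"),
                          mcnemar_pair = c("logistic", "gaussian_nb"),
                          model_args = list()) {
  aggregate <- match.arg(aggregate)
  n_repeats <- check_count(n_repeats, "n_repeats")
  registry <- classifier_registry()
  unknown <- setdiff(models, names(registry))
  if (length(unknown)) {
    abort(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
  }
  if (n_repeats == 1) warn("n_repeats = 1: standard deviations omitted")
  cohort <- tibble::as_tibble(cohort)
  patients <- dplyr::distinct(cohort, .data$patient_id, .data$label)
  if (!positive %in% patients$label) {
    abort(sprintf("positive class `%s` absent from cohort", positive))
  }
  agg_fun <- if (aggregate == "mean") mean else max

  metric_rows <- list()
  mcnemar_rows <- list()
  do_mcnemar <- all(mcnemar_pair %in% models) && length(mcnemar_pair) == 2

  for (r in seq_len(n_repeats)) {
    train_ids <- with_stream(seed, paste0("split", r), {
      unlist(lapply(split(patients$patient_id, patients$label), function(ids) {
        sample(ids, round(train_frac * length(ids)))
      }), use.names = FALSE)
    })
    train <- cohort[cohort$patient_id %in% train_ids, , drop = FALSE]
    test <- cohort[!cohort$patient_id %in% train_ids, , drop = FALSE]

    patient_scores <- function(model, data) {
      p <- predict(model, data, type = "prob")[[positive]]
      dplyr::summarise(
        dplyr::group_by(tibble::tibble(patient_id = data$patient_id,
                                       label = data$label, p = p),
                        .data$patient_id, .data$label),
        score = agg_fun(.data$p), .groups = "drop")
    }

    preds <- list()
    for (m in models) {
      args <- c(list(train), model_args[[m]] %||% list())
      model <- do.call(registry[[m]], args)
      tr_scores <- patient_scores(model, train)
      te_scores <- patient_scores(model, test)
      thr <- youden_threshold(tr_scores, "label", "score", positive)
      pred_pos <- te_scores$score >= thr
      truth_pos <- te_scores$label == positive
      cm <- confusion_metrics(tp = sum(pred_pos & truth_pos),
                              fp = sum(pred_pos & !truth_pos),
                              tn = sum(!pred_pos & !truth_pos),
                              fn = sum(!pred_pos & truth_pos))
      metric_rows[[length(metric_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_id = r, model = m, threshold = thr),
        dplyr::select(cm, "tp_rate", "fp_rate", "precision", "recall",
                      "f1", "accuracy", "mcc"),
        tibble::tibble(
          roc_auc = roc_auc(te_scores, "label", "score", positive),
          pr_auc = pr_auc(te_scores, "label", "score", positive))
      )
      preds[[m]] <- tibble::tibble(patient_id = te_scores$patient_id,
                                   correct = pred_pos == truth_pos)
    }
    if (do_mcnemar) {
      joined <- dplyr::inner_join(preds[[mcnemar_pair[1]]],
                                  preds[[mcnemar_pair[2]]],
                                  by = "patient_id",
                                  suffix = c("_1", "_2"))
      b <- sum(joined$correct_1 & !joined$correct_2)
      cc <- sum(!joined$correct_1 & joined$correct_2)
      mt <- mcnemar_test(b, cc)
      mt$repeat_id <- r
      mcnemar_rows[[r]] <- mt
    }
  }

  metrics <- dplyr::bind_rows(metric_rows)
  summary <- dplyr::summarise(
    dplyr::group_by(
      tidyr::pivot_longer(metrics, cols = c("tp_rate", "fp_rate", "precision",
                                            "recall", "f1", "accuracy", "mcc",
                                            "roc_auc", "pr_auc"),
                          names_to = "metric"),
      .data$model, .data$metric),
    mean = mean(.data$value),
    sd = if (n_repeats >= 2) sd(.data$value) else NA_real_,
    .groups = "drop")
  structure(
    list(metrics = metrics, summary = summary,
         mcnemar = if (do_mcnemar) dplyr::bind_rows(mcnemar_rows) else NULL,
         models = models, n_repeats = n_repeats, seed = seed,
         train_frac = train_frac, positive = positive,
         aggregate = aggregate, mcnemar_pair = if (do_mcnemar) mcnemar_pair),
    class = "vw_benchmark"
  )
}

#' @export
print.vw_benchmark <- function(x, ...) {
  cat(sprintf("<vw_benchmark: %d models x %d repeats (stratified %.0f/%.0f patient-level splits)>\n",
              length(x$models), x$n_repeats,
              100 * x$train_frac, 100 * (1 - x$train_frac)))
  print(glance(x))
  invisible(x)
}

#' Render a benchmark summary as a Markdown table
#'
#' Columns mirror the conventional evaluation layout: TP-rate, FP-rate,
#' precision, recall, F-measure, MCC, ROC (AUC) and PRC (AUC), as
#' `mean +/- sd` per classifier.
#'
#' @param bench A [run_benchmark()] result.
#' @return A character scalar of Markdown.
#' @export
benchmark_markdown <- function(bench) {
  stopifnot(inherits(bench, "vw_benchmark"))
  cols <- c(tp_rate = "TP-rate", fp_rate = "FP-rate", precision = "Precision",
            recall = "Recall", f1 = "F-measure", mcc = "MCC",
            roc_auc = "ROC", pr_auc = "PRC")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(bench$summary,
                  cell = ifelse(is.na(.data$sd), sprintf("%.3f", .data$mean),
                                sprintf("%.3f ± %.3f", .data$mean, .data$sd))),
    id_cols = "model", names_from = "metric", values_from = "cell")
  header <- paste0("| Algorithm | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(wide)), function(i) {
    paste0("| ", wide$model[i], " | ",
           paste(unlist(wide[i, names(cols)]), collapse = " | "), " |")
  }, character(1))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Write a benchmark report as JSON
#'
#' @param bench A [run_benchmark()] result.
#' @param path File path.
#' @export
write_benchmark_json <- function(bench, path) {
  stopifnot(inherits(bench, "vw_benchmark"))
  obj <- list(
    models = bench$models, n_repeats = bench$n_repeats, seed = bench$seed,
    train_frac = bench$train_frac, positive = bench$positive,
    aggregate = bench$aggregate,
    summary = bench$summary, metrics = bench$metrics,
    mcnemar = bench$mcnemar
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
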