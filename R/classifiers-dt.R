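#' Decision-table classifier
#'
#' A rule-lookup classifier of the "IF(Condition_1 AND ... AND Condition_n)
#' THEN Action" form. Features are discretized into equal-width bins; the
#' condition schema (which features participate) is chosen by greedy forward
#' selection maximizing cross-validated accuracy, starting from the empty
#' schema (a majority-class model). The fitted table maps each observed
#' condition key to the majority class among matching training rows;
#' condition keys never seen in training fall back to the global majority
#' class. Fitting is deterministic: folds are assigned by row order and
#' feature order breaks score ties.
#'
#' @inheritParams fit_multinomial_nb
#' @param cv_folds Number of cross-validation folds for feature selection.
#' @return A `vw_dtable` model.
#' @export
fit_decision_table <- function(data, label = "label", features = NULL,
                               n_bins = 10, cv_folds = 3) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  cv_folds <- check_count(cv_folds, "cv_folds", min = 2)
  d <- design(data, label, features)
  classes <- sort(unique(d$y))
  edges <- purrr::map(seq_along(d$features), ~ bin_edges(d$X[, .x], n_bins))
  names(edges) <- d$features
  B <- vapply(seq_along(d$features),
              function(j) bin_assign(d$X[, j], edges[[j]]),
              integer(nrow(d$X)))
  B <- matrix(B, nrow = nrow(d$X), dimnames = list(NULL, d$features))
  y <- d$y
  n <- length(y)
  fold <- (seq_len(n) - 1L) %% cv_folds + 1L
  majority <- function(yy) names(which.max(table(yy)))

  cv_accuracy <- function(selected) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(selected) == 0) {
        pred <- rep(majority(y[tr]), sum(!tr))
      } else {
        key_tr <- do.call(paste, c(as.data.frame(B[tr, selected, drop = FALSE]),
                                   sep = "\r"))
        key_te <- do.call(paste, c(as.data.frame(B[!tr, selected, drop = FALSE]),
                                   sep = "\r"))
        tab <- table(key_tr, factor(y[tr], classes))
        maj <- classes[max.col(tab, ties.method = "first")]
        names(maj) <- rownames(tab)
        pred <- maj[key_te]
        pred[is.na(pred)] <- majority(y[tr])
      }
      correct <- correct + sum(pred == y[!tr])
    }
    correct / n
  }

  selected <- character()
  best_acc <- cv_accuracy(selected)
  repeat {
    remaining <- setdiff(d$features, selected)
    if (length(remaining) == 0) break
    accs <- vapply(remaining, function(f) cv_accuracy(c(selected, f)),
                   numeric(1))
    if (max(accs) > best_acc) {
      selected <- c(selected, remaining[which.max(accs)])
      best_acc <- max(accs)
    } else {
      break
    }
  }

  if (length(selected)) {
    key <- do.call(paste, c(as.data.frame(B[, selected, drop = FALSE]),
                            sep = "\r"))
    tab <- table(key, factor(y, classes))
    table_counts <- unclass(tab)
  } else {
    table_counts <- NULL
  }
  structure(list(classes = classes, features = d$features, edges = edges,
                 selected = selected, table_counts = table_counts,
                 global_majority = majority(y),
                 priors = as.numeric(table(factor(y, classes))) / n,
                 n_bins = n_bins, cv_accuracy = best_acc),
            class = "vw_dtable")
}

#' @export
predict.vw_dtable <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  classes <- object$classes
  if (length(object$selected) == 0) {
    if (type == "class") return(rep(object$global_majority, n))
    return(prob_tibble(matrix(rep(object$priors, each = n), nrow = n), classes))
  }
  Bsel <- vapply(object$selected, function(f) {
    bin_assign(newdata[[f]], object$edges[[f]])
  }, integer(n))
  Bsel <- matrix(Bsel, nrow = n, dimnames = list(NULL, object$selected))
  key <- do.call(paste, c(as.data.frame(Bsel), sep = "\r"))
  idx <- match(key, rownames(object$table_counts))
  if (type == "class") {
    maj <- classes[max.col(object$table_counts, ties.method = "first")]
    pred <- maj[idx]
    pred[is.na(pred)] <- object$global_majority
    pred
  } else {
    # Laplace-smoothed per-key class frequencies; unseen keys get the priors.
    counts <- object$table_counts[ifelse(is.na(idx), 1L, idx), , drop = FALSE] + 1
    p <- counts / rowSums(counts)
    p[is.na(idx), ] <- matrix(rep(object$priors, each = sum(is.na(idx))),
                              ncol = length(classes))
    prob_tibble(p, classes)
  }
}
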