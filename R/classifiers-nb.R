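#' Gaussian naive Bayes
#'
#' Fits the classic naive Bayes model with Gaussian class-conditional
#' densities: class priors \eqn{P(C_k)} and, under the conditional-
#' independence assumption, one mean and variance per feature per class.
#' Posteriors follow Bayes' theorem,
#' \eqn{P(C_k | x) \propto P(C_k) \prod_i P(x_i | C_k)}, and the predicted
#' class is the posterior argmax. Plain Gaussian densities only (no kernel
#' density estimation); variances are floored at `var_floor` to guard
#' zero-variance features.
#'
#' @param data Training data frame.
#' @param label Name of the class-label column.
#' @param features Feature column names; default all numeric columns except
#'   the label and `tick`.
#' @param var_floor Lower bound applied to every estimated variance.
#' @return A `vw_gnb` model.
#' @export
fit_gaussian_nb <- function(data, label = "label", features = NULL,
                            var_floor = 1e-9) {
  d <- design(data, label, features)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) abort("training data must contain at least two classes")
  stats_by_class <- purrr::map(classes, function(k) {
    Xk <- d$X[d$y == k, , drop = FALSE]
    list(
      prior = nrow(Xk) / nrow(d$X),
      mean = colMeans(Xk),
      var = pmax(apply(Xk, 2, function(col) {
        if (length(col) > 1) stats::var(col) else 0
      }), var_floor)
    )
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, features = d$features,
                 params = stats_by_class, var_floor = var_floor),
            class = "vw_gnb")
}

#' @export
predict.vw_gnb <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(tibble::as_tibble(newdata)[object$features])
  log_scores <- vapply(object$classes, function(k) {
    p <- object$params[[k]]
    ll <- log(p$prior)
    for (j in seq_along(object$features)) {
      ll <- ll + dnorm(X[, j], p$mean[j], sqrt(p$var[j]), log = TRUE)
    }
    ll
  }, numeric(nrow(X)))
  log_scores <- matrix(log_scores, nrow = nrow(X))
  probs <- softmax_rows(log_scores)
  if (type == "class") {
    object$classes[max.col(probs, ties.method = "first")]
  } else {
    prob_tibble(probs, object$classes)
  }
}

#' Multinomial naive Bayes over binned vitals
#'
#' The multinomial variant adapted from token counts to continuous vitals:
#' each feature is discretized into `n_bins` equal-width bins fitted on the
#' training range, per-class bin frequencies are Laplace-smoothed with
#' pseudo-count `alpha`, and posteriors combine the smoothed log-likelihoods
#' with class priors. Bins unseen at training time survive through the
#' smoothing; a constant feature collapses to a single bin and contributes
#' nothing.
#'
#' @inheritParams fit_gaussian_nb
#' @param n_bins Number of equal-width bins per feature (>= 2).
#' @param alpha Laplace smoothing pseudo-count (> 0).
#' @return A `vw_mnb` model.
#' @export
fit_multinomial_nb <- function(data, label = "label", features = NULL,
                               n_bins = 10, alpha = 1) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  if (alpha <= 0) abort("`alpha` must be > 0")
  d <- design(data, label, features)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) abort("training data must contain at least two classes")
  edges <- purrr::map(seq_along(d$features), ~ bin_edges(d$X[, .x], n_bins))
  names(edges) <- d$features
  log_lik <- purrr::map(seq_along(d$features), function(j) {
    if (is.null(edges[[j]])) return(NULL)  # constant feature: no contribution
    bins <- bin_assign(d$X[, j], edges[[j]])
    sapply(classes, function(k) {
      counts <- tabulate(bins[d$y == k], nbins = n_bins) + alpha
      log(counts / sum(counts))
    })
  })
  names(log_lik) <- d$features
  priors <- as.numeric(table(factor(d$y, classes))) / length(d$y)
  structure(list(classes = classes, features = d$features, priors = priors,
                 edges = edges, log_lik = log_lik, n_bins = n_bins,
                 alpha = alpha),
            class = "vw_mnb")
}

#' @export
predict.vw_mnb <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(tibble::as_tibble(newdata)[object$features])
  log_scores <- matrix(rep(log(object$priors), each = nrow(X)),
                       nrow = nrow(X))
  for (j in seq_along(object$features)) {
    ll <- object$log_lik[[j]]
    if (is.null(ll)) next
    bins <- bin_assign(X[, j], object$edges[[j]])
    log_scores <- log_scores + ll[bins, , drop = FALSE]
  }
  probs <- softmax_rows(log_scores)
  if (type == "class") {
    object$classes[max.col(probs, ties.method = "first")]
  } else {
    prob_tibble(probs, object$classes)
  }
}
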