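#' Ridge-penalized logistic regression
#'
#' Binary logistic regression fitted from its defining equation
#' \deqn{P(Y = 1 | x) = \frac{1}{1 + e^{-(b_0 + b_1 x_1 + \dots + b_n x_n)}}}
#' by penalized maximum likelihood, with an L2 (ridge) penalty on the
#' coefficients (the intercept is unpenalized) and a damped Newton / IRLS
#' optimizer capped at `max_iter` iterations. The default ridge strength
#' 1e-8 is the conventional "numerical-stability" default of rule-learning
#' workbenches; non-convergence at the iteration cap returns the fit with
#' `converged = FALSE` rather than an error. Fitting is deterministic.
#'
#' @inheritParams fit_gaussian_nb
#' @param positive Class modelled as \eqn{Y = 1}; default `"SARS-risk"`
#'   when present, else the last class in sort order.
#' @param ridge L2 penalty strength (>= 0).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficient max-change.
#' @return A `vw_logistic` model with elements `coef` (intercept first),
#'   `converged`, `iter`.
#' @export
fit_logistic <- function(data, label = "label", features = NULL,
                         positive = NULL, ridge = 1e-8, max_iter = 100,
                         tol = 1e-8) {
  if (ridge < 0) abort("`ridge` must be >= 0")
  max_iter <- check_count(max_iter, "max_iter")
  d <- design(data, label, features)
  classes <- sort(unique(d$y))
  if (length(classes) != 2) abort("logistic regression requires exactly two classes")
  positive <- resolve_positive(classes, positive)
  y <- as.numeric(d$y == positive)
  X <- cbind(`(Intercept)` = 1, d$X)
  p <- ncol(X)
  penalty <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - penalty %*% beta
    hess <- crossprod(X * w, X) + penalty
    step <- tryCatch(solve(hess, grad), error = function(e) {
      solve(hess + diag(1e-8, p), grad)
    })
    # Halve the step while it degrades the penalized log-likelihood.
    pll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - (pmax(e, 0) + log1p(exp(-abs(e))))) -
        0.5 * drop(t(b) %*% penalty %*% b)
    }
    cur <- pll(beta)
    damp <- 1
    repeat {
      cand <- beta + damp * drop(step)
      if (pll(cand) >= cur - 1e-12 || damp < 1e-4) break
      damp <- damp / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(classes = classes, positive = positive,
                 features = d$features, coef = drop(beta), ridge = ridge,
                 converged = converged, iter = iter),
            class = "vw_logistic")
}

#' @export
predict.vw_logistic <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(tibble::as_tibble(newdata)[object$features]))
  p_pos <- plogis(drop(X %*% object$coef))
  if (type == "class") {
    ifelse(p_pos >= 0.5, object$positive,
           setdiff(object$classes, object$positive))
  } else {
    p <- cbind(1 - p_pos, p_pos)
    prob_tibble(p, c(setdiff(object$classes, object$positive), object$positive))
  }
}
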