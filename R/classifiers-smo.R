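#' Support vector machine trained by sequential minimal optimization
#'
#' Solves the soft-margin SVM dual with the simplified SMO algorithm,
#' implemented directly from its update algebra: for a violating pair
#' \eqn{(i, j)} compute the prediction errors \eqn{E_i = f(x_i) - y_i},
#' the curvature \eqn{\eta = K(x_i,x_i) + K(x_j,x_j) - 2K(x_i,x_j)}, step
#' \eqn{\alpha_j \leftarrow \alpha_j + y_j (E_i - E_j)/\eta}, clip
#' \eqn{\alpha_j} to its \eqn{[L, H]} box (from the constraints
#' \eqn{0 \le \alpha \le C} and \eqn{\sum_i \alpha_i y_i = 0}), move
#' \eqn{\alpha_i} by the pair constraint, and recompute the threshold
#' \eqn{b}. Pairs with \eqn{\eta \le 0} are skipped. The partner index j is
#' chosen deterministically as the point maximizing \eqn{|E_i - E_j|}
#' (cached errors, updated incrementally), falling back to the next-best
#' partner whenever a pair permits no progress, so repeated fits on the
#' same data are identical. The sweep terminates after `max_passes` consecutive
#' full passes without an update.
#'
#' Training cost grows quadratically with the number of rows, so fits are
#' capped at `max_train` rows via deterministic stratified thinning
#' (class-proportional, evenly spaced in row order).
#'
#' @inheritParams fit_logistic
#' @param C Box constraint (regularization); larger C fits training data
#'   harder.
#' @param tol KKT violation tolerance.
#' @param max_passes Consecutive no-change passes before termination.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param gamma RBF bandwidth; default `1 / n_features`.
#' @param max_train Training-set cap (rows).
#' @return A `vw_smo` model with multipliers `alpha`, threshold `b`, and
#'   (linear kernel) weight vector `w`.
#' @export
fit_smo <- function(data, label = "label", features = NULL, positive = NULL,
                    C = 1, tol = 1e-3, max_passes = 10,
                    kernel = c("linear", "rbf"), gamma = NULL,
                    max_train = 2000) {
  kernel <- match.arg(kernel)
  if (C <= 0) abort("`C` must be > 0")
  d <- design(data, label, features)
  classes <- sort(unique(d$y))
  if (length(classes) != 2) abort("SMO requires exactly two classes")
  positive <- resolve_positive(classes, positive)
  X <- d$X
  y <- ifelse(d$y == positive, 1, -1)
  if (nrow(X) > max_train) {
    keep <- sort(unlist(lapply(c(-1, 1), function(cls) {
      idx <- which(y == cls)
      k <- max(1L, round(max_train * length(idx) / length(y)))
      idx[unique(round(seq(1, length(idx), length.out = k)))]
    })))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  kcol <- switch(kernel,
    linear = function(i) drop(X %*% X[i, ]),
    rbf = function(i) {
      d2 <- rowSums(sweep(X, 2, X[i, ])^2)
      exp(-gamma * d2)
    }
  )
  kdiag <- switch(kernel,
    linear = rowSums(X^2),
    rbf = rep(1, n)
  )

  alpha <- numeric(n)
  b <- 0
  E <- -y  # f(x) = 0 initially
  passes <- 0L
  sweeps <- 0L
  while (passes < max_passes && sweeps < 200L) {
    changed <- 0L
    for (i in seq_len(n)) {
      ri <- E[i] * y[i]
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0))) next
      Ki <- kcol(i)
      # partner candidates by decreasing |Ei - Ej|; fall through on failure
      for (j in setdiff(order(abs(E[i] - E), decreasing = TRUE), i)) {
        if (y[i] == y[j]) {
          L <- max(0, alpha[i] + alpha[j] - C)
          H <- min(C, alpha[i] + alpha[j])
        } else {
          L <- max(0, alpha[j] - alpha[i])
          H <- min(C, C + alpha[j] - alpha[i])
        }
        if (L >= H) next
        eta <- kdiag[i] + kdiag[j] - 2 * Ki[j]
        if (eta <= 0) next
        aj_new <- min(max(alpha[j] + y[j] * (E[i] - E[j]) / eta, L), H)
        if (abs(aj_new - alpha[j]) < 1e-7) next
        Kj <- kcol(j)
        ai_new <- alpha[i] + y[i] * y[j] * (alpha[j] - aj_new)
        b1 <- b - E[i] - y[i] * (ai_new - alpha[i]) * kdiag[i] -
          y[j] * (aj_new - alpha[j]) * Ki[j]
        b2 <- b - E[j] - y[i] * (ai_new - alpha[i]) * Ki[j] -
          y[j] * (aj_new - alpha[j]) * kdiag[j]
        b_new <- if (ai_new > 0 && ai_new < C) b1
                 else if (aj_new > 0 && aj_new < C) b2
                 else (b1 + b2) / 2
        E <- E + y[i] * (ai_new - alpha[i]) * Ki +
          y[j] * (aj_new - alpha[j]) * Kj + (b_new - b)
        alpha[i] <- ai_new
        alpha[j] <- aj_new
        b <- b_new
        changed <- changed + 1L
        break
      }
    }
    sweeps <- sweeps + 1L
    passes <- if (changed == 0L) passes + 1L else 0L
  }

  sv <- alpha > 1e-12
  model <- list(classes = classes, positive = positive,
                features = d$features, kernel = kernel, gamma = gamma,
                C = C, tol = tol, b = b,
                alpha = alpha[sv], sv_x = X[sv, , drop = FALSE],
                sv_y = y[sv], n_train = n, sweeps = sweeps)
  if (kernel == "linear") {
    model$w <- drop(crossprod(X, alpha * y))
  }
  f_train <- smo_decision(model, X)
  model$score_range <- range(f_train)
  structure(model, class = "vw_smo")
}

smo_decision <- function(model, X) {
  if (model$kernel == "linear") {
    drop(X %*% model$w) + model$b
  } else {
    if (length(model$alpha) == 0) return(rep(model$b, nrow(X)))
    K <- exp(-model$gamma * outer(rowSums(X^2), rep(1, nrow(model$sv_x))) -
               model$gamma * outer(rep(1, nrow(X)), rowSums(model$sv_x^2)) +
               2 * model$gamma * X %*% t(model$sv_x))
    drop(K %*% (model$alpha * model$sv_y)) + model$b
  }
}

#' @rdname fit_smo
#' @param model A fitted `vw_smo` model.
#' @param newdata Data frame of instances to score.
#' @return `decision_value()`: the signed margin \eqn{f(x)} per row.
#' @export
decision_value <- function(model, newdata) {
  stopifnot(inherits(model, "vw_smo"))
  X <- as.matrix(tibble::as_tibble(newdata)[model$features])
  smo_decision(model, X)
}

#' @export
predict.vw_smo <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  f <- decision_value(object, newdata)
  negative <- setdiff(object$classes, object$positive)
  if (type == "class") {
    ifelse(f >= 0, object$positive, negative)
  } else {
    # Decision values min-max mapped into [0, 1] on the training range:
    # a monotone score for ranking/alerting, not a calibrated probability.
    r <- object$score_range
    p_pos <- if (r[2] > r[1]) pmin(pmax((f - r[1]) / (r[2] - r[1]), 0), 1)
             else rep(0.5, length(f))
    prob_tibble(cbind(1 - p_pos, p_pos), c(negative, object$positive))
  }
}

#' KKT feasibility diagnostics for a fitted SMO model
#'
#' Recomputes, on the training support information, the dual-feasibility
#' checks: the box constraint \eqn{0 \le \alpha_i \le C}, the equality
#' constraint \eqn{\sum_i \alpha_i y_i = 0}, and the count of KKT
#' violations at tolerance `tol` under the simplified criterion
#' (\eqn{y_i E_i < -tol} with \eqn{\alpha_i < C}, or \eqn{y_i E_i > tol}
#' with \eqn{\alpha_i > 0}) evaluated on the supplied data.
#'
#' @param model A fitted `vw_smo`.
#' @param data Data frame with the training features and labels.
#' @param label Label column name.
#' @return A one-row tibble: `box_ok`, `sum_alpha_y`, `n_violations`.
#' @export
smo_kkt <- function(model, data, label = "label") {
  stopifnot(inherits(model, "vw_smo"))
  X <- as.matrix(tibble::as_tibble(data)[model$features])
  y <- ifelse(as.character(data[[label]]) == model$positive, 1, -1)
  f <- smo_decision(model, X)
  Ei <- f - y
  alpha_full <- numeric(nrow(X))
  # reconstruct alignment: alphas are stored for support vectors only
  # (match by row of the stored support-vector matrix)
  if (length(model$alpha)) {
    key <- function(m) apply(m, 1, paste, collapse = "\r")
    idx <- match(key(model$sv_x), key(X))
    alpha_full[idx[!is.na(idx)]] <- model$alpha[!is.na(idx)]
  }
  ri <- Ei * y
  viol <- (ri < -model$tol & alpha_full < model$C) |
    (ri > model$tol & alpha_full > 0)
  tibble::tibble(
    box_ok = all(alpha_full >= -1e-9 & alpha_full <= model$C + 1e-9),
    sum_alpha_y = sum(alpha_full * y),
    n_violations = sum(viol)
  )
}
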