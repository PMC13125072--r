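# broom-style tidiers for the fitted objects.

#' @exportS3Method generics::tidy
tidy.vw_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @exportS3Method generics::glance
glance.vw_logistic <- function(x, ...) {
  tibble::tibble(converged = x$converged, iter = x$iter, ridge = x$ridge,
                 n_features = length(x$features), positive = x$positive)
}

#' @exportS3Method generics::tidy
tidy.vw_gnb <- function(x, ...) {
  purrr::imap_dfr(x$params, function(p, cls) {
    tibble::tibble(class = cls, feature = x$features,
                   prior = p$prior, mean = unname(p$mean),
                   variance = unname(p$var))
  })
}

#' @exportS3Method generics::glance
glance.vw_gnb <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_features = length(x$features), var_floor = x$var_floor)
}

#' @exportS3Method generics::tidy
tidy.vw_dtable <- function(x, ...) {
  tibble::tibble(order = seq_along(x$selected), feature = x$selected)
}

#' @exportS3Method generics::glance
glance.vw_dtable <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 cv_accuracy = x$cv_accuracy,
                 global_majority = x$global_majority, n_bins = x$n_bins)
}

#' @exportS3Method generics::tidy
tidy.vw_smo <- function(x, ...) {
  tibble::tibble(support_vector = seq_along(x$alpha), alpha = x$alpha,
                 y = x$sv_y)
}

#' @exportS3Method generics::glance
glance.vw_smo <- function(x, ...) {
  tibble::tibble(n_support = length(x$alpha), b = x$b, C = x$C,
                 kernel = x$kernel, sweeps = x$sweeps, n_train = x$n_train)
}

#' @exportS3Method generics::tidy
tidy.vw_benchmark <- function(x, ...) {
  x$summary
}

#' @exportS3Method generics::glance
glance.vw_benchmark <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$summary, "model", "metric", "mean"),
    names_from = "metric", values_from = "mean")
}
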