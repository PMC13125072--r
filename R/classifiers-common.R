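# Shared plumbing for the classifier implementations.

# Default predictor set: numeric columns, excluding identifiers and the label.
default_features <- function(data, label) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, c(label, "tick"))
}

# Extract a numeric feature matrix + response vector, validating completeness.
design <- function(data, label, features) {
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) abort(sprintf("label column `%s` not found", label))
  features <- features %||% default_features(data, label)
  if (length(features) == 0) abort("no feature columns available")
  if (anyDuplicated(features)) abort("feature names must be unique")
  X <- as.matrix(data[features])
  if (!is.numeric(X)) abort("features must be numeric")
  if (anyNA(X)) abort("features contain missing values; preprocess first")
  y <- as.character(data[[label]])
  list(X = X, y = y, features = features)
}

resolve_positive <- function(classes, positive) {
  if (is.null(positive)) {
    if ("SARS-risk" %in% classes) "SARS-risk" else classes[length(classes)]
  } else {
    if (!positive %in% classes) {
      abort(sprintf("positive class `%s` absent from training labels", positive))
    }
    positive
  }
}

# Row-normalize a matrix of log-scores into probabilities (log-sum-exp).
softmax_rows <- function(log_scores) {
  m <- apply(log_scores, 1, max)
  p <- exp(log_scores - m)
  p / rowSums(p)
}

prob_tibble <- function(p, classes) {
  colnames(p) <- classes
  tibble::as_tibble(p)
}

#' Save and load fitted classifiers as JSON
#'
#' Persists a fitted model's parameters (no code, no environments) as JSON
#' and restores it to a predict-ready object.
#'
#' @param model A fitted `vw_*` classifier.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  writeLines(jsonlite::serializeJSON(model, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

# Equal-width bin edges on the training range; constant features degenerate
# to a single bin and contribute nothing to the likelihood.
bin_edges <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  seq(lo, hi, length.out = n_bins + 1)
}

# Assign values to bins, clamping out-of-range values to the edge bins.
bin_assign <- function(x, edges) {
  if (is.null(edges)) return(rep(1L, length(x)))
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}
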