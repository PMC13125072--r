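# ggplot2 visualizations for the main result types.

#' Plot a patient's vital-sign traces
#'
#' Faceted time-series of each vital channel for one or more patients.
#'
#' @param records A cohort tibble.
#' @param patients Patient ids to show (default: first patient).
#' @return A ggplot object.
#' @export
plot_vitals <- function(records, patients = NULL) {
  records <- tibble::as_tibble(records)
  patients <- patients %||% records$patient_id[1]
  d <- tidyr::pivot_longer(
    dplyr::filter(records, .data$patient_id %in% patients),
    cols = -dplyr::any_of(c("patient_id", "tick", "label")),
    names_to = "channel")
  ggplot2::ggplot(d, ggplot2::aes(.data$tick, .data$value,
                                  colour = .data$patient_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "tick", y = NULL, colour = "patient") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param data Scored instances (see [roc_points()]).
#' @inheritParams roc_points
#' @return A ggplot object.
#' @export
plot_roc <- function(data, truth, score, positive = "SARS-risk") {
  pts <- roc_points(data, {{ truth }}, {{ score }}, positive)
  auc <- roc_auc(data, {{ truth }}, {{ score }}, positive)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", auc)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vw_benchmark <- function(object, ...) {
  d <- dplyr::filter(object$summary,
                     .data$metric %in% c("accuracy", "mcc", "roc_auc", "pr_auc"))
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "mean ± SD over repeats") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.vw_world <- function(object, ...) {
  d <- dplyr::mutate(object$agents,
                     role = ifelse(.data$is_doctor, "doctor",
                                   ifelse(grepl("^sensor", .data$kind),
                                          "sensor", "patient")))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, shape = .data$role)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$probability), size = 3,
                        na.rm = TRUE) +
    ggplot2::scale_colour_gradient(low = "seagreen", high = "firebrick",
                                   limits = c(0, 1), na.value = "grey40") +
    ggplot2::coord_equal(xlim = c(0, object$config$grid_size),
                         ylim = c(0, object$config$grid_size)) +
    ggplot2::labs(title = sprintf("tick %d", object$tick)) +
    ggplot2::theme_minimal()
}
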