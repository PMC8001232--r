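# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline geom_line
#'   geom_point geom_col facet_wrap labs scale_y_log10 theme_minimal
NULL

#' Plot the distribution of normalized risk scores
#'
#' @param object A `crc_scores` tibble.
#' @param ... Unused.
#' @return A ggplot: score histogram with the decision threshold marked.
#' @export
autoplot.crc_scores <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 50
  ggplot(tibble::as_tibble(object), aes(x = .data$normalized)) +
    geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = thr, linetype = "dashed", colour = "firebrick") +
    labs(x = "normalized risk score (%)", y = "records",
         title = "Worst-case-normalized risk scores",
         subtitle = paste0("scheme: ", object$scheme[1], "; threshold ", thr, "%")) +
    theme_minimal()
}

#' Compare the three weight schemes record by record
#'
#' Line plot of normalized scores per record under the convergent, deflection
#' and combined strategies; the combined curve typically runs between the
#' other two.
#'
#' @param cohort A `crc_cohort`.
#' @param schema Schema override.
#' @param records Optional subset of record indices to draw (default first 50).
#' @return A ggplot.
#' @export
plot_scheme_comparison <- function(cohort, schema = NULL, records = 1:50) {
  long <- score_all_schemes(cohort, schema = schema)
  ids <- unique(long$record_id)
  records <- records[records <= length(ids)]
  long <- dplyr::filter(long, .data$record_id %in% ids[records])
  long$index <- match(long$record_id, ids)
  ggplot(long, aes(x = .data$index, y = .data$normalized, colour = .data$scheme)) +
    geom_line(alpha = 0.8) + geom_point(size = 0.8) +
    labs(x = "record", y = "normalized risk score (%)", colour = "weights",
         title = "Risk scores under the three weighting strategies") +
    theme_minimal()
}

#' Plot a classification bench report
#'
#' @param object A `crc_bench` tibble.
#' @param ... Unused.
#' @return A ggplot: the four measures by model, faceted by protocol.
#' @export
autoplot.crc_bench <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("accuracy", "sensitivity", "specificity", "precision"),
    names_to = "measure", values_to = "value")
  ggplot(long, aes(x = .data$model, y = .data$value, fill = .data$measure)) +
    geom_col(position = "dodge") +
    facet_wrap(~protocol) +
    labs(x = NULL, y = "percent", title = "Classification bench") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an architecture sweep
#'
#' @param object A `crc_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot: best-validation MSE (log scale) per architecture.
#' @export
autoplot.crc_sweep <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$arch <- paste0(tab$hidden_layers, "x", tab$neurons)
  tab$arch <- factor(tab$arch, levels = tab$arch)
  ggplot(tab, aes(x = .data$arch, y = .data$mse, fill = .data$best)) +
    geom_col() +
    scale_y_log10() +
    labs(x = "hidden layers x neurons", y = "validation MSE (log scale)",
         title = "Feedforward-network architecture sweep") +
    theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' Plot a training run's performance curves
#'
#' @param object A `crc_training`.
#' @param ... Unused.
#' @return A ggplot: training and validation MSE per epoch.
#' @export
autoplot.crc_training <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("train_mse", "val_mse"),
                              names_to = "partition", values_to = "mse")
  ggplot(long, aes(x = .data$epoch, y = .data$mse, colour = .data$partition)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "epoch", y = "MSE (log scale)",
         title = "Levenberg-Marquardt training performance") +
    theme_minimal()
}
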