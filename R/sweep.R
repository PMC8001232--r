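#' The ten benchmark architectures
#'
#' Hidden-layer counts of 1, 5 and 10 crossed with 3, 10 and 20 neurons per
#' layer, plus the optimized (5 layers, 40 neurons) design.
#'
#' @return Tibble with `hidden_layers` and `neurons` columns, 10 rows.
#' @export
table_architectures <- function() {
  tibble::tibble(
    hidden_layers = c(1L, 1L, 1L, 5L, 5L, 5L, 5L, 10L, 10L, 10L),
    neurons = c(3L, 10L, 20L, 3L, 10L, 20L, 40L, 3L, 10L, 20L))
}

#' Continuous regression inputs of a cohort
#'
#' The regression bench takes continuous inputs rather than the Boolean label
#' matrix: raw numeric analyte values, with qualitative variables encoded by
#' their 0/1 benign-set labels (they have no continuous form).
#'
#' @param cohort A `crc_cohort`.
#' @param schema Schema override.
#' @return A numeric tibble with one column per schema variable.
#' @export
regression_inputs <- function(cohort, schema = NULL) {
  schema <- schema %||% attr(cohort, "schema")
  if (is.null(schema)) abort_format("regression_inputs needs a schema")
  records <- if (inherits(cohort, "crc_cohort")) cohort_records(cohort) else tibble::as_tibble(cohort)
  records <- records[variable_names(schema)]
  cols <- purrr::imap(schema$variables, function(v, nm) {
    if (v$kind == "numeric") as.numeric(records[[nm]])
    else as.numeric(label_value(records[[nm]], v))
  })
  tibble::as_tibble(cols)
}

#' Train the full architecture sweep
#'
#' Trains each architecture of [table_architectures()] on identical seeded
#' train/validation/test partitions with [lm_train()], and reports a
#' benchmark-table-shaped summary with the minimum-validation-MSE
#' architecture flagged. Per-architecture weight initializations are seeded
#' deterministically from the training seed.
#'
#' @param inputs Continuous input table (e.g. [regression_inputs()]).
#' @param response Numeric response vector (0-100 normalized risk scores).
#' @param config A [training_config()].
#' @param architectures Tibble of `hidden_layers`/`neurons` rows (default the
#'   ten benchmark architectures).
#' @return A `crc_sweep` tibble: one row per architecture with `epochs`,
#'   `mse` (best-validation), `train_mse`, `test_mse`, `seconds`
#'   (informational), `gradient`, `stop_reason` and a `best` flag. The fitted
#'   `crc_training` objects ride along in the `fits` attribute.
#' @export
architecture_sweep <- function(inputs, response, config = training_config(),
                               architectures = table_architectures()) {
  stopifnot(nrow(architectures) >= 1)
  X <- as.matrix(inputs)
  fits <- purrr::pmap(architectures, function(hidden_layers, neurons) {
    net <- build_network(hidden_layers, neurons, ncol(X),
                         seed = config$seed + 1000L * hidden_layers + neurons)
    lm_train(net, X, response, config)
  })
  out <- dplyr::bind_cols(
    architectures,
    purrr::map_dfr(fits, function(f) {
      tibble::tibble(epochs = f$epochs, mse = f$mse, train_mse = f$train_mse,
                     test_mse = f$test_mse, seconds = f$seconds,
                     gradient = f$gradient, stop_reason = f$stop_reason)
    }))
  out$best <- out$mse == min(out$mse)
  structure(out, fits = fits, class = c("crc_sweep", class(tibble::tibble())))
}

#' Tolerance-band regression accuracy
#'
#' The share of predictions within `tolerance` percentage points of the true
#' 0-100 response — a surrogate accuracy for a continuous diagnosis score.
#'
#' @param predictions,truth Aligned numeric vectors.
#' @param tolerance Half-width of the agreement band in percentage points
#'   (default 5).
#' @return Percentage of predictions inside the band.
#' @export
regression_accuracy <- function(predictions, truth, tolerance = 5) {
  if (length(predictions) == 0L || length(predictions) != length(truth)) {
    abort_format("predictions and truth must be non-empty and aligned")
  }
  100 * mean(abs(predictions - truth) <= tolerance)
}
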