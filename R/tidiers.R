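# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-epoch trace of a training run
#' @param x A `crc_training`.
#' @param ... Unused.
#' @return Tibble: epoch, damping, train/validation MSE, gradient norm.
#' @export
tidy.crc_training <- function(x, ...) x$trace

#' One-row summary of a training run
#' @param x A `crc_training`.
#' @param ... Unused.
#' @return Tibble: architecture, parameter count, epochs, MSEs, gradient,
#'   stop reason, seconds.
#' @export
glance.crc_training <- function(x, ...) {
  tibble::tibble(hidden_layers = x$network$hidden_layers,
                 neurons = x$network$neurons,
                 n_parameters = n_parameters(x$network),
                 epochs = x$epochs, mse = x$mse, train_mse = x$train_mse,
                 test_mse = x$test_mse, gradient = x$gradient,
                 stop_reason = x$stop_reason, seconds = x$seconds)
}

#' Sweep report as a plain tibble
#' @param x A `crc_sweep`.
#' @param ... Unused.
#' @return The per-architecture report tibble.
#' @export
tidy.crc_sweep <- function(x, ...) tibble::as_tibble(x)

#' Best architecture of a sweep
#' @param x A `crc_sweep`.
#' @param ... Unused.
#' @return One-row tibble: the minimum-validation-MSE architecture.
#' @export
glance.crc_sweep <- function(x, ...) {
  tab <- tibble::as_tibble(x)
  tab[which.min(tab$mse), ]
}

#' Bench report as a plain tibble
#' @param x A `crc_bench`.
#' @param ... Unused.
#' @return The per-model, per-protocol report tibble.
#' @export
tidy.crc_bench <- function(x, ...) tibble::as_tibble(x)

#' Best model per protocol
#' @param x A `crc_bench`.
#' @param ... Unused.
#' @return Tibble of the highest-accuracy row within each protocol.
#' @export
glance.crc_bench <- function(x, ...) {
  tab <- tibble::as_tibble(x)
  dplyr::slice_max(dplyr::group_by(tab, .data$protocol), .data$accuracy,
                   n = 1, with_ties = FALSE)
}

#' Weight vector as a plain tibble
#' @param x A `crc_weights`.
#' @param ... Unused.
#' @return Tibble: variable, raw and unit-sum weight, scheme.
#' @export
tidy.crc_weights <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), scheme = weight_scheme(x))
}
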