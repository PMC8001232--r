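new_weights <- function(schema, raw, scheme) {
  w <- raw / sum(raw)
  structure(
    tibble::tibble(variable = variable_names(schema), raw = unname(raw), weight = unname(w)),
    scheme = scheme, schema = schema,
    class = c("crc_weights", class(tibble::tibble())))
}

#' Weight scheme attached to a weight vector
#' @param weights A `crc_weights` tibble.
#' @return The scheme name.
#' @export
weight_scheme <- function(weights) attr(weights, "scheme")

#' Convergent (near-uniform) weights of risk
#'
#' The first weighting strategy presumes every variable has approximately the
#' same impact on the diagnosis: by default each of the `n` variables gets
#' weight `1/n` (0.0222 for the 45-variable schema, inside the 0.015-0.05
#' band the strategy works in). Per-variable overrides within that band are
#' accepted and rescaled to unit sum, preserving their order.
#'
#' @param schema A `crc_schema`.
#' @param overrides Optional named numeric vector of raw weights in
#'   `[0.015, 0.05]` for some or all variables.
#' @return A `crc_weights` tibble (`variable`, `raw`, `weight`); the `weight`
#'   column always sums to 1.
#' @export
weights_convergent <- function(schema, overrides = NULL) {
  stopifnot(inherits(schema, "crc_schema"))
  n <- n_variables(schema)
  raw <- stats::setNames(rep(1 / n, n), variable_names(schema))
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% names(raw))) {
      abort_schema("overrides must be named after schema variables")
    }
    if (any(overrides <= 0)) abort_schema("override weights must be positive")
    if (any(overrides < 0.015 - 1e-12 | overrides > 0.05 + 1e-12)) {
      abort_schema("convergent override weights must lie in [0.015, 0.05]")
    }
    raw[names(overrides)] <- overrides
  }
  new_weights(schema, raw, "convergent")
}

# Deflection raw weight of one variable: mean relative difference between the
# healthy boundaries and the plausible extremes; qualitative variables take
# the full-deflection convention (raw 1).
deflection_raw <- function(schema) {
  vapply(schema$variables, function(v) {
    if (v$kind == "qualitative") return(1)
    dev <- flank_deviations(v) / 100
    mean(dev)
  }, numeric(1))
}

#' Deflection-range weights of risk
#'
#' The second strategy makes a variable's weight proportional to how far its
#' values can possibly deflect: for each numeric variable the relative
#' difference between healthy boundary and plausible extreme is computed for
#' both flanks and averaged; qualitative variables take the full-deflection
#' convention (raw weight 1). The raw weights are rescaled to unit sum.
#'
#' @param schema A `crc_schema` whose numeric variables all carry extremes.
#' @return A `crc_weights` tibble with unit-sum `weight`.
#' @export
weights_deflection <- function(schema) {
  stopifnot(inherits(schema, "crc_schema"))
  new_weights(schema, deflection_raw(schema), "deflection")
}

#' Combined (final) weights of risk
#'
#' The third strategy compresses the deflection ordering into a narrow,
#' convergent band: the deflection raw weights are mapped affinely onto
#' `[0.01, 0.03]` (min to max), keeping each variable's importance rank, and
#' then rescaled to unit sum. When all deflection raws coincide the map is
#' undefined and every variable takes the band midpoint, giving uniform
#' weights.
#'
#' @param schema A `crc_schema`.
#' @return A `crc_weights` tibble with unit-sum `weight`.
#' @export
weights_combined <- function(schema) {
  stopifnot(inherits(schema, "crc_schema"))
  r <- deflection_raw(schema)
  rng <- range(r)
  raw <- if (diff(rng) < 1e-12) {
    rep(0.02, length(r))
  } else {
    0.01 + 0.02 * (r - rng[1]) / diff(rng)
  }
  new_weights(schema, stats::setNames(raw, names(r)), "combined")
}

#' Build a weight vector by scheme name
#'
#' @param schema A `crc_schema`.
#' @param scheme `"convergent"`, `"deflection"` or `"combined"`.
#' @return A `crc_weights` tibble.
#' @export
risk_weights <- function(schema, scheme = c("combined", "convergent", "deflection")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         convergent = weights_convergent(schema),
         deflection = weights_deflection(schema),
         combined = weights_combined(schema))
}
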