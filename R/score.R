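#' Percentage deviation of a value from its healthy range
#'
#' The deviation is the distance from the violated healthy boundary, relative
#' to that boundary, in percent: in-range values (boundaries inclusive) score
#' 0; above-range values score `100 * (value - healthy_hi) / healthy_hi`;
#' below-range values score `100 * (healthy_lo - value) / healthy_lo`.
#' Qualitative values are binary: 0 for benign categories, 100 otherwise.
#'
#' @param value Vector of measurements or category labels.
#' @param spec The column's [variable_spec()].
#' @return Non-negative numeric vector of percentage deviations.
#' @export
deviation_percent <- function(value, spec) {
  stopifnot(inherits(spec, "crc_variable"))
  if (spec$kind == "qualitative") {
    return(100 * label_value(value, spec))
  }
  if (!is.numeric(value) || anyNA(value)) {
    abort_format(paste0("non-numeric entry in numeric column ", spec$name))
  }
  dplyr::case_when(
    value > spec$healthy_hi ~ 100 * (value - spec$healthy_hi) / spec$healthy_hi,
    value < spec$healthy_lo ~ 100 * (spec$healthy_lo - value) / spec$healthy_lo,
    TRUE ~ 0
  )
}

#' Deviation matrix of a cohort
#'
#' @param cohort A `crc_cohort` or data frame over the schema variables.
#' @param schema Schema to measure against; defaults to the cohort's own.
#' @return A tibble: `record_id` plus one percentage-deviation column per
#'   variable; entries are 0 exactly where the label matrix is 0.
#' @export
deviation_matrix <- function(cohort, schema = NULL) {
  schema <- schema %||% attr(cohort, "schema")
  if (is.null(schema)) abort_format("deviation_matrix needs a schema")
  records <- if (inherits(cohort, "crc_cohort")) cohort_records(cohort) else tibble::as_tibble(cohort)
  ids <- if ("record_id" %in% names(cohort)) as.character(cohort$record_id) else sprintf("R%04d", seq_len(nrow(records)))
  records <- records[variable_names(schema)]
  devs <- purrr::imap(schema$variables, function(v, nm) deviation_percent(records[[nm]], v))
  dplyr::bind_cols(tibble::tibble(record_id = ids), tibble::as_tibble(devs))
}

#' Weighted raw risk score of one deviation vector
#'
#' The weighted average `sum(w_i * d_i)` of per-variable percentage
#' deviations under unit-sum weights of risk.
#'
#' @param deviations Numeric vector of percentage deviations, aligned with
#'   the weight vector.
#' @param weights A `crc_weights` tibble (or bare unit-sum numeric vector).
#' @return The raw weighted deviation percentage.
#' @export
raw_score <- function(deviations, weights) {
  w <- if (inherits(weights, "crc_weights")) weights$weight else weights
  if (length(deviations) != length(w)) {
    abort_format("deviation vector and weight vector lengths differ")
  }
  sum(w * deviations)
}

# Per-variable maximal attainable deviation (in %).
max_deviations <- function(schema) {
  vapply(schema$variables, function(v) {
    if (v$kind == "qualitative") return(100)
    max(flank_deviations(v))
  }, numeric(1))
}

#' Worst-case raw score (the normalization denominator)
#'
#' The raw score of the worst-case fictive patient, i.e. the maximum value
#' the weighted deviation percentage can take under the schema's extremes.
#' Every record's raw score is divided by this quantity so that normalized
#' scores live on 0-100.
#'
#' @param schema A `crc_schema`.
#' @param weights A `crc_weights` for the same schema.
#' @return A strictly positive percentage.
#' @export
worst_case_score <- function(schema, weights) {
  stopifnot(inherits(schema, "crc_schema"))
  raw_score(max_deviations(schema), weights)
}

#' Score a single record
#'
#' Computes the record's deviation vector, its raw weighted score, the
#' worst-case-normalized score on 0-100, and the binary diagnosis label
#' (1 when the normalized score strictly exceeds the threshold; a score at
#' exactly the threshold is labelled 0).
#'
#' @param record One-row data frame over the schema's variables.
#' @param schema A `crc_schema`.
#' @param weights A `crc_weights`.
#' @param threshold Decision threshold in percent (default 50).
#' @return A one-row tibble: `raw`, `normalized`, `label`, `scheme`,
#'   `threshold`.
#' @export
normalized_score <- function(record, schema, weights, threshold = 50) {
  devs <- deviation_matrix(record, schema)
  d <- as.numeric(devs[1, -1])
  raw <- raw_score(d, weights)
  wc <- worst_case_score(schema, weights)
  norm <- 100 * raw / wc
  tibble::tibble(raw = raw, normalized = norm,
                 label = as.integer(norm > threshold),
                 scheme = weight_scheme(weights) %||% "custom",
                 threshold = threshold)
}

#' Score every record of a cohort
#'
#' Vectorized worst-case-normalized risk scoring: the continuous `normalized`
#' column is the regression-bench response, the binary `label` column the
#' classification-bench response.
#'
#' @param cohort A `crc_cohort` (or data frame plus explicit `schema`).
#' @param weights A `crc_weights`; defaults to the combined scheme on the
#'   cohort's schema.
#' @param threshold Decision threshold in percent (default 50; scores at
#'   exactly the threshold are labelled 0).
#' @param schema Schema override.
#' @return A `crc_scores` tibble: `record_id`, `raw`, `normalized`, `label`,
#'   `scheme`.
#' @export
score_cohort <- function(cohort, weights = NULL, threshold = 50, schema = NULL) {
  schema <- schema %||% attr(cohort, "schema")
  if (is.null(schema)) abort_format("score_cohort needs a schema")
  weights <- weights %||% weights_combined(schema)
  devs <- deviation_matrix(cohort, schema)
  d <- as.matrix(devs[, -1])
  raw <- as.numeric(d %*% weights$weight)
  wc <- worst_case_score(schema, weights)
  norm <- 100 * raw / wc
  structure(
    tibble::tibble(record_id = devs$record_id, raw = raw, normalized = norm,
                   label = as.integer(norm > threshold),
                   scheme = weight_scheme(weights) %||% "custom"),
    threshold = threshold, worst_case = wc, schema = schema,
    class = c("crc_scores", class(tibble::tibble())))
}

#' Scores under all three weight schemes
#'
#' Long-format convenience used to compare the convergent, deflection and
#' combined strategies record by record (the combined score typically falls
#' between the other two).
#'
#' @inheritParams score_cohort
#' @return A tibble: `record_id`, `scheme`, `raw`, `normalized`, `label`.
#' @export
score_all_schemes <- function(cohort, threshold = 50, schema = NULL) {
  schema <- schema %||% attr(cohort, "schema")
  if (is.null(schema)) abort_format("score_all_schemes needs a schema")
  purrr::map_dfr(c("convergent", "deflection", "combined"), function(s) {
    sc <- score_cohort(cohort, risk_weights(schema, s), threshold, schema)
    dplyr::select(tibble::as_tibble(sc), "record_id", "scheme", "raw", "normalized", "label")
  })
}
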