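#' Label a single value as out-of-range
#'
#' Numeric values are labelled 1 exactly when they fall strictly outside the
#' healthy interval (the boundaries count as healthy). Qualitative values are
#' labelled 0 when the category belongs to the variable's benign set, 1
#' otherwise — for the living-environment variable urban is 1 and rural 0,
#' and for associated pathology the first category (no relevant pathology)
#' is 0.
#'
#' @param value Vector of measurements (numeric variable) or category labels
#'   (qualitative variable).
#' @param spec The [variable_spec()] of the column.
#' @return Integer vector of 0/1 labels.
#' @export
label_value <- function(value, spec) {
  stopifnot(inherits(spec, "crc_variable"))
  if (spec$kind == "numeric") {
    if (!is.numeric(value) || anyNA(value)) {
      abort_format(paste0("non-numeric entry in numeric column ", spec$name))
    }
    as.integer(value < spec$healthy_lo | value > spec$healthy_hi)
  } else {
    value <- as.character(value)
    bad <- setdiff(unique(value), spec$categories)
    if (length(bad) > 0L) {
      abort_format(paste0("unknown category '", bad[1], "' in column ", spec$name))
    }
    as.integer(!(value %in% spec$benign))
  }
}

#' Boolean label matrix of a cohort
#'
#' Applies [label_value()] element-wise to every record, producing the 0/1
#' matrix used as classifier input: one row per patient, one column per
#' variable, 1 marking a value outside its healthy range (or a non-benign
#' category). Reference rows are not part of the records and are excluded by
#' construction.
#'
#' @param cohort A `crc_cohort` (or any data frame over the schema's
#'   variables, in which case `schema` must be given).
#' @param schema Schema to label against; defaults to the cohort's own.
#' @return A `crc_labels` tibble: `record_id` plus one 0/1 integer column per
#'   variable.
#' @export
label_cohort <- function(cohort, schema = NULL) {
  schema <- schema %||% attr(cohort, "schema")
  if (is.null(schema)) abort_format("label_cohort needs a schema")
  records <- if (inherits(cohort, "crc_cohort")) cohort_records(cohort) else tibble::as_tibble(cohort)
  ids <- if ("record_id" %in% names(cohort)) as.character(cohort$record_id) else sprintf("R%04d", seq_len(nrow(records)))
  records <- records[variable_names(schema)]
  labels <- purrr::imap(schema$variables, function(v, nm) label_value(records[[nm]], v))
  out <- dplyr::bind_cols(tibble::tibble(record_id = ids), tibble::as_tibble(labels))
  structure(out, schema = schema, class = c("crc_labels", class(tibble::tibble())))
}

#' Label values without the id column
#' @param labels A `crc_labels` tibble.
#' @return Tibble of the 0/1 columns only.
#' @export
label_values <- function(labels) {
  stopifnot(inherits(labels, "crc_labels"))
  tibble::as_tibble(labels)[, setdiff(names(labels), "record_id")]
}
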