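#' Construct a cohort table
#'
#' A cohort is a tibble of patient records (one row per patient, one column
#' per schema variable) carrying its schema and the two reference rows
#' (healthy minimum and maximum per column) as attributes, mirroring the
#' spreadsheet layout in which the table's first two data rows hold the
#' healthy range of each column.
#'
#' @param records Data frame whose columns match the schema's variables in
#'   name and order.
#' @param schema A `crc_schema`.
#' @param record_ids Optional character vector of record identifiers; defaults
#'   to `R0001`, `R0002`, ...
#' @return A `crc_cohort` tibble with a `record_id` column followed by the
#'   schema variables.
#' @export
as_cohort <- function(records, schema, record_ids = NULL) {
  stopifnot(inherits(schema, "crc_schema"))
  records <- tibble::as_tibble(records)
  nms <- variable_names(schema)
  if (!identical(names(records), nms)) {
    if (!setequal(names(records), nms)) {
      abort_format(paste0("record columns do not match schema variables; expected ",
                          length(nms), " columns"))
    }
    records <- records[nms]
  }
  n <- nrow(records)
  if (is.null(record_ids)) record_ids <- sprintf("R%04d", seq_len(n))
  if (length(record_ids) != n) abort_format("record_ids length must match record count")
  validate_records(records, schema)
  out <- dplyr::bind_cols(tibble::tibble(record_id = as.character(record_ids)), records)
  structure(out,
            schema = schema,
            reference = reference_rows(schema),
            class = c("crc_cohort", class(tibble::tibble())))
}

# The two reference rows implied by a schema (qualitative columns are empty).
reference_rows <- function(schema) {
  vals <- lapply(schema$variables, function(v) {
    if (v$kind == "numeric") c(v$healthy_lo, v$healthy_hi) else c(NA, NA)
  })
  tibble::as_tibble(vals)
}

validate_records <- function(records, schema) {
  for (v in schema$variables) {
    col <- records[[v$name]]
    if (v$kind == "numeric") {
      if (!is.numeric(col)) abort_format(paste0("non-numeric entry in numeric column ", v$name))
      if (anyNA(col)) abort_format(paste0("missing value in numeric column ", v$name))
    } else {
      bad <- setdiff(unique(as.character(col)), v$categories)
      if (length(bad) > 0L) {
        abort_format(paste0("unknown category '", bad[1], "' in column ", v$name))
      }
    }
  }
  invisible(records)
}

#' Extract the record values of a cohort (without the id column)
#'
#' @param cohort A `crc_cohort`.
#' @return A tibble of the 45 variable columns.
#' @export
cohort_records <- function(cohort) {
  stopifnot(inherits(cohort, "crc_cohort"))
  tibble::as_tibble(cohort)[, setdiff(names(cohort), "record_id")]
}

#' Schema attached to a cohort
#' @param cohort A `crc_cohort`.
#' @return The `crc_schema` the cohort was built against.
#' @export
cohort_schema_of <- function(cohort) {
  sch <- attr(cohort, "schema")
  if (is.null(sch)) abort_format("cohort carries no schema attribute")
  sch
}

#' Read a cohort file
#'
#' The file dialect is comma-separated UTF-8: a header row of variable names,
#' then the healthy-minimum row, then the healthy-maximum row, then one row
#' per patient. The two reference rows must agree with the schema's healthy
#' bounds for every numeric column; qualitative cells in the reference rows
#' are empty.
#'
#' @param path Path to a cohort CSV.
#' @param schema `crc_schema` the file must conform to.
#' @return A `crc_cohort` (reference rows are consumed into attributes, the
#'   remaining rows become patient records).
#' @export
read_cohort <- function(path, schema) {
  stopifnot(inherits(schema, "crc_schema"))
  if (!file.exists(path)) abort_format(paste0("cohort file not found: ", path))
  nms <- variable_names(schema)
  num <- numeric_mask(schema)
  # read everything as text and convert numerics with base R's exact parser,
  # so that written files round-trip bit-for-bit
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  if (ncol(tab) != length(nms)) {
    abort_format(paste0("cohort file has ", ncol(tab), " columns; expected ", length(nms)))
  }
  if (!identical(names(tab), nms)) {
    abort_format("cohort file header does not match the schema's variable names")
  }
  for (nm in nms[num]) {
    parsed <- suppressWarnings(as.numeric(tab[[nm]]))
    if (anyNA(parsed) && !all(is.na(tab[[nm]][is.na(parsed)]))) {
      abort_format(paste0("non-numeric entry in numeric column ", nm))
    }
    tab[[nm]] <- parsed
  }
  if (nrow(tab) < 2L) abort_format("cohort file must contain the two reference rows")
  ref <- tab[1:2, ]
  for (v in schema$variables[num]) {
    got <- ref[[v$name]]
    want <- c(v$healthy_lo, v$healthy_hi)
    if (anyNA(got) || max(abs(got - want)) > 1e-6 * max(1, abs(want))) {
      abort_format(paste0("reference rows do not match the schema's healthy range for ", v$name))
    }
  }
  as_cohort(tab[-(1:2), ], schema)
}

#' Write a cohort file
#'
#' Emits the CSV dialect read by [read_cohort()]: header, two reference rows,
#' then the patient records. Writing is deterministic, so
#' `write(read(write(x)))` is byte-identical, and numeric values round-trip
#' at printed precision.
#'
#' @param cohort A `crc_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "crc_cohort"))
  schema <- cohort_schema_of(cohort)
  ref <- reference_rows(schema)
  body <- cohort_records(cohort)
  out <- dplyr::bind_rows(ref, body)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
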