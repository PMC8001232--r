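#' Declare one clinical variable
#'
#' A variable spec carries everything the scoring method needs to know about a
#' single column of the cohort table: for numeric analytes, the healthy
#' (reference) interval and the plausible extreme bounds that delimit how far
#' a result can deviate; for qualitative variables, the ordered category set
#' and the subset of categories considered benign (label 0).
#'
#' Invariants enforced: `extreme_lo <= healthy_lo < healthy_hi <= extreme_hi`
#' for numeric variables, with strictly positive healthy boundaries wherever a
#' deviation can occur on that side (the deviation formula divides by the
#' violated healthy boundary); qualitative variables need a non-empty category
#' set, at least one benign and at least one non-benign category.
#'
#' @param name Variable name (unique within a schema).
#' @param kind `"numeric"` or `"qualitative"`.
#' @param healthy_lo,healthy_hi Healthy reference interval (numeric only).
#' @param extreme_lo,extreme_hi Smallest/largest plausible values (numeric only).
#' @param categories Ordered character vector of category labels (qualitative).
#' @param benign Character vector: categories labelled 0 (qualitative).
#' @param unit Optional measurement unit, informational.
#' @return A `crc_variable` list.
#' @export
variable_spec <- function(name, kind = c("numeric", "qualitative"),
                          healthy_lo = NULL, healthy_hi = NULL,
                          extreme_lo = NULL, extreme_hi = NULL,
                          categories = NULL, benign = NULL, unit = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_schema("variable name must be a non-empty string")
  }
  kind <- match.arg(kind)
  spec <- structure(
    list(name = name, kind = kind,
         healthy_lo = healthy_lo, healthy_hi = healthy_hi,
         extreme_lo = extreme_lo, extreme_hi = extreme_hi,
         categories = categories, benign = benign, unit = unit),
    class = "crc_variable")
  validate_variable(spec)
  spec
}

validate_variable <- function(spec) {
  nm <- spec$name
  if (spec$kind == "numeric") {
    for (f in c("healthy_lo", "healthy_hi", "extreme_lo", "extreme_hi")) {
      if (!is_scalar_number(spec[[f]])) {
        abort_schema(paste0("numeric variable must supply finite ", f), nm)
      }
    }
    if (!(spec$extreme_lo <= spec$healthy_lo)) {
      abort_schema("extreme_lo must not exceed healthy_lo", nm)
    }
    if (!(spec$healthy_lo < spec$healthy_hi)) {
      abort_schema("healthy interval inverted (healthy_lo >= healthy_hi)", nm)
    }
    if (!(spec$healthy_hi <= spec$extreme_hi)) {
      abort_schema("extreme_hi must not fall below healthy_hi", nm)
    }
    if (spec$extreme_lo < spec$healthy_lo && spec$healthy_lo <= 0) {
      abort_schema("healthy_lo must be > 0 when deviation below the range is possible", nm)
    }
    if (spec$extreme_hi > spec$healthy_hi && spec$healthy_hi <= 0) {
      abort_schema("healthy_hi must be > 0 when deviation above the range is possible", nm)
    }
  } else {
    if (!is.character(spec$categories) || length(spec$categories) == 0L ||
        anyDuplicated(spec$categories) > 0L) {
      abort_schema("qualitative variable needs a non-empty set of unique categories", nm)
    }
    if (!is.character(spec$benign) || length(spec$benign) == 0L) {
      abort_schema("qualitative variable needs at least one benign category", nm)
    }
    if (!all(spec$benign %in% spec$categories)) {
      abort_schema("benign categories must be a subset of categories", nm)
    }
    if (length(setdiff(spec$categories, spec$benign)) == 0L) {
      abort_schema("qualitative variable needs at least one non-benign category", nm)
    }
  }
  invisible(spec)
}

#' Assemble a cohort schema from variable specs
#'
#' @param variables List of [variable_spec()] objects, numeric variables first
#'   by convention. Names must be unique.
#' @param check_count Optional integer: error unless the schema has exactly
#'   this many variables. [load_schema()] uses 45, the layout of the cohort
#'   table (33 blood/urine analytes followed by 12 qualitative variables).
#' @return A `crc_schema` object.
#' @export
cohort_schema <- function(variables, check_count = NULL) {
  if (!is.list(variables) || length(variables) == 0L) {
    abort_schema("a schema needs at least one variable")
  }
  variables <- lapply(variables, function(v) {
    if (!inherits(v, "crc_variable")) abort_schema("variables must be variable_spec() objects")
    validate_variable(v)
    v
  })
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms) > 0L) {
    abort_schema(paste0("duplicate variable name: ", nms[duplicated(nms)][1]))
  }
  names(variables) <- nms
  if (!is.null(check_count) && length(variables) != check_count) {
    abort_schema(paste0("schema has ", length(variables),
                        " variables; expected ", check_count))
  }
  structure(list(variables = variables), class = "crc_schema")
}

#' Read a schema from a YAML config
#'
#' The config has one block per variable under a top-level `variables:` key;
#' numeric blocks supply `healthy: [lo, hi]` and `extreme: [lo, hi]`,
#' qualitative blocks supply `categories:` and `benign:`. All variable-spec
#' invariants are enforced, and errors name the offending variable.
#'
#' @param path Path to a YAML schema config.
#' @param n_expected Required variable count (default 45, the cohort layout).
#'   Use `NULL` to skip the count check.
#' @return A validated `crc_schema`.
#' @export
load_schema <- function(path, n_expected = 45L) {
  if (!file.exists(path)) abort_schema(paste0("schema file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variables)) abort_schema("schema config lacks a 'variables' block")
  vars <- lapply(raw$variables, function(v) {
    nm <- v$name %||% "<unnamed>"
    kind <- v$kind %||% abort_schema("missing kind", nm)
    if (!kind %in% c("numeric", "qualitative")) {
      abort_schema(paste0("unknown kind '", kind, "'"), nm)
    }
    if (kind == "numeric") {
      if (length(v$healthy) != 2L || length(v$extreme) != 2L) {
        abort_schema("numeric variable must supply healthy: [lo, hi] and extreme: [lo, hi]", nm)
      }
      variable_spec(nm, "numeric",
                    healthy_lo = as.numeric(v$healthy[[1]]),
                    healthy_hi = as.numeric(v$healthy[[2]]),
                    extreme_lo = as.numeric(v$extreme[[1]]),
                    extreme_hi = as.numeric(v$extreme[[2]]),
                    unit = v$unit)
    } else {
      variable_spec(nm, "qualitative",
                    categories = as.character(unlist(v$categories)),
                    benign = as.character(unlist(v$benign)),
                    unit = v$unit)
    }
  })
  cohort_schema(vars, check_count = n_expected)
}

#' Default 45-variable colorectal-cohort schema
#'
#' Loads the bundled schema: 33 blood/urine analytes with standard adult
#' reference intervals and explicit plausible extremes, followed by 12
#' qualitative variables (living environment, tumor position, T/N/M and Dukes
#' staging, associated pathology, technical approach, complications,
#' incidents, ultrasonography dimensions and localization). The reference
#' intervals are documented stand-ins: they are parameters of the method, not
#' results, and any of them can be overridden by editing a copy of the config
#' and calling [load_schema()].
#'
#' @return A `crc_schema` with 45 variables.
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "crc_schema.yaml", package = "crcrisk"))
}

#' @export
print.crc_schema <- function(x, ...) {
  tab <- schema_table(x)
  cat("<crc_schema> ", nrow(tab), " variables (",
      sum(tab$kind == "numeric"), " numeric, ",
      sum(tab$kind == "qualitative"), " qualitative)\n", sep = "")
  print(tab, n = 10)
  invisible(x)
}

#' Tabular view of a schema
#'
#' @param schema A `crc_schema`.
#' @return A tibble with one row per variable: name, kind, healthy and extreme
#'   bounds (NA for qualitative), category counts.
#' @export
schema_table <- function(schema) {
  stopifnot(inherits(schema, "crc_schema"))
  purrr::map_dfr(schema$variables, function(v) {
    tibble::tibble(
      name = v$name, kind = v$kind,
      healthy_lo = v$healthy_lo %||% NA_real_,
      healthy_hi = v$healthy_hi %||% NA_real_,
      extreme_lo = v$extreme_lo %||% NA_real_,
      extreme_hi = v$extreme_hi %||% NA_real_,
      n_categories = if (is.null(v$categories)) NA_integer_ else length(v$categories),
      n_benign = if (is.null(v$benign)) NA_integer_ else length(v$benign))
  })
}

variable_names <- function(schema) names(schema$variables)

numeric_mask <- function(schema) {
  vapply(schema$variables, function(v) v$kind == "numeric", logical(1))
}

n_variables <- function(schema) length(schema$variables)
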