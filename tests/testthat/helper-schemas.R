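# Toy schema builders used across tests.

# k numeric variables with supplied bounds; bounds is a list of
# c(extreme_lo, healthy_lo, healthy_hi, extreme_hi).
toy_numeric_schema <- function(bounds, names = NULL) {
  names <- names %||% paste0("v", seq_along(bounds))
  vars <- purrr::map2(bounds, names, function(b, nm) {
    variable_spec(nm, "numeric", healthy_lo = b[2], healthy_hi = b[3],
                  extreme_lo = b[1], extreme_hi = b[4])
  })
  cohort_schema(vars)
}

toy_qualitative_var <- function(name = "q1") {
  variable_spec(name, "qualitative",
                categories = c("good", "bad", "worse"), benign = "good")
}

# A small mixed schema: 3 numeric + 1 qualitative.
toy_mixed_schema <- function() {
  cohort_schema(list(
    variable_spec("a", "numeric", healthy_lo = 3.5, healthy_hi = 5, extreme_lo = 0, extreme_hi = 15),
    variable_spec("b", "numeric", healthy_lo = 10, healthy_hi = 20, extreme_lo = 5, extreme_hi = 60),
    variable_spec("c", "numeric", healthy_lo = 100, healthy_hi = 140, extreme_lo = 50, extreme_hi = 300),
    toy_qualitative_var("q1")))
}

# Random numeric toy schema with n_vars variables (seeded by caller).
random_toy_schema <- function(n_vars = 5) {
  bounds <- purrr::map(seq_len(n_vars), function(i) {
    lo <- runif(1, 1, 10)
    hi <- lo + runif(1, 0.5, 10)
    c(max(0.1, lo - runif(1, 0.5, 5)), lo, hi, hi + runif(1, 0.5, 30))
  })
  toy_numeric_schema(bounds)
}

# Random records respecting a numeric toy schema's extremes.
random_records <- function(schema, n) {
  cols <- purrr::map(schema$variables, function(v) {
    if (v$kind == "qualitative") sample(v$categories, n, replace = TRUE)
    else runif(n, v$extreme_lo, v$extreme_hi)
  })
  tibble::as_tibble(cols)
}

`%||%` <- rlang::`%||%`
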