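#' Configure the synthetic-cohort generator
#'
#' The generator emulates the structure of an augmented surgical cohort: a
#' base set of patients sampled from a case/control mixture, expanded to a
#' larger table by resampling-with-replacement plus per-variable jitter. Its
#' defaults encode the study conditions the analysis assumes: 200 base
#' patients augmented to 900 records and a positive-label prevalence near
#' 0.649 (584 positives in 900, the prevalence back-solvable from the pooled
#' confusion counts of the classification bench).
#'
#' Per record, the fraction of out-of-range variables ("abnormality burden")
#' is Beta-distributed with a case/control separation chosen so that the
#' marginal expected out-of-range fraction equals `abnormality_burden`.
#' Out-of-range numeric draws traverse a fraction of the flank between the
#' violated healthy boundary and the plausible extreme; that fraction follows
#' a truncated-exponential law decaying away from the healthy boundary for
#' control-like records (mild abnormalities dominate) and away from the
#' extreme for case-like records (severe, characteristic-direction
#' abnormalities dominate, toward the larger-deviation flank with probability
#' `case_side_bias`).
#'
#' @param n_base Base patient count before augmentation (default 200).
#' @param n_total Total records after augmentation (default 900).
#' @param abnormality_burden Marginal expected fraction of out-of-range
#'   variables per record, in `[0, 1]` (default 0.65).
#' @param positive_prevalence_target Fraction of case-like records
#'   (default 0.649).
#' @param jitter_fraction Augmentation noise scale as a fraction of each
#'   variable's healthy-range width (default 0.02).
#' @param burden_separation Case/control separation of the per-record burden
#'   means, in `[0, 1]`; scaled down automatically near degenerate burdens so
#'   the marginal burden is always honoured (default 0.8).
#' @param burden_concentration Beta concentration of per-record burdens
#'   (default 25).
#' @param severity_rate Truncated-exponential decay rate of the flank
#'   fraction; `Inf` collapses case draws onto the extremes (default 7).
#' @param case_side_bias Probability that a case-like out-of-range draw
#'   deviates toward the larger-deviation flank (default 0.95).
#' @param seed Integer seed; identical (schema, config) reproduce identical
#'   cohorts.
#' @return A `crc_generator_config` list.
#' @export
generator_config <- function(n_base = 200L, n_total = 900L,
                             abnormality_burden = 0.65,
                             positive_prevalence_target = 0.649,
                             jitter_fraction = 0.02,
                             burden_separation = 0.8,
                             burden_concentration = 25,
                             severity_rate = 7,
                             case_side_bias = 0.95,
                             seed = 1L) {
  stopifnot(n_base >= 1, n_total >= n_base)
  for (f in c(abnormality_burden, positive_prevalence_target, jitter_fraction,
              burden_separation, case_side_bias)) {
    if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1) {
      abort("generator fractions must lie in [0, 1]", class = "crcrisk_config_error")
    }
  }
  stopifnot(burden_concentration > 0, severity_rate > 0)
  structure(list(n_base = as.integer(n_base), n_total = as.integer(n_total),
                 abnormality_burden = abnormality_burden,
                 positive_prevalence_target = positive_prevalence_target,
                 jitter_fraction = jitter_fraction,
                 burden_separation = burden_separation,
                 burden_concentration = burden_concentration,
                 severity_rate = severity_rate,
                 case_side_bias = case_side_bias,
                 seed = as.integer(seed)),
            class = "crc_generator_config")
}

# Per-record burden means (case, control) honouring the marginal burden.
burden_means <- function(config) {
  u <- config$abnormality_burden
  p <- config$positive_prevalence_target
  s <- config$burden_separation
  if (u <= 0 || u >= 1 || p <= 0 || p >= 1) return(c(case = u, control = u))
  s_eff <- s * min(1, u * (1 - p) / (p * (1 - u)))
  m1 <- u + s_eff * (1 - u)
  m0 <- u - s_eff * p * (1 - u) / (1 - p)
  c(case = m1, control = m0)
}

rbeta_mean <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

# Relative deviations of the two flanks of a numeric variable (in %).
# A zero-width flank cannot be violated and contributes 0.
flank_deviations <- function(v) {
  c(lo = if (v$healthy_lo > v$extreme_lo) 100 * (v$healthy_lo - v$extreme_lo) / v$healthy_lo else 0,
    hi = if (v$extreme_hi > v$healthy_hi) 100 * (v$extreme_hi - v$healthy_hi) / v$healthy_hi else 0)
}

#' Sample a base synthetic cohort
#'
#' Draws `n_base` records against a schema. In-range numeric values follow a
#' truncated bell curve over the healthy interval (mean at the midpoint, sd a
#' sixth of the width); out-of-range values land in a flanking interval as
#' described in [generator_config()]. Qualitative values are benign with
#' probability one minus the record's burden, otherwise uniform over the
#' non-benign categories.
#'
#' @param schema A `crc_schema`.
#' @param config A [generator_config()].
#' @return A seeded, reproducible `crc_cohort` with `n_base` records.
#' @export
sample_base_cohort <- function(schema, config = generator_config()) {
  stopifnot(inherits(schema, "crc_schema"), inherits(config, "crc_generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n_base
    # Fixed cohort composition (a clinical dataset has a set number of
    # positives): exactly round(prevalence * n) case-like records, shuffled.
    n_case <- round(config$positive_prevalence_target * n)
    is_case <- sample(rep(c(TRUE, FALSE), c(n_case, n - n_case)))
    m <- burden_means(config)
    burden <- numeric(n)
    burden[is_case] <- rbeta_mean(sum(is_case), m[["case"]], config$burden_concentration)
    burden[!is_case] <- rbeta_mean(sum(!is_case), m[["control"]], config$burden_concentration)

    cols <- lapply(schema$variables, function(v) {
      oor <- stats::runif(n) < burden
      if (v$kind == "qualitative") {
        non_benign <- setdiff(v$categories, v$benign)
        val <- character(n)
        val[!oor] <- sample(v$benign, sum(!oor), replace = TRUE)
        val[oor] <- sample(non_benign, sum(oor), replace = TRUE)
        return(val)
      }
      mid <- (v$healthy_lo + v$healthy_hi) / 2
      width <- v$healthy_hi - v$healthy_lo
      val <- rtruncnorm(n, mid, width / 6, v$healthy_lo, v$healthy_hi)
      k <- sum(oor)
      if (k > 0L) {
        dev <- flank_deviations(v)
        feasible <- c(dev[["lo"]] > 0, dev[["hi"]] > 0)
        if (any(feasible)) {
          big_is_hi <- dev[["hi"]] >= dev[["lo"]]
          p_big <- ifelse(is_case[oor], config$case_side_bias, 0.5)
          take_big <- stats::runif(k) < p_big
          side_hi <- ifelse(take_big, big_is_hi, !big_is_hi)
          side_hi[!feasible[2]] <- FALSE  # a zero-width flank cannot be violated
          side_hi[!feasible[1]] <- TRUE
          h <- rtruncexp01(k, config$severity_rate)
          g <- ifelse(is_case[oor], 1 - h, h)
          hi_w <- v$extreme_hi - v$healthy_hi
          lo_w <- v$healthy_lo - v$extreme_lo
          val[oor] <- ifelse(side_hi,
                             v$healthy_hi + g * hi_w,
                             v$healthy_lo - g * lo_w)
        }
      }
      val
    })
    as_cohort(tibble::as_tibble(cols), schema,
              record_ids = sprintf("B%04d", seq_len(n)))
  })
}

#' Augment a cohort by jittered resampling
#'
#' Expands a base cohort to `n_total` records: the base records are kept, and
#' the remainder are resampled with replacement and perturbed by zero-mean
#' Gaussian noise with per-variable scale `jitter_fraction` times the healthy
#' range width, clipped to the plausible extremes. Qualitative values are
#' copied unchanged.
#'
#' @param base A `crc_cohort` with at least one record.
#' @param config A [generator_config()]; `n_total` must be at least the base
#'   size.
#' @return A `crc_cohort` with exactly `n_total` records.
#' @export
augment_cohort <- function(base, config = generator_config()) {
  stopifnot(inherits(base, "crc_cohort"), inherits(config, "crc_generator_config"))
  schema <- cohort_schema_of(base)
  n0 <- nrow(base)
  if (config$n_total < n0) {
    abort("n_total is smaller than the base cohort", class = "crcrisk_config_error")
  }
  n_extra <- config$n_total - n0
  if (n_extra == 0L) return(base)
  records <- cohort_records(base)
  withr::with_seed(config$seed + 1L, {
    idx <- sample.int(n0, n_extra, replace = TRUE)
    extra <- records[idx, ]
    for (v in schema$variables) {
      if (v$kind != "numeric") next
      width <- v$healthy_hi - v$healthy_lo
      noise <- stats::rnorm(n_extra, 0, config$jitter_fraction * width)
      extra[[v$name]] <- pmin(pmax(extra[[v$name]] + noise, v$extreme_lo), v$extreme_hi)
    }
    ids <- c(base$record_id, sprintf("A%04d", seq_len(n_extra)))
    as_cohort(dplyr::bind_rows(records, extra), schema, record_ids = ids)
  })
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: [sample_base_cohort()] then [augment_cohort()].
#'
#' @inheritParams sample_base_cohort
#' @return A `crc_cohort` with `config$n_total` records.
#' @export
generate_cohort <- function(schema = default_schema(), config = generator_config()) {
  augment_cohort(sample_base_cohort(schema, config), config)
}

#' The all-healthy reference patient
#'
#' A synthetic record with every numeric value at its healthy-interval
#' midpoint and every qualitative value at a benign category: all its labels
#' are 0 and its normalized risk score is 0 under any weight scheme.
#'
#' @param schema A `crc_schema`.
#' @return A one-row tibble over the schema's variables.
#' @export
make_healthy_patient <- function(schema) {
  stopifnot(inherits(schema, "crc_schema"))
  vals <- lapply(schema$variables, function(v) {
    if (v$kind == "numeric") (v$healthy_lo + v$healthy_hi) / 2 else v$benign[[1]]
  })
  tibble::as_tibble(vals)
}

#' The worst-case fictive patient
#'
#' A synthetic record in which every variable attains its maximal possible
#' deviation: each numeric value sits at the extreme bound whose relative
#' deviation from the healthy range is larger (ties go to the upper extreme),
#' and each qualitative value is non-benign. Its raw score defines the
#' normalization denominator, so its normalized score is 100 under every
#' weight scheme.
#'
#' @param schema A `crc_schema`.
#' @return A one-row tibble over the schema's variables.
#' @export
make_worst_case_patient <- function(schema) {
  stopifnot(inherits(schema, "crc_schema"))
  vals <- lapply(schema$variables, function(v) {
    if (v$kind == "qualitative") return(setdiff(v$categories, v$benign)[[1]])
    dev <- flank_deviations(v)
    if (dev[["hi"]] >= dev[["lo"]]) v$extreme_hi else v$extreme_lo
  })
  tibble::as_tibble(vals)
}
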