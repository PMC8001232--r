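test_that("generation is deterministic in (schema, config, seed) and shaped right", {
  sch <- default_schema()
  cfg <- generator_config(n_base = 30, n_total = 75, seed = 21)
  a <- generate_cohort(sch, cfg)
  b <- generate_cohort(sch, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 75)
  expect_equal(ncol(a) - 1L, 45)  # record_id + 45 variables
  c2 <- generate_cohort(sch, generator_config(n_base = 30, n_total = 75, seed = 22))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("the abnormality burden is honoured marginally and at its degenerate ends", {
  sch <- default_schema()
  big <- sample_base_cohort(sch, generator_config(n_base = 10000, n_total = 10000, seed = 42))
  oor <- mean(as.matrix(label_values(label_cohort(big))))
  expect_lt(abs(oor - 0.65), 0.02)

  none <- sample_base_cohort(sch, generator_config(n_base = 60, n_total = 60,
                                                   abnormality_burden = 0, seed = 3))
  expect_equal(sum(as.matrix(label_values(label_cohort(none)))), 0)

  # full burden with all flank mass at the extremes puts every numeric value
  # on an extreme bound
  all_extreme <- sample_base_cohort(
    sch, generator_config(n_base = 60, n_total = 60, abnormality_burden = 1,
                          positive_prevalence_target = 1, severity_rate = Inf, seed = 3))
  rec <- cohort_records(all_extreme)
  for (v in sch$variables) {
    if (v$kind != "numeric") next
    d <- pmin(abs(rec[[v$name]] - v$extreme_lo), abs(rec[[v$name]] - v$extreme_hi))
    expect_lt(max(d), 1e-8 * max(abs(v$extreme_lo), abs(v$extreme_hi)))
  }
})

test_that("augmentation expands the base cohort with jittered, clipped copies", {
  sch <- default_schema()
  cfg <- generator_config(n_base = 200, n_total = 900, seed = 5)
  base <- sample_base_cohort(sch, cfg)
  full <- augment_cohort(base, cfg)
  expect_equal(nrow(full), 900)
  expect_identical(as.data.frame(full[1:200, ]), as.data.frame(base))

  # zero jitter makes the 700 extra records exact copies of base records
  cfg0 <- generator_config(n_base = 200, n_total = 900, jitter_fraction = 0, seed = 5)
  full0 <- augment_cohort(sample_base_cohort(sch, cfg0), cfg0)
  extra <- cohort_records(full0)[201:900, ]
  base_rec <- cohort_records(full0)[1:200, ]
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  expect_true(all(key(extra) %in% key(base_rec)))

  expect_error(augment_cohort(base, generator_config(n_base = 200, n_total = 100)),
               "n_total")
})

test_that("augmented values stay inside the plausible extremes across seeds", {
  sch <- toy_mixed_schema()
  for (s in 1:100) {
    cfg <- generator_config(n_base = 10, n_total = 25, jitter_fraction = 0.3, seed = s)
    rec <- cohort_records(generate_cohort(sch, cfg))
    for (v in sch$variables) {
      if (v$kind != "numeric") next
      expect_true(all(rec[[v$name]] >= v$extreme_lo & rec[[v$name]] <= v$extreme_hi))
    }
  }
})

test_that("the all-healthy reference patient sits at midpoints with zero labels and score", {
  sch <- default_schema()
  h <- make_healthy_patient(sch)
  for (v in sch$variables) {
    if (v$kind == "numeric") {
      expect_equal(h[[v$name]], (v$healthy_lo + v$healthy_hi) / 2)
    } else {
      expect_true(h[[v$name]] %in% v$benign)
    }
  }
  expect_equal(sum(as.matrix(label_values(label_cohort(h, sch)))), 0)
  expect_equal(normalized_score(h, sch, weights_combined(sch))$normalized, 0)
})

test_that("the worst-case fictive patient attains every variable's maximal deviation", {
  # healthy [3.5, 5], extremes [0, 15]: upper deviation 200% beats lower 100%
  sch <- toy_numeric_schema(list(c(0, 3.5, 5, 15)))
  w <- make_worst_case_patient(sch)
  expect_equal(w$v1, 15)

  sch45 <- default_schema()
  w45 <- make_worst_case_patient(sch45)
  devs <- as.numeric(deviation_matrix(w45, sch45)[1, -1])
  maxes <- crcrisk:::max_deviations(sch45)
  expect_equal(devs, unname(maxes))
  expect_equal(sum(as.matrix(label_values(label_cohort(w45, sch45)))), 45)
})
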