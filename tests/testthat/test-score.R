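test_that("deviation percentages measure distance from the violated healthy boundary", {
  spec <- variable_spec("x", "numeric", healthy_lo = 3.5, healthy_hi = 5,
                        extreme_lo = 0, extreme_hi = 15)
  expect_equal(deviation_percent(4.2, spec), 0)
  expect_equal(deviation_percent(7.5, spec), 50)   # 100 * (7.5 - 5) / 5
  expect_equal(deviation_percent(1.75, spec), 50)  # 100 * (3.5 - 1.75) / 3.5
  expect_equal(deviation_percent(c(3.5, 5), spec), c(0, 0))  # boundaries healthy
  q <- toy_qualitative_var()
  expect_equal(deviation_percent(c("good", "bad"), q), c(0, 100))
})

test_that("raw and worst-case scores are the documented weighted averages", {
  expect_equal(raw_score(c(50, 0), c(0.6, 0.4)), 30)
  expect_equal(raw_score(rep(7.3, 5), rep(0.2, 5)), 7.3)  # unit-sum, constant
  expect_error(raw_score(c(1, 2), c(0.5, 0.3, 0.2)), "lengths")

  # two variables with maximal deviations 200% and 100%, uniform weights -> 150
  sch <- toy_numeric_schema(list(c(5, 5, 10, 30), c(5, 5, 10, 20)))
  expect_equal(worst_case_score(sch, weights_convergent(sch)), 150)

  # qualitative-only schema: every maximal deviation is 100
  schq <- cohort_schema(list(toy_qualitative_var("q1"), toy_qualitative_var("q2")))
  expect_equal(worst_case_score(schq, weights_convergent(schq)), 100)

  # worst-case dominates any valid record (property, random schemas/records)
  set.seed(77)
  for (i in 1:10) {
    s <- random_toy_schema(5)
    w <- risk_weights(s, sample(c("convergent", "deflection", "combined"), 1))
    wc <- worst_case_score(s, w)
    recs <- random_records(s, 20)
    raws <- as.matrix(deviation_matrix(recs, s)[, -1]) %*% w$weight
    expect_true(all(raws <= wc + 1e-9))
  }
})

test_that("normalized scores pin the healthy patient at 0 and the worst case at 100", {
  sch <- default_schema()
  h <- make_healthy_patient(sch)
  w <- make_worst_case_patient(sch)
  for (s in c("convergent", "deflection", "combined")) {
    wt <- risk_weights(sch, s)
    expect_equal(normalized_score(h, sch, wt)$normalized, 0)
    expect_equal(normalized_score(w, sch, wt)$normalized, 100)
    expect_equal(normalized_score(w, sch, wt)$label, 1L)
  }
})

test_that("a score exactly at the threshold is labelled healthy", {
  sch <- toy_numeric_schema(list(c(10, 10, 20, 40)))  # max deviation 100%
  rec <- tibble::tibble(v1 = 30)                      # deviation 50%
  out <- normalized_score(rec, sch, weights_convergent(sch))
  expect_equal(out$normalized, 50)
  expect_equal(out$label, 0L)
  out2 <- normalized_score(tibble::tibble(v1 = 30.2), sch, weights_convergent(sch))
  expect_equal(out2$label, 1L)
})

test_that("scores are bounded, monotone in deviations, and scheme-invariant on degenerate schemas", {
  set.seed(99)
  sch <- random_toy_schema(5)
  w <- weights_combined(sch)
  recs <- random_records(sch, 50)
  sc <- score_cohort(recs, w, schema = sch)
  expect_true(all(sc$normalized >= 0 & sc$normalized <= 100))

  # raising one variable's deviation cannot lower the score
  r <- recs[1, ]
  v <- sch$variables[[1]]
  r_out <- r
  r_out$v1 <- v$extreme_hi
  s_in <- score_cohort(r, w, schema = sch)$normalized
  s_out <- score_cohort(r_out, w, schema = sch)$normalized
  expect_gte(s_out, s_in)

  # identical ranges for all variables: the three schemes agree everywhere
  sch_eq <- toy_numeric_schema(rep(list(c(1, 2, 4, 9)), 4))
  recs_eq <- random_records(sch_eq, 30)
  s1 <- score_cohort(recs_eq, weights_convergent(sch_eq), schema = sch_eq)$normalized
  s2 <- score_cohort(recs_eq, weights_deflection(sch_eq), schema = sch_eq)$normalized
  s3 <- score_cohort(recs_eq, weights_combined(sch_eq), schema = sch_eq)$normalized
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
})

test_that("scores agree with a brute-force recomputation on random toy schemas", {
  set.seed(123)
  for (i in 1:8) {
    sch <- random_toy_schema(5)
    recs <- random_records(sch, 25)
    for (scheme in c("convergent", "deflection", "combined")) {
      got <- score_cohort(recs, risk_weights(sch, scheme), schema = sch)$normalized
      want <- brute_force_scores(sch, recs, scheme)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("the combined scheme mostly scores between the other two strategies", {
  sch <- default_schema()
  co <- generate_cohort(sch, generator_config(seed = 31))
  long <- score_all_schemes(co)
  wide <- tidyr::pivot_wider(long[, c("record_id", "scheme", "normalized")],
                             names_from = "scheme", values_from = "normalized")
  between <- wide$combined >= pmin(wide$convergent, wide$deflection) - 1e-9 &
    wide$combined <= pmax(wide$convergent, wide$deflection) + 1e-9
  expect_gte(mean(between), 0.9)
})

test_that("the default synthetic cohort hits the target positive prevalence", {
  sch <- default_schema()
  co <- generate_cohort(sch, generator_config(seed = 1))
  sc <- score_cohort(co)
  expect_equal(nrow(sc), 900)
  expect_lt(abs(mean(sc$label) - 0.649), 0.05)
})
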