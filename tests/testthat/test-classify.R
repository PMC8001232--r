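test_that("confusion counts match a hand cross-tabulation", {
  expect_equal(as.numeric(confusion(rep(1, 5), rep(1, 5))[1, ]), c(5, 0, 0, 0))
  expect_equal(as.numeric(confusion(rep(0, 7), rep(1, 7))[1, ]), c(0, 7, 0, 0))
  set.seed(55)
  for (i in 1:5) {
    pred <- rbinom(10, 1, 0.5); truth <- rbinom(10, 1, 0.5)
    cm <- confusion(pred, truth)
    # brute-force count
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (j in 1:10) {
      if (truth[j] == 1 && pred[j] == 1) tp <- tp + 1
      if (truth[j] == 1 && pred[j] == 0) fn <- fn + 1
      if (truth[j] == 0 && pred[j] == 0) tn <- tn + 1
      if (truth[j] == 0 && pred[j] == 1) fp <- fp + 1
    }
    expect_equal(as.numeric(cm[1, ]), c(tp, fn, tn, fp))
  }
  expect_error(confusion(1:3, 1:4), "lengths")
})

test_that("metric arithmetic reproduces the published 5-fold logistic-regression row", {
  cm <- tibble::tibble(tp = 525, fn = 59, tn = 115, fp = 201)
  m <- metrics(cm, denominator_total = 900, denominator_kind = "whole_dataset")
  trunc2 <- function(x) trunc(x * 100) / 100
  expect_equal(round(m$accuracy, 1), 71.1)
  expect_equal(trunc2(m$sensitivity), 89.89)  # 525/584 = 89.897..., truncated in print
  expect_equal(round(m$specificity, 2), 36.39)
  expect_equal(round(m$precision, 2), 72.31)
  expect_equal(trunc2(m$pct_false_negatives), 6.55)
})

test_that("metric arithmetic reproduces the published 5%-holdout linear-discriminant row", {
  cm <- tibble::tibble(tp = 29, fn = 0, tn = 6, fp = 10)
  m <- metrics(cm, denominator_total = 45, denominator_kind = "validation_set")
  expect_equal(round(m$accuracy, 1), 77.8)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 37.5)
  expect_equal(trunc(m$precision * 100) / 100, 74.35)
  expect_equal(m$pct_false_negatives, 0)
})

test_that("degenerate confusion matrices flag undefined ratios as NA, never 0", {
  all_pos <- metrics(tibble::tibble(tp = 12, fn = 0, tn = 0, fp = 0))
  expect_equal(all_pos$accuracy, 100)
  expect_equal(all_pos$sensitivity, 100)
  expect_true(is.na(all_pos$specificity))
  none_pos <- metrics(tibble::tibble(tp = 0, fn = 0, tn = 9, fp = 0))
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$precision))
})

test_that("the confusion back-solver inverts the printed aggregate figures", {
  s1 <- solve_confusion(900, 71.8, 56, 72.72)
  expect_equal(as.numeric(s1[1, c("tp", "fn", "tn", "fp")]), c(528, 56, 118, 198))
  expect_equal(round(s1$sensitivity, 2), 90.41)

  s2 <- solve_confusion(45, 77.8, 0, 74.35)
  expect_equal(as.numeric(s2[1, c("tp", "fn", "tn", "fp")]), c(29, 0, 6, 10))
  expect_equal(s2$specificity, 37.5)

  s3 <- solve_confusion(900, 71.3, 36, 71.16)
  expect_equal(as.numeric(s3[1, c("tp", "fn", "tn", "fp")]), c(548, 36, 94, 222))

  expect_error(solve_confusion(45, 99.9, 20, 10), "consistent")
})

test_that("solving from a matrix's own printed figures recovers those figures", {
  set.seed(88)
  for (i in 1:10) {
    tp <- sample(50:500, 1); fn <- sample(0:80, 1)
    tn <- sample(20:300, 1); fp <- sample(1:200, 1)
    total <- tp + fn + tn + fp
    acc <- round(100 * (tp + tn) / total, 1)
    pre <- round(100 * tp / (tp + fp), 2)
    sol <- solve_confusion(total, acc, fn, pre)
    expect_equal(sol$fn, fn)
    expect_equal(sol$tp + sol$tn + sol$fn + sol$fp, total)
    expect_equal(round(sol$accuracy, 1), acc)
    expect_equal(round(sol$precision, 2), pre)
  }
})

test_that("holdout and k-fold protocols partition the data as specified", {
  set.seed(7)
  x <- tibble::as_tibble(matrix(rbinom(900 * 3, 1, 0.5), ncol = 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  y <- rbinom(900, 1, 0.6)
  roster1 <- default_roster()["knn"]

  # 5% holdout of 900 records validates on exactly 45
  h <- run_protocol(x, y, validation_protocol("holdout", holdout_fraction = 0.05),
                    roster1, seed = 2)
  expect_equal(h$tp + h$fn + h$tn + h$fp, 45)
  expect_equal(h$denominator, 45)
  expect_equal(h$denominator_kind, "validation_set")

  # pooled k-fold confusion counts sum to the dataset size
  k5 <- run_protocol(x, y, validation_protocol("kfold", k = 5), roster1, seed = 2)
  expect_equal(k5$tp + k5$fn + k5$tn + k5$fp, 900)
  expect_equal(k5$denominator, 900)
  expect_equal(k5$denominator_kind, "whole_dataset")

  expect_error(run_protocol(x[1:4, ], y[1:4], validation_protocol("kfold", k = 10)),
               "folds")
  expect_error(validation_protocol("kfold", k = 5, holdout_fraction = 0.1))
  expect_error(validation_protocol("holdout"))
})

test_that("every roster model beats the majority baseline on separable data", {
  set.seed(19)
  n <- 80
  x <- tibble::tibble(s1 = rbinom(n, 1, 0.5), s2 = rbinom(n, 1, 0.5),
                      s3 = rbinom(n, 1, 0.5))
  y <- as.integer(x$s1 + x$s2 + x$s3 >= 2)  # majority rule: linearly separable
  rep_ <- run_protocol(x, y, validation_protocol("kfold", k = 5),
                       default_roster(), seed = 4)
  majority <- 100 * max(mean(y), 1 - mean(y))
  expect_true(all(rep_$accuracy > majority))
  # the linearly separable signal is found exactly by the linear models
  lin <- rep_$accuracy[rep_$model %in% c("logistic_regression", "linear_discriminant")]
  expect_equal(lin, c(100, 100))
})

test_that("the six-protocol bench runs end to end and is seed-reproducible", {
  sch <- default_schema()
  co <- generate_cohort(sch, generator_config(n_base = 40, n_total = 100, seed = 3))
  lab <- label_cohort(co)
  sc <- score_cohort(co)
  roster <- default_roster()[c("logistic_regression", "decision_tree")]
  protos <- list(validation_protocol("kfold", k = 5),
                 validation_protocol("holdout", holdout_fraction = 0.25))
  b1 <- run_bench(lab, sc, protos, roster, seed = 6)
  b2 <- run_bench(lab, sc, protos, roster, seed = 6)
  expect_equal(nrow(b1), 4)  # 2 models x 2 protocols
  expect_equal(b1$accuracy, b2$accuracy)
  expect_equal(b1$tp, b2$tp)
  expect_true(any(b1$best))
})
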