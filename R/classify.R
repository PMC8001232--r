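#' Define a validation protocol
#'
#' Either k-fold cross validation (metrics pooled over the out-of-fold
#' predictions of all folds) or a single random holdout split (metrics on the
#' held-out set). The study regimes are k in \{5, 25, 50\} and held-out
#' fractions in \{0.05, 0.15, 0.25\}.
#'
#' @param kind `"kfold"` or `"holdout"`.
#' @param k Fold count (kfold only, `k >= 2`).
#' @param holdout_fraction Held-out fraction in (0, 1) (holdout only).
#' @return A `crc_protocol` list.
#' @export
validation_protocol <- function(kind = c("kfold", "holdout"), k = NULL,
                                holdout_fraction = NULL) {
  kind <- match.arg(kind)
  if (kind == "kfold") {
    if (is.null(k) || !is.null(holdout_fraction)) {
      abort("kfold protocols set k and only k", class = "crcrisk_protocol_error")
    }
    stopifnot(k >= 2)
  } else {
    if (is.null(holdout_fraction) || !is.null(k)) {
      abort("holdout protocols set holdout_fraction and only holdout_fraction",
            class = "crcrisk_protocol_error")
    }
    stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  }
  structure(list(kind = kind, k = k, holdout_fraction = holdout_fraction),
            class = "crc_protocol")
}

#' The six benchmark validation protocols
#'
#' @return List of six `crc_protocol`s: 5-, 25-, 50-fold cross validation and
#'   5%, 15%, 25% holdout.
#' @export
protocol_set <- function() {
  c(lapply(c(5L, 25L, 50L), function(k) validation_protocol("kfold", k = k)),
    lapply(c(0.05, 0.15, 0.25), function(f) validation_protocol("holdout", holdout_fraction = f)))
}

protocol_id <- function(p) {
  if (p$kind == "kfold") paste0("kfold_", p$k) else paste0("holdout_", 100 * p$holdout_fraction)
}

# ---- model roster ---------------------------------------------------------

majority_predictor <- function(y) {
  lev <- as.integer(names(which.max(table(y))))
  structure(list(level = lev), class = "crc_majority")
}

fit_or_majority <- function(x, y, fit) {
  if (length(unique(y)) < 2L) return(majority_predictor(y))
  fit(x, y)
}

drop_constant <- function(x) {
  keep <- vapply(x, function(col) stats::sd(col) > 0, logical(1))
  if (!any(keep)) keep[1] <- TRUE
  x[, keep, drop = FALSE]
}

#' The classifier roster of the benchmark
#'
#' Six model families: logistic regression, linear discriminant analysis,
#' a decision tree, bagged trees, a Gaussian-kernel support vector machine
#' (kernel scale `sqrt(p)`, the "medium Gaussian" convention, i.e.
#' `gamma = 1/p`), and k-nearest neighbours (k = 10). Each entry is a list
#' with `fit(x, y)` and `predict(model, x)` returning 0/1 predictions; models
#' degenerate gracefully to a majority vote when a training partition holds a
#' single class.
#'
#' @return Named list of model definitions.
#' @export
default_roster <- function() {
  list(
    logistic_regression = list(
      fit = function(x, y) fit_or_majority(x, y, function(x, y) {
        suppressWarnings(stats::glm(y ~ ., data = cbind(x, y = y), family = stats::binomial()))
      }),
      predict = function(m, x) {
        if (inherits(m, "crc_majority")) return(rep(m$level, nrow(x)))
        as.integer(suppressWarnings(stats::predict(m, newdata = x, type = "response")) > 0.5)
      }),
    linear_discriminant = list(
      fit = function(x, y) fit_or_majority(x, y, function(x, y) {
        x <- drop_constant(x)
        # lda cannot use predictors that are constant within both groups;
        # degenerate folds fall back to a majority vote
        tryCatch({
          m <- suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0, 1))))
          list(lda = m, cols = names(x))
        }, error = function(e) majority_predictor(y))
      }),
      predict = function(m, x) {
        if (inherits(m, "crc_majority")) return(rep(m$level, nrow(x)))
        as.integer(as.character(stats::predict(m$lda, x[, m$cols, drop = FALSE])$class))
      }),
    decision_tree = list(
      fit = function(x, y) fit_or_majority(x, y, function(x, y) {
        rpart::rpart(y ~ ., data = cbind(x, y = factor(y, levels = c(0, 1))), method = "class")
      }),
      predict = function(m, x) {
        if (inherits(m, "crc_majority")) return(rep(m$level, nrow(x)))
        as.integer(as.character(stats::predict(m, newdata = x, type = "class")))
      }),
    bagged_trees = list(
      fit = function(x, y) fit_or_majority(x, y, function(x, y) {
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   mtry = ncol(x), ntree = 60)
      }),
      predict = function(m, x) {
        if (inherits(m, "crc_majority")) return(rep(m$level, nrow(x)))
        as.integer(as.character(stats::predict(m, newdata = x)))
      }),
    gaussian_svm = list(
      fit = function(x, y) fit_or_majority(x, y, function(x, y) {
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   gamma = 1 / ncol(x), scale = FALSE)
      }),
      predict = function(m, x) {
        if (inherits(m, "crc_majority")) return(rep(m$level, nrow(x)))
        as.integer(as.character(stats::predict(m, newdata = x)))
      }),
    knn = list(
      fit = function(x, y) list(x = x, y = y),
      predict = function(m, x) {
        k <- min(10L, nrow(m$x))
        as.integer(as.character(class::knn(m$x, x, cl = factor(m$y, levels = c(0, 1)), k = k)))
      })
  )
}

# ---- confusion and metrics ------------------------------------------------

#' Confusion matrix of binary predictions
#'
#' Positive class is 1 ("suspected to have cancer").
#'
#' @param predictions,truth Aligned 0/1 vectors.
#' @return A `crc_confusion` one-row tibble: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort_format("predictions and truth have different lengths")
  }
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  structure(
    tibble::tibble(
      tp = sum(predictions == 1L & truth == 1L),
      fn = sum(predictions == 0L & truth == 1L),
      tn = sum(predictions == 0L & truth == 0L),
      fp = sum(predictions == 1L & truth == 0L)),
    class = c("crc_confusion", class(tibble::tibble())))
}

#' Performance measures of a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and precision `TP/(TP+FP)`, each times 100, plus the
#' percentage of false negatives `100*FN/denominator`. For k-fold pooling the
#' denominator is the whole dataset; for holdout it is the validation set.
#' A ratio with zero denominator is reported as `NA` (undefined), never 0.
#'
#' @param cm A confusion matrix (`crc_confusion` or anything with
#'   `tp`/`fn`/`tn`/`fp`).
#' @param denominator_total Denominator of the false-negative percentage;
#'   defaults to the matrix total.
#' @param denominator_kind `"whole_dataset"` or `"validation_set"`,
#'   informational.
#' @return A one-row tibble of the five measures (percent scale) plus the
#'   denominator bookkeeping.
#' @export
metrics <- function(cm, denominator_total = NULL,
                    denominator_kind = c("whole_dataset", "validation_set")) {
  denominator_kind <- match.arg(denominator_kind)
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  stopifnot(all(c(tp, fn, tn, fp) >= 0))
  total <- tp + fn + tn + fp
  denominator_total <- denominator_total %||% total
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    accuracy = ratio(tp + tn, total),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    pct_false_negatives = ratio(fn, denominator_total),
    denominator = denominator_total,
    denominator_kind = denominator_kind)
}

# ---- protocol runner ------------------------------------------------------

coerce_features <- function(features) {
  x <- tibble::as_tibble(features)
  if ("record_id" %in% names(x)) x <- x[, setdiff(names(x), "record_id")]
  x <- dplyr::mutate(x, dplyr::across(dplyr::everything(), as.numeric))
  as.data.frame(x)
}

coerce_response <- function(response) {
  if (inherits(response, "crc_scores")) return(as.integer(response$label))
  if (is.data.frame(response)) return(as.integer(response$label))
  as.integer(response)
}

#' Run one validation protocol over a model roster
#'
#' For k-fold protocols the dataset is partitioned into k folds; each model
#' is trained k times and its out-of-fold predictions pooled into a single
#' confusion matrix, whose counts therefore sum to the dataset size, with the
#' false-negative percentage taken relative to the whole dataset. For holdout
#' protocols a single stratification-free random split is drawn; metrics and
#' the false-negative denominator use the held-out validation set.
#'
#' @param features Boolean label matrix (a `crc_labels`, or any data frame of
#'   0/1 features).
#' @param response Binary response (0/1 vector, or a `crc_scores`, whose
#'   `label` column is used).
#' @param protocol A [validation_protocol()].
#' @param roster Model list as in [default_roster()].
#' @param seed Integer seed for the fold/split assignment.
#' @return A `crc_bench` tibble: one row per model with confusion counts, the
#'   five measures, timing (informational) and a best-model flag (highest
#'   accuracy within the protocol).
#' @export
run_protocol <- function(features, response, protocol, roster = default_roster(),
                         seed = 1L) {
  stopifnot(inherits(protocol, "crc_protocol"), length(roster) > 0)
  x <- coerce_features(features)
  y <- coerce_response(response)
  if (nrow(x) != length(y)) abort_format("features and response are not aligned")
  n <- nrow(x)
  if (protocol$kind == "kfold" && protocol$k > n) {
    abort("more folds than records", class = "crcrisk_protocol_error")
  }
  assignment <- withr::with_seed(seed, {
    if (protocol$kind == "kfold") sample(rep_len(seq_len(protocol$k), n))
    else sample.int(n, max(1L, round(protocol$holdout_fraction * n)))
  })
  rows <- purrr::imap(roster, function(model, name) {
    t0 <- proc.time()[["elapsed"]]
    if (protocol$kind == "kfold") {
      pred <- integer(n)
      for (fold in seq_len(protocol$k)) {
        test_idx <- which(assignment == fold)
        m <- model$fit(x[-test_idx, , drop = FALSE], y[-test_idx])
        pred[test_idx] <- model$predict(m, x[test_idx, , drop = FALSE])
      }
      cm <- confusion(pred, y)
      met <- metrics(cm, denominator_total = n, denominator_kind = "whole_dataset")
    } else {
      val_idx <- assignment
      m <- model$fit(x[-val_idx, , drop = FALSE], y[-val_idx])
      pred <- model$predict(m, x[val_idx, , drop = FALSE])
      cm <- confusion(pred, y[val_idx])
      met <- metrics(cm, denominator_total = length(val_idx),
                     denominator_kind = "validation_set")
    }
    secs <- proc.time()[["elapsed"]] - t0
    pid <- protocol_id(protocol)
    pkind <- protocol$kind
    dplyr::bind_cols(
      tibble::tibble(model = name, protocol = pid, kind = pkind),
      tibble::as_tibble(cm), met, tibble::tibble(seconds = secs))
  })
  out <- dplyr::bind_rows(rows)
  out$best <- out$accuracy == max(out$accuracy, na.rm = TRUE)
  structure(out, class = c("crc_bench", class(tibble::tibble())))
}

#' Run the full classification bench
#'
#' [run_protocol()] over a list of protocols (default: the six study
#' regimes), bound into one report shaped like the benchmark's result tables.
#'
#' @inheritParams run_protocol
#' @param protocols List of protocols (default [protocol_set()]).
#' @return A `crc_bench` tibble with one row per model and protocol.
#' @export
run_bench <- function(features, response, protocols = protocol_set(),
                      roster = default_roster(), seed = 1L) {
  out <- purrr::imap_dfr(protocols, function(p, i) {
    run_protocol(features, response, p, roster, seed = seed + i - 1L)
  })
  structure(out, class = c("crc_bench", class(tibble::tibble())))
}
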