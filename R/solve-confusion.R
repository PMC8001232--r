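#' Back-solve an integer confusion matrix from printed aggregate figures
#'
#' Published benchmark tables often print only the dataset size, accuracy,
#' false-negative count and precision of a model. Because the counts are
#' integers, those figures usually pin down the full confusion matrix: the
#' accuracy band at its printed precision fixes `TP + TN`, which fixes
#' `FP = total - (TP + TN) - FN`, and the precision band then selects `TP`.
#' Printed figures are accepted under either round-half-even or truncation at
#' their printed decimal count (published tables mix both conventions), and
#' the report says which convention reproduces each figure.
#'
#' @param total Dataset (or validation-set) size.
#' @param accuracy Printed accuracy in percent.
#' @param fn Printed false-negative count.
#' @param precision Printed precision in percent.
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, the implied exact
#'   `accuracy`/`sensitivity`/`specificity`/`precision` (percent), and
#'   `accuracy_match`/`precision_match` (`"round"`, `"trunc"` or `"both"`).
#'   Errors if no integer matrix is consistent with the figures; if several
#'   are, the one closest to the printed figures is returned and the count of
#'   candidates recorded in the `n_candidates` attribute.
#' @export
solve_confusion <- function(total, accuracy, fn, precision) {
  stopifnot(total >= 1, fn >= 0, fn <= total)
  d_acc <- printed_decimals(accuracy)
  d_pre <- printed_decimals(precision)
  candidates <- list()
  for (s in 0:(total - fn)) {
    acc_m <- matches_printed(100 * s / total, accuracy, d_acc)
    if (!any(acc_m)) next
    fp <- total - s - fn
    if (fp < 0) next
    for (tp in 0:s) {
      if (tp + fp == 0) next
      pre_m <- matches_printed(100 * tp / (tp + fp), precision, d_pre)
      if (!any(pre_m)) next
      tn <- s - tp
      err <- abs(100 * s / total - accuracy) + abs(100 * tp / (tp + fp) - precision)
      candidates[[length(candidates) + 1L]] <- list(
        tp = tp, fn = fn, tn = tn, fp = fp, err = err,
        acc_match = match_label(acc_m), pre_match = match_label(pre_m))
    }
  }
  if (length(candidates) == 0L) {
    abort("no integer confusion matrix is consistent with the printed figures",
          class = "crcrisk_inconsistency_error")
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "err"))]]
  out <- tibble::tibble(
    tp = best$tp, fn = best$fn, tn = best$tn, fp = best$fp,
    accuracy = 100 * (best$tp + best$tn) / total,
    sensitivity = if (best$tp + best$fn > 0) 100 * best$tp / (best$tp + best$fn) else NA_real_,
    specificity = if (best$tn + best$fp > 0) 100 * best$tn / (best$tn + best$fp) else NA_real_,
    precision = 100 * best$tp / (best$tp + best$fp),
    accuracy_match = best$acc_match,
    precision_match = best$pre_match)
  attr(out, "n_candidates") <- length(candidates)
  out
}

match_label <- function(m) {
  if (all(m)) "both" else if (m[["round"]]) "round" else "trunc"
}
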