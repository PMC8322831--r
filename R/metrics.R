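#' Precision, recall and F-score over the positive class
#'
#' Computes the confusion counts of predicted against true 0/1 labels and
#' the derived metrics: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f_score = 2PR/(P+R)` (balanced F1 over the positive/match class). By
#' convention a metric with a zero denominator is 0, and `f_score = 0`
#' whenever `P + R = 0`.
#'
#' @param truth Integer 0/1 vector of reference labels.
#' @param estimate Integer 0/1 vector of predicted labels.
#' @return One-row tibble: `precision`, `recall`, `f_score`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' match_metrics(rep(c(1, 0), c(10, 10)), rep(c(1, 0, 1, 0), c(8, 2, 2, 8)))
#' @export
match_metrics <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("match_metrics: length mismatch", call. = FALSE)
  }
  if (anyNA(truth)) stop("match_metrics: unlabeled data", call. = FALSE)
  stopifnot(all(truth %in% 0:1), all(estimate %in% 0:1))
  tp <- sum(truth == 1L & estimate == 1L)
  fp <- sum(truth == 0L & estimate == 1L)
  fn <- sum(truth == 1L & estimate == 0L)
  tn <- sum(truth == 0L & estimate == 0L)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(precision = p, recall = r, f_score = f,
                 tp = tp, fp = fp, fn = fn, tn = tn)
}
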