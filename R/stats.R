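#' One-tailed Mann-Whitney U comparison of two groups
#'
#' Exact p-value for small tie-free samples, normal approximation with tie
#' and continuity correction otherwise (the behaviour of
#' [stats::wilcox.test] with its defaults, reported here together with the
#' group medians and the U statistic).
#'
#' @param x,y numeric samples.
#' @param alternative `"less"` (x tends below y) or `"greater"`.
#' @return list: `median_x`, `median_y`, `u_statistic`, `p_value`, `n_x`,
#'   `n_y`, `alternative`, `method`.
#' @examples
#' mannWhitneyOneTailed(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 0.05
#' @export
mannWhitneyOneTailed <- function(x, y,
                                 alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = NULL,
                       correct = TRUE))
  list(median_x = stats::median(x), median_y = stats::median(y),
       u_statistic = unname(wt$statistic), p_value = wt$p.value,
       n_x = length(x), n_y = length(y), alternative = alternative,
       method = wt$method)
}

#' Binary-classification performance metrics
#'
#' Standard definitions: `ACC = (TP + TN) / N`,
#' `F1 = 2 TP / (2 TP + FP + FN)`, Matthews correlation coefficient (0 by
#' convention when any confusion-matrix marginal is 0), and
#' `FPR = FP / (FP + TN)`.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return list with the counts and `acc`, `f1`, `mcc`, `fpr`.
#' @examples
#' confusionMetrics(tp = 23, fp = 2, tn = 23, fn = 2)$fpr  # 0.08
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp)
  fp <- unname(fp)
  tn <- unname(tn)
  fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  acc <- if (n > 0) (tp + tn) / n else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (tp * tn - fp * fn) / sqrt(denom)
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = acc, f1 = f1, mcc = mcc, fpr = fpr)
}
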