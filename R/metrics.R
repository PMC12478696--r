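# Imbalance-aware evaluation: AUROC (rank / Mann-Whitney definition) and
# AUPR (step-interpolated average precision). Both are written directly from
# their definitions; the test suite cross-checks AUROC against the
# Mann-Whitney U statistic and pROC.

#' Evaluate probabilities against binary labels
#'
#' AUROC is computed from the rank statistic
#' `(sum of positive ranks - n1(n1+1)/2) / (n1 n0)`, equivalent to the
#' probability that a random positive outranks a random negative (ties count
#' one half). AUPR is step-interpolated average precision,
#' `sum over threshold steps of (recall_i - recall_{i-1}) * precision_i`,
#' with tied scores collapsed into single threshold steps. AUPR is the
#' headline metric under heavy class imbalance: a random ranker scores about
#' the positive prevalence, not 0.5.
#'
#' @param probabilities numeric scores (higher = more likely positive).
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return a list with elements `auroc` and `aupr`, both in `[0, 1]`.
#' @export
evaluate_predictions <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  r <- rank(probabilities)
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(probabilities, decreasing = TRUE)
  y <- labels[ord]
  s <- probabilities[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1L - y)
  # keep only the last index of each tied-score run (one threshold per score)
  keep <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cum_tp[keep]; fp <- cum_fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  aupr <- sum(diff(c(0, recall)) * precision)

  list(auroc = auroc, aupr = aupr)
}
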