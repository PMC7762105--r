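#' ROC analysis with DeLong intervals and operating-point metrics
#'
#' The AUC is computed by the rank (Mann-Whitney) construction with midrank
#' tie handling: the probability that a random positive outranks a random
#' negative, counting ties as 1/2. The 95% CI and the test of AUC = 0.5 use
#' the DeLong variance (normal approximation). Sensitivity, specificity,
#' accuracy and misclassification (all percentages) are reported at the
#' supplied probability threshold if given, otherwise at the Youden-optimal
#' threshold (maximizing sensitivity + specificity - 1; ties broken toward
#' the lowest threshold). A case is called positive when its score is >= the
#' threshold.
#'
#' @param scores numeric scores (higher = more likely positive/high).
#' @param labels binary labels ("high"/"low", logical, or 0/1).
#' @param threshold optional explicit operating threshold on the score scale.
#' @param conf_level confidence level for the AUC interval.
#' @return Object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`, `accuracy`,
#'   `misclassification`, `p_value`, `threshold`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, threshold = NULL,
                         conf_level = 0.95) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("score/label length mismatch",
                                        call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present (degenerate-label error)",
         call. = FALSE)
  }

  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  robj <- pROC::roc(response = y, predictor = scores,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
  v <- suppressWarnings(as.numeric(pROC::var(robj, method = "delong")))
  if (is.finite(v) && v > 0) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci_low <- max(0, auc - z * sqrt(v))
    ci_high <- min(1, auc + z * sqrt(v))
    p_value <- 2 * pnorm(-abs((auc - 0.5) / sqrt(v)))
  } else {
    ci_low <- ci_high <- auc
    p_value <- if (auc == 0.5) 1 else 0
  }

  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    best_j <- -Inf
    threshold <- cand[1]
    sens <- spec <- NA_real_
    for (thr in cand) {
      se <- mean(scores[y == 1L] >= thr)
      sp <- mean(scores[y == 0L] < thr)
      j <- se + sp - 1
      if (j > best_j + 1e-12) {
        best_j <- j
        threshold <- thr
        sens <- se
        spec <- sp
      }
    }
  } else {
    sens <- mean(scores[y == 1L] >= threshold)
    spec <- mean(scores[y == 0L] < threshold)
  }
  acc <- (sens * n_pos + spec * n_neg) / (n_pos + n_neg)

  structure(list(
    auc = auc, ci_low = ci_low, ci_high = ci_high,
    sensitivity = 100 * sens, specificity = 100 * spec,
    accuracy = 100 * acc, misclassification = 100 * (1 - acc),
    p_value = p_value, threshold = threshold,
    n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g vs 0.5\n",
              x$auc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf(
    "  at threshold %.4g: sens %.1f%%, spec %.1f%%, acc %.1f%%, misclass %.1f%%\n",
    x$threshold, x$sensitivity, x$specificity, x$accuracy,
    x$misclassification))
  invisible(x)
}
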