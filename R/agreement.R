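#' Dice similarity coefficient of two contours
#'
#' `2|A intersect B| / (|A| + |B|)`: the standard overlap measure for
#' repeated tumor contours. Symmetric; 1 iff the masks are identical as
#' voxel sets, 0 iff disjoint.
#'
#' @param mask_a,mask_b binary 3D arrays on the same grid; at least one
#'   non-empty.
#' @return coefficient in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_mask(mask_a, "mask_a")
  b <- as_mask(mask_b, "mask_b")
  if (!identical(dim(a), dim(b))) {
    stop("masks are not on a common grid", call. = FALSE)
  }
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) {
    stop("Dice is undefined for two empty masks", call. = FALSE)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Intraclass correlation for repeated NE measurements, ICC(A,1)
#'
#' Single-measure absolute-agreement ICC from the two-way ANOVA
#' decomposition of a subjects-by-raters matrix (McGraw-Wong ICC(A,1)):
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}}
#' with `MS_R`, `MS_C`, `MS_E` the between-subject, between-rater and
#' residual mean squares. The point estimate is the same for the two-way
#' random-effects model (interrater: raters sampled from a population) and
#' the two-way mixed-effects model (intrarater: occasions fixed); the model
#' choice affects interpretation. The 95% CI uses the McGraw-Wong
#' F-distribution bounds. Adding one constant to every cell leaves the ICC
#' unchanged; a rater-specific offset lowers it (absolute agreement, unlike
#' a consistency ICC).
#'
#' @param values numeric matrix or data.frame, subjects in rows, raters (or
#'   occasions) in columns; no missing cells.
#' @param model `"two_way_random_absolute"` (interrater) or
#'   `"two_way_mixed_absolute"` (intrarater).
#' @param conf_level confidence level.
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `mean_squares` (MSR, MSC, MSE), `n_subjects`, `n_raters`,
#'   `label` (qualitative annotation: "excellent" >= 0.9, "good" >= 0.75).
#' @export
icc <- function(values,
                model = c("two_way_random_absolute",
                          "two_way_mixed_absolute"),
                conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(values)
  if (!is.numeric(m)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(m)) stop("rating matrix must have no missing cells",
                     call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need >= 2 subjects and >= 2 raters/occasions", call. = FALSE)
  }

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    stop("zero total variance; ICC undefined", call. = FALSE)
  }
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- ss_total - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  r <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1)
  } else {
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(r, r)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- qf(1 - alpha / 2, n - 1, v)
      f_u <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(lo, hi)
    }
  }
  ci[1] <- min(ci[1], r)
  ci[2] <- max(ci[2], r)

  label <- if (r >= 0.9) "excellent" else if (r >= 0.75) "good" else
    if (r >= 0.5) "moderate" else "poor"

  structure(list(icc = r, ci_low = ci[1], ci_high = ci[2], model = model,
                 mean_squares = list(msr = msr, msc = msc, mse = mse),
                 n_subjects = n, n_raters = k, label = label),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f-%.3f), %s agreement [%s]\n",
              x$icc, x$ci_low, x$ci_high, x$label, x$model))
  invisible(x)
}
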