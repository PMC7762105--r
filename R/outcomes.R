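#' Kaplan-Meier curves, medians and log-rank test
#'
#' Product-limit survival estimates per group, with the median defined as
#' the earliest time at which the estimated survival drops to 0.5 or below
#' (reported as NA, "not reached", when the curve never does). With two or
#' more groups the log-rank chi-square p-value is included.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups optional group labels; `NULL` fits a single curve.
#' @return Object of class `km_result`: `curves` (data.frame with `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `medians` (named vector),
#'   `logrank_p` (NA for a single group), `n`, `n_events`.
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.character(groups)
  if (length(unique(groups)) != length(unique(groups[!is.na(groups)])) ||
      anyNA(groups)) {
    stop("groups must not contain NA", call. = FALSE)
  }
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  dat <- data.frame(t = times, e = events, g = factor(groups))

  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = dat)
  sm <- summary(fit, censored = TRUE)
  grp_lab <- if (is.null(sm$strata)) {
    rep(levels(dat$g)[1], length(sm$time))
  } else {
    sub("^g=", "", as.character(sm$strata))
  }
  curves <- data.frame(group = grp_lab, time = sm$time,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       surv = sm$surv, stringsAsFactors = FALSE)

  medians <- vapply(split(curves, curves$group), function(cc) {
    hit <- cc$time[cc$surv <= 0.5 + 1e-12]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))

  logrank_p <- NA_real_
  if (nlevels(dat$g) >= 2L) {
    sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = dat)
    logrank_p <- pchisq(sd_$chisq, df = nlevels(dat$g) - 1L,
                        lower.tail = FALSE)
  }
  structure(list(curves = curves, medians = medians, logrank_p = logrank_p,
                 n = nrow(dat), n_events = sum(dat$e)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier fit:", x$n, "subjects,", x$n_events, "events\n")
  for (g in names(x$medians)) {
    med <- x$medians[[g]]
    cat(sprintf("  %s: median %s months\n", g,
                if (is.na(med)) "not reached" else sprintf("%.1f", med)))
  }
  if (!is.na(x$logrank_p)) {
    cat(sprintf("  log-rank p = %.4g\n", x$logrank_p))
  }
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' confidence intervals and p-values per term. Monotone likelihood /
#' non-convergence is flagged in the result rather than silently returned.
#'
#' @param records data.frame of one row per patient.
#' @param covariates character vector of column names to adjust over (the
#'   first is conventionally the exposure of interest, e.g.
#'   `qdelta_class`).
#' @param time_col,event_col names of the follow-up time and event columns.
#' @return Object of class `cox_result`: `table` (data.frame with `term`,
#'   `hr`, `ci_low`, `ci_high`, `p`), `flagged`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates, time_col = "os_months",
                    event_col = "os_event") {
  need <- c(time_col, event_col, covariates)
  missing <- setdiff(need, colnames(records))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- records[, need, drop = FALSE]
  if (!all(complete.cases(dat))) {
    stop("records contain missing values", call. = FALSE)
  }
  if (sum(dat[[event_col]]) < 1) stop("need at least one event",
                                      call. = FALSE)
  for (cv in covariates) {
    if (length(unique(dat[[cv]])) < 2L) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
    if (is.character(dat[[cv]])) dat[[cv]] <- factor(dat[[cv]])
  }
  form <- as.formula(paste0("survival::Surv(`", time_col, "`, `", event_col,
                            "`) ~ ",
                            paste(sprintf("`%s`", covariates),
                                  collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(!is.finite(co[, "coef"])) || any(abs(co[, "coef"]) > 15)) {
    flagged <- TRUE
  }
  z <- qnorm(0.975)
  tab <- data.frame(
    term = rownames(co),
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, flagged = flagged, n = sm$n,
                 n_events = sm$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties):", x$n, "subjects,",
      x$n_events, "events\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                tab$term[i], tab$hr[i], tab$ci_low[i], tab$ci_high[i],
                tab$p[i]))
  }
  if (x$flagged) cat("  NOTE: fit flagged (convergence/monotone likelihood)\n")
  invisible(x)
}

#' Fisher exact and likelihood-ratio tests with relative risk on a 2x2 table
#'
#' For an exposure-by-outcome table with counts `a`, `b` (exposed:
#' outcome yes/no) and `c`, `d` (unexposed): two-sided Fisher exact p by
#' hypergeometric enumeration (summing the probabilities of all tables with
#' the observed margins that are no more probable than the observed one),
#' the likelihood-ratio G-test p, and the relative risk
#' `RR = [a/(a+b)] / [c/(c+d)]` with a log-normal 95% CI.
#'
#' @param a,b,c,d non-negative integer cell counts; alternatively `a` may be
#'   a 2x2 matrix (rows = exposure, columns = outcome).
#' @return list with `fisher_p`, `lr_p`, `relative_risk`, `rr_ci_low`,
#'   `rr_ci_high`, `table`.
#' @export
fisher_rr <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2L)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row/column margin; relative risk undefined", call. = FALSE)
  }
  a_ <- m[1, 1]; b_ <- m[1, 2]; c_ <- m[2, 1]; d_ <- m[2, 2]

  fisher_p <- fisher.test(m)$p.value

  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  obs <- as.numeric(m)
  exp_ <- as.numeric(expected)
  g <- 2 * sum(ifelse(obs == 0, 0, obs * log(obs / exp_)))
  lr_p <- pchisq(g, df = 1, lower.tail = FALSE)

  rr <- (a_ / (a_ + b_)) / (c_ / (c_ + d_))
  if (a_ == 0 || c_ == 0) {
    warning("zero event cell; RR interval undefined", call. = FALSE)
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(1 / a_ - 1 / (a_ + b_) + 1 / c_ - 1 / (c_ + d_))
    z <- qnorm(0.975)
    ci <- exp(log(rr) + c(-z, z) * se)
  }
  list(fisher_p = fisher_p, lr_p = lr_p, relative_risk = rr,
       rr_ci_low = ci[1], rr_ci_high = ci[2], table = m)
}

#' Dichotomize survival at a one-year horizon
#'
#' Builds the exposure-by-outcome table used when full survival curves are
#' not available: an event before the horizon counts as failure, follow-up
#' reaching the horizon counts as success, and patients censored before the
#' horizon are excluded. Rows are the exposure classes (`low` first, so the
#' RR from [fisher_rr()] reads "low-delta patients are RR times as likely to
#' reach one-year survival"); columns are success/failure.
#'
#' @param times,events follow-up times and event indicators.
#' @param classes "high"/"low" class per patient.
#' @param horizon_months dichotomization horizon (12 by default).
#' @return 2x2 integer matrix with dimnames.
#' @export
one_year_table <- function(times, events, classes, horizon_months = 12) {
  cls <- as.character(classes)
  if (!all(cls %in% c("high", "low"))) {
    stop("classes must be 'high'/'low'", call. = FALSE)
  }
  keep <- !(times < horizon_months & events == 0)
  times <- times[keep]; events <- events[keep]; cls <- cls[keep]
  success <- times >= horizon_months
  m <- matrix(c(sum(cls == "low" & success), sum(cls == "low" & !success),
                sum(cls == "high" & success), sum(cls == "high" & !success)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(class = c("low", "high"),
                              outcome = c("survived", "failed")))
  storage.mode(m) <- "integer"
  m
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The p-value uses the exact permutation
#' distribution (full enumeration) for n <= 9 with untied data, and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant vector; correlation undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)

  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    perms <- .all_perms(n)
    denom <- n * (n^2 - 1)
    s_obs <- sum((rx - ry)^2)
    rho_obs <- 1 - 6 * s_obs / denom
    s_all <- colSums((t(perms) - rx)^2)
    rho_all <- 1 - 6 * s_all / denom
    p <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# All permutations of 1..n as an n!-by-n matrix (n <= 9).
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- nrow(sub)
    before <- seq_len(pos - 1L)
    out[row + seq_len(blk), ] <- cbind(
      sub[, before, drop = FALSE],
      rep(n, blk),
      sub[, setdiff(seq_len(n - 1L), before), drop = FALSE])
    row <- row + blk
  }
  out
}

#' Welch two-sample t-test on a grouped measurement
#'
#' Two-sided unequal-variance t-test comparing a continuous measurement
#' (e.g. stromal area %) between the two delta classes. When both groups
#' are constant with equal means the convention t = 0, p = 1 applies.
#'
#' @param values numeric measurements.
#' @param groups two-level group labels, >= 2 observations per level.
#' @return list with `t`, `df`, `p_value`, `group_means` (named), `n`.
#' @export
ttest_groups <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("need >= 2 observations per group",
                               call. = FALSE)
  means <- tapply(values, g, mean)
  res <- tryCatch(t.test(values ~ g), error = function(e) e)
  if (inherits(res, "error")) {
    if (grepl("essentially constant", conditionMessage(res))) {
      if (isTRUE(all.equal(means[[1]], means[[2]]))) {
        return(list(t = 0, df = NA_real_, p_value = 1,
                    group_means = means, n = table(g)))
      }
      return(list(t = Inf * sign(means[[1]] - means[[2]]), df = NA_real_,
                  p_value = 0, group_means = means, n = table(g)))
    }
    stop(res)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, group_means = means, n = table(g))
}
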