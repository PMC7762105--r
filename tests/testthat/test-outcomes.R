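test_that("Kaplan-Meier product limit, medians and degenerate cases", {
  # four events, no censoring: survival steps 0.75 / 0.5 / 0.25 / 0
  km <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(unname(km$medians["all"]), 2)

  # all censored -> error (no events to estimate from)
  expect_error(km_fit(c(1, 2, 3), c(0, 0, 0)), "at least one event")

  # curve never reaching 0.5 -> median not reached (NA)
  km2 <- km_fit(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  expect_true(is.na(km2$medians["all"]))
  expect_true(all(diff(km2$curves$surv) <= 0))  # non-increasing
  expect_true(all(km2$curves$surv <= 1))

  # 20-patient random case matches the hand product-limit oracle
  set.seed(121)
  tt <- round(rexp(20, 1 / 20), 1)
  ee <- rbinom(20, 1, 0.7); ee[1] <- 1
  km3 <- km_fit(tt, ee)
  o <- oracle_km(tt, ee)
  got <- km3$curves[km3$curves$n_event > 0, c("time", "surv")]
  expect_equal(got$time, o$time)
  expect_equal(got$surv, o$surv, tolerance = 1e-12)
})

test_that("log-rank flags separated groups", {
  sim <- simulate_cohort(cohort_params(n_patients = 200, seed = 131,
                                       true_log_hr = log(3)))
  km <- km_fit(sim$cohort$os_months, sim$cohort$os_event,
               sim$cohort$delta_label)
  expect_lt(km$logrank_p, 0.01)
  expect_lt(km$medians["high"], km$medians["low"])
})

test_that("Cox fit: null covariate near HR 1; finite-MLE toy matches a grid oracle", {
  set.seed(141)
  n <- 1000
  dat <- data.frame(os_months = rexp(n, 0.05),
                    os_event = 1L,
                    x = rnorm(n))
  cx <- cox_fit(dat, "x")
  expect_lt(abs(log(cx$table$hr)), 0.12)
  expect_true(cx$table$ci_low < 1 & cx$table$ci_high > 1)

  # small no-tie dataset with a finite MLE: compare to 1-D grid search of a
  # hand-written partial likelihood
  toy <- data.frame(os_months = c(1, 2, 3, 4),
                    os_event = c(1, 1, 1, 1),
                    x = c(1, 0, 1, 0))
  pl <- function(b) {
    risk <- exp(b * toy$x)
    ll <- 0
    for (i in order(toy$os_months)) {
      at_risk <- toy$os_months >= toy$os_months[i]
      ll <- ll + b * toy$x[i] - log(sum(risk[at_risk]))
    }
    ll
  }
  b_hat <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  cx_toy <- cox_fit(toy, "x")
  expect_equal(log(cx_toy$table$hr), b_hat, tolerance = 1e-4)

  expect_error(cox_fit(data.frame(os_months = 1:4, os_event = c(1, 1, 0, 0),
                                  x = rep(2, 4)), "x"),
               "constant covariate")
})

test_that("Fisher exact p matches full enumeration; RR is the risk ratio", {
  # worked example: (8,2 | 4,6) -> RR exactly 2
  f <- fisher_rr(8, 2, 4, 6)
  expect_equal(f$relative_risk, 2.0)
  expect_equal(f$fisher_p, oracle_fisher_enum(8, 2, 4, 6), tolerance = 1e-12)

  # fully symmetric table: RR 1, p 1
  f1 <- fisher_rr(5, 5, 5, 5)
  expect_equal(f1$relative_risk, 1.0)
  expect_equal(f1$fisher_p, 1.0)

  # random tables with margins <= 15 vs exhaustive enumeration
  set.seed(151)
  for (i in 1:40) {
    m <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0) ||
        any(rowSums(m) > 15) || any(colSums(m) > 15)) next
    f2 <- fisher_rr(m)
    expect_equal(f2$fisher_p,
                 oracle_fisher_enum(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
    expect_equal(f2$relative_risk,
                 (m[1, 1] / sum(m[1, ])) / (m[2, 1] / sum(m[2, ])))
  }

  # transposition invariance of the exact p; RR inverts when rows swap
  f3 <- fisher_rr(7, 3, 2, 9)
  expect_equal(fisher_rr(t(matrix(c(7, 3, 2, 9), 2, byrow = TRUE)))$fisher_p,
               f3$fisher_p, tolerance = 1e-12)
  f3swap <- fisher_rr(2, 9, 7, 3)
  expect_equal(f3swap$relative_risk, 1 / f3$relative_risk, tolerance = 1e-12)

  expect_error(fisher_rr(0, 0, 3, 4), "margin")
})

test_that("one-year dichotomization excludes early-censored patients", {
  times <- c(20, 5, 11, 14, 3, 18)
  events <- c(0, 1, 0, 1, 1, 0)
  cls <- c("low", "low", "low", "high", "high", "high")
  # censored at 11 months is excluded; times >= 12 survive
  m <- one_year_table(times, events, cls)
  expect_equal(unname(m["low", "survived"]), 1L)
  expect_equal(unname(m["low", "failed"]), 1L)
  expect_equal(unname(m["high", "survived"]), 2L)
  expect_equal(unname(m["high", "failed"]), 1L)
  expect_equal(sum(m), 5)
})

test_that("Spearman rho and its exact small-sample p-value", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman(x, x^3)$rho, 1.0)      # strictly increasing
  expect_equal(spearman(x, -2 * x + 1)$rho, -1.0)

  # n = 8 random untied pair: p matches exhaustive 8! enumeration
  set.seed(161)
  xr <- rnorm(8); yr <- rnorm(8)
  s <- spearman(xr, yr)
  expect_equal(s$method, "exact permutation")
  rx <- rank(xr); ry <- rank(yr)
  rho_obs <- cor(rx, ry)
  perms <- qdelta:::.all_perms(8)
  rho_all <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(s$p_value, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)

  # large-sample t approximation agrees with cor.test
  set.seed(162)
  xl <- rnorm(60); yl <- 0.5 * xl + rnorm(60)
  sl <- spearman(xl, yl)
  ct <- suppressWarnings(cor.test(xl, yl, method = "spearman"))
  expect_equal(sl$rho, unname(ct$estimate), tolerance = 1e-12)

  expect_error(spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman(1:3, 1:3), "n >= 4")
})

test_that("Welch t-test matches the textbook formula; constant-data conventions hold", {
  set.seed(171)
  x <- rnorm(15, 60, 12)
  y <- rnorm(15, 48, 6)
  r <- ttest_groups(c(x, y), rep(c("low", "high"), each = 15))
  # groups are ordered by factor level: high then low
  o <- oracle_welch(y, x)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)

  # identical constant groups: t = 0, p = 1
  rc <- ttest_groups(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(rc$t, 0)
  expect_equal(rc$p_value, 1)

  # extreme separation: p near 0
  v <- c(rep(0, 4), rep(10, 4)) + rnorm(8, 0, 1e-4)
  rs <- ttest_groups(v, rep(c("a", "b"), each = 4))
  expect_lt(rs$p_value, 1e-6)

  expect_error(ttest_groups(rnorm(5), c("a", "a", "a", "a", "b")),
               ">= 2 observations")
})
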