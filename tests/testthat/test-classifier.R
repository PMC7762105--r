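sim_logit <- function(n, beta0, beta, seed, mu = 50, sd = 15) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta), mu, sd), ncol = length(beta))
  colnames(X) <- paste0("x", seq_along(beta))
  p <- plogis(beta0 + drop(X %*% beta))
  list(X = as.data.frame(X), y = rbinom(n, 1, p))
}

test_that("univariate screen: null features give AUC ~ 0.5, separation is flagged", {
  set.seed(21)
  x <- rnorm(1000, 50, 15)
  y <- sample(rep(0:1, 500))
  f <- fit_univariate(x, y)
  expect_lt(abs(f$roc$auc - 0.5), 0.06)
  expect_gt(f$wald_p, 0.001)
  expect_false(f$separation)

  # perfect separation: AUC 1 and the flag set
  xs <- c(rnorm(30, 20, 2), rnorm(30, 80, 2))
  ys <- rep(c(0, 1), each = 30)
  fs <- fit_univariate(xs, ys)
  expect_true(fs$separation)
  expect_equal(fs$roc$auc, 1.0)

  expect_error(fit_univariate(x, rep(1, 1000)), "single class")
  expect_error(fit_univariate(x[1:5], y[1:5]), "n >= 10")
})

test_that("known-coefficient logistic model is recovered within 3 SE", {
  d <- sim_logit(2000, beta0 = -1, beta = c(0.08, -0.05), seed = 31)
  m <- fit_qdelta(d$X, d$y)
  expect_false(m$separation)
  expect_lt(abs(m$coefficients[["x1"]] - 0.08), 3 * m$se[["x1"]])
  expect_lt(abs(m$coefficients[["x2"]] - (-0.05)), 3 * m$se[["x2"]])
})

test_that("backward elimination honors alpha and column-order invariance", {
  d <- sim_logit(400, beta0 = -3.5, beta = c(0.05, 0.04, 0, 0), seed = 41)
  # alpha = 1 never triggers a removal
  keep_all <- backward_eliminate(d$X, d$y, alpha = 1)
  expect_equal(sort(keep_all$selected), paste0("x", 1:4))
  expect_equal(nrow(keep_all$removed), 0L)

  sel <- backward_eliminate(d$X, d$y, alpha = 0.05)
  expect_true(all(c("x1", "x2") %in% sel$selected))

  # shuffling columns does not change the selected set (untied p-values)
  sel_shuf <- backward_eliminate(d$X[, c(3, 1, 4, 2)], d$y, alpha = 0.05)
  expect_setequal(sel$selected, sel_shuf$selected)

  # likelihood-ratio variant agrees here
  sel_lr <- backward_eliminate(d$X, d$y, alpha = 0.05, test = "lr")
  expect_true(all(c("x1", "x2") %in% sel_lr$selected))
})

test_that("all-noise candidates collapse to a single retained feature", {
  n_final <- sapply(1:25, function(s) {
    d <- sim_logit(300, beta0 = 0, beta = rep(0, 4), seed = 700 + s)
    length(backward_eliminate(d$X, d$y, alpha = 0.05)$selected)
  })
  expect_gt(mean(n_final == 1L), 0.7)
})

test_that("q-delta prediction is the inverse-logit formula with >= threshold ties to high", {
  m <- structure(list(intercept = -2, coefficients = c(a = 0.05, b = -0.01),
                      feature_names = c("a", "b"), decision_threshold = 0.5,
                      penalty = 0, separation = FALSE, n_train = 50L),
                 class = "qdelta_model")
  set.seed(51)
  X <- data.frame(a = rnorm(50, 40, 20), b = rnorm(50, 40, 20))
  pr <- predict_qdelta(m, X)
  manual <- 1 / (1 + exp(-(-2 + 0.05 * X$a - 0.01 * X$b)))
  expect_equal(pr$prob_high, manual, tolerance = 1e-12)
  expect_equal(pr$qdelta_class, ifelse(manual >= 0.5, "high", "low"))

  # exactly at the boundary: probability = threshold, class high
  xb <- data.frame(a = 40, b = 0)  # eta = 0 -> p = 0.5
  prb <- predict_qdelta(m, xb)
  expect_equal(prb$prob_high, 0.5)
  expect_equal(prb$qdelta_class, "high")

  # null model: probability 0.5 everywhere
  m0 <- structure(list(intercept = 0, coefficients = c(a = 0, b = 0),
                       feature_names = c("a", "b"), decision_threshold = 0.5,
                       penalty = 0, separation = FALSE, n_train = 50L),
                  class = "qdelta_model")
  expect_true(all(predict_qdelta(m0, X)$prob_high == 0.5))

  expect_error(predict_qdelta(m, data.frame(a = 1)), "missing feature")
})

test_that("probability is monotone in a feature with positive coefficient", {
  d <- sim_logit(500, beta0 = -2, beta = c(0.06, 0.03), seed = 61)
  m <- fit_qdelta(d$X, d$y)
  expect_gt(m$coefficients[["x1"]], 0)
  grid <- data.frame(x1 = seq(0, 100, by = 5), x2 = 50)
  p <- predict_qdelta(m, grid)$prob_high
  expect_true(all(diff(p) > 0))
})

test_that("model serialization round-trips predictions exactly", {
  d <- sim_logit(200, beta0 = -1.5, beta = c(0.05, -0.02), seed = 71)
  m <- fit_qdelta(d$X, d$y)
  path <- tempfile(fileext = ".json")
  write_qdelta_model(m, path)
  m2 <- read_qdelta_model(path)
  set.seed(72)
  Xnew <- data.frame(x1 = rnorm(100, 50, 20), x2 = rnorm(100, 50, 20))
  expect_identical(predict_qdelta(m, Xnew), predict_qdelta(m2, Xnew))
  unlink(path)
})

test_that("deterministic threshold labels are ranked perfectly by the fit", {
  set.seed(81)
  x1 <- rnorm(100, 50, 15)
  x2 <- rnorm(100, 50, 15)
  y <- as.integer(x1 > 55)
  m <- fit_qdelta(data.frame(ne_ar_npp = x1, ne_pv_npp = x2), y)
  expect_true(m$separation)  # a deterministic rule separates the classes
  r <- roc_analysis(predict_qdelta(m, data.frame(ne_ar_npp = x1,
                                                 ne_pv_npp = x2))$prob_high, y)
  expect_equal(r$auc, 1.0)
})
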