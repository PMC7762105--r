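# Internal logistic-regression machinery shared by the classifier module.
# Maximum-likelihood fits go through stats::glm; when (quasi-)complete
# separation or non-convergence is detected the fit is repeated with a weak
# ridge penalty (lambda = 1e-6 on the slopes, not the intercept) by damped
# Newton iterations, and the result is flagged rather than failing silently.

.RIDGE_LAMBDA <- 1e-6

# Fit y ~ X (X without intercept column). Returns coefficients (intercept
# first), standard errors, Wald p-values, log-likelihood, separation flag.
fit_logistic <- function(X, y, penalty_on_separation = TRUE) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class (degenerate-label error)",
         call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("feature/label length mismatch",
                                 call. = FALSE)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  form <- as.formula(paste("`.y` ~", paste(sprintf("`%s`", colnames(X)),
                                           collapse = " + ")))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separated <- sep_warned || !fit$converged ||
    any(abs(coef(fit)[-1]) * apply(X, 2, sd) > 30)
  if (separated && penalty_on_separation) {
    rf <- ridge_logistic(X, y, lambda = .RIDGE_LAMBDA)
    return(list(coefficients = rf$coefficients, se = rf$se,
                wald_p = rf$wald_p, fitted = rf$fitted,
                loglik = rf$loglik, separation = TRUE,
                penalty = .RIDGE_LAMBDA))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = coef(fit),
       se = sm[, "Std. Error"],
       wald_p = sm[, "Pr(>|z|)"],
       fitted = fit$fitted.values,
       loglik = as.numeric(logLik(fit)),
       separation = separated,
       penalty = 0)
}

# Damped-Newton ridge logistic regression; penalty lambda/2 * sum(beta^2)
# over slopes only.
ridge_logistic <- function(X, y, lambda = .RIDGE_LAMBDA, max_iter = 200L,
                           tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  obj <- function(b) {
    eta <- drop(X1 %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * lambda * sum(b[-1]^2)
  }
  cur <- obj(beta)
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X1 * w, X1) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # step halving
    lam <- 1
    repeat {
      cand <- beta + lam * step
      val <- obj(cand)
      if (val >= cur - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta_new <- beta + lam * step
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; cur <- val; break }
    beta <- beta_new
    cur <- val
  }
  eta <- drop(X1 %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X1 * w, X1) + pen
  se <- sqrt(diag(tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, p, p)
  })))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X1)
  list(coefficients = beta, se = se,
       wald_p = 2 * pnorm(-abs(z)),
       fitted = mu,
       loglik = sum(y * eta - log1p(exp(eta))),
       separation = TRUE, penalty = lambda)
}
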