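#' Univariate logistic screen of one NE feature
#'
#' Single-predictor maximum-likelihood logistic regression of the delta
#' class on one normalized-enhancement feature, with the ROC of the fitted
#' probabilities. Complete separation is flagged and handled by a weak
#' ridge-penalized refit rather than failing.
#'
#' @param feature numeric vector of NE percentages.
#' @param labels binary class labels ("high"/"low" or 0/1).
#' @return list with `coefficient`, `se`, `wald_p` (for the feature term),
#'   `intercept`, `separation`, and `roc` (a [roc_analysis()] result on the
#'   fitted probabilities).
#' @export
fit_univariate <- function(feature, labels) {
  y <- as_binary_labels(labels)
  if (length(feature) < 10L) stop("need n >= 10", call. = FALSE)
  X <- matrix(feature, ncol = 1, dimnames = list(NULL, "feature"))
  f <- fit_logistic(X, y)
  list(coefficient = unname(f$coefficients["feature"]),
       se = unname(f$se["feature"]),
       wald_p = unname(f$wald_p["feature"]),
       intercept = unname(f$coefficients["(Intercept)"]),
       separation = f$separation,
       roc = roc_analysis(f$fitted, y))
}

#' Backward elimination over candidate NE features
#'
#' Iteratively refits the multivariate logistic model, removing the feature
#' with the largest p-value while that p-value exceeds `alpha`; stops when
#' all remaining features have p <= `alpha` or only one remains. Wald tests
#' are the default; likelihood-ratio tests (each feature dropped in turn)
#' are available via `test = "lr"`. With untied p-values the result does not
#' depend on column order; exact ties are broken by the current column
#' order (first column wins retention).
#'
#' @param features data.frame or matrix of candidate features (>= 2 columns).
#' @param labels binary class labels.
#' @param alpha retention threshold on the per-feature p-value.
#' @param test `"wald"` or `"lr"`.
#' @return list with `selected` (character vector of retained features) and
#'   `removed` (data.frame logging `step`, `feature`, `p_value`).
#' @export
backward_eliminate <- function(features, labels, alpha = 0.05,
                               test = c("wald", "lr")) {
  test <- match.arg(test)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 candidate features", call. = FALSE)
  y <- as_binary_labels(labels)
  vars <- colnames(X)
  log_step <- list()
  step <- 0L
  repeat {
    f <- tryCatch(fit_logistic(X[, vars, drop = FALSE], y),
                  error = function(e) e)
    if (inherits(f, "error")) {
      stop("elimination failed at step ", step + 1L, ": ",
           conditionMessage(f), call. = FALSE)
    }
    pvals <- if (test == "wald") {
      f$wald_p[vars]
    } else {
      vapply(vars, function(v) {
        keep <- setdiff(vars, v)
        ll0 <- if (length(keep) == 0L) {
          p0 <- mean(y)
          sum(y * log(p0) + (1 - y) * log(1 - p0))
        } else {
          fit_logistic(X[, keep, drop = FALSE], y)$loglik
        }
        pchisq(2 * (f$loglik - ll0), df = 1, lower.tail = FALSE)
      }, numeric(1))
    }
    worst <- which.max(pvals)
    if (length(vars) == 1L || pvals[worst] <= alpha) break
    step <- step + 1L
    log_step[[step]] <- data.frame(step = step, feature = vars[worst],
                                   p_value = unname(pvals[worst]),
                                   stringsAsFactors = FALSE)
    vars <- setdiff(vars, vars[worst])
  }
  removed <- if (length(log_step)) {
    do.call(rbind, log_step)
  } else {
    data.frame(step = integer(), feature = character(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  list(selected = vars, removed = removed, test = test, alpha = alpha)
}

#' Fit the q-delta multivariate logistic model
#'
#' Maximum-likelihood logistic regression of the delta class on the selected
#' NE features (in routine use, the parenchyma-referenced AR and PV
#' features). The fitted model predicts the most likely class at the
#' decision threshold (default 0.5). Separation triggers a flagged
#' weak-ridge refit.
#'
#' @param features data.frame or matrix of NE features (columns named).
#' @param labels binary class labels.
#' @param decision_threshold probability cutoff in (0, 1) for calling a
#'   tumor "high".
#' @return Object of class `qdelta_model`: `intercept`, `coefficients`
#'   (named), `feature_names`, `decision_threshold`, `penalty`,
#'   `separation`, `n_train`.
#' @export
fit_qdelta <- function(features, labels, decision_threshold = 0.5) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("feature columns must be named",
                                 call. = FALSE)
  y <- as_binary_labels(labels)
  if (nrow(X) < 20L) stop("need n >= 20 to train the q-delta model",
                          call. = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("`decision_threshold` must be in (0, 1)", call. = FALSE)
  }
  f <- fit_logistic(X, y)
  structure(list(
    intercept = unname(f$coefficients["(Intercept)"]),
    coefficients = f$coefficients[colnames(X)],
    feature_names = colnames(X),
    decision_threshold = decision_threshold,
    penalty = f$penalty,
    separation = f$separation,
    se = f$se[colnames(X)],
    wald_p = f$wald_p[colnames(X)],
    n_train = nrow(X)
  ), class = "qdelta_model")
}

#' Predict the q-delta class
#'
#' Evaluates the model's probability formula
#' `p = plogis(intercept + sum(coef * feature))` and assigns "high" when the
#' probability is >= the decision threshold (ties to "high").
#'
#' @param model a [fit_qdelta()] model.
#' @param features an `ne_features` object, or a data.frame/matrix carrying
#'   the model's feature columns.
#' @return data.frame with `prob_high` and `qdelta_class`.
#' @export
predict_qdelta <- function(model, features) {
  if (!inherits(model, "qdelta_model")) {
    stop("`model` must be a qdelta_model", call. = FALSE)
  }
  if (inherits(features, "ne_features")) {
    features <- as.data.frame(features)
  }
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  eta <- model$intercept + drop(X %*% model$coefficients)
  prob <- plogis(eta)
  data.frame(prob_high = prob,
             qdelta_class = ifelse(prob >= model$decision_threshold,
                                   "high", "low"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a q-delta model as JSON
#'
#' The JSON carries the feature names, intercept, coefficients, decision
#' threshold, ridge penalty (0 for a plain ML fit) and training size, so a
#' restored model reproduces predictions exactly.
#'
#' @param model a `qdelta_model`.
#' @param path output (input) JSON path.
#' @return `write_qdelta_model()` returns `path` invisibly;
#'   `read_qdelta_model()` returns the restored `qdelta_model`.
#' @export
write_qdelta_model <- function(model, path) {
  if (!inherits(model, "qdelta_model")) {
    stop("`model` must be a qdelta_model", call. = FALSE)
  }
  payload <- list(
    feature_names = model$feature_names,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    decision_threshold = model$decision_threshold,
    penalty = model$penalty,
    separation = model$separation,
    n_train = model$n_train
  )
  # 17 significant digits so coefficients survive the decimal round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qdelta_model
#' @export
read_qdelta_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = p$intercept,
    coefficients = setNames(unlist(p$coefficients), names(p$coefficients)),
    feature_names = p$feature_names,
    decision_threshold = p$decision_threshold,
    penalty = p$penalty,
    separation = isTRUE(p$separation),
    n_train = p$n_train
  ), class = "qdelta_model")
}

#' @export
print.qdelta_model <- function(x, ...) {
  cat("q-delta logistic model (n =", x$n_train, ")\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (nm in x$feature_names) {
    cat(sprintf("  %s: %.4f\n", nm, x$coefficients[[nm]]))
  }
  cat("  decision threshold:", x$decision_threshold, "\n")
  if (isTRUE(x$separation)) {
    cat("  NOTE: separation detected; weak ridge penalty applied\n")
  }
  invisible(x)
}
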