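#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac12 \log |I(\beta)|}
#' by iteratively reweighted least squares with the hat-diagonal-adjusted
#' score \eqn{U^*(\beta) = X^\top\{y - \pi + h(\tfrac12 - \pi)\}}, where
#' \eqn{h} are the diagonal elements of the penalized-regression hat matrix.
#' The penalty keeps every coefficient finite even under complete
#' separation and reduces the small-sample bias of maximum likelihood.
#' Step-halving guards against decreases in the penalized likelihood.
#'
#' @param x Design matrix (n x p) including the intercept column.
#' @param y Binary outcome vector of length n.
#' @param tolerance Convergence criterion: maximum absolute component of the
#'   modified score.
#' @param max_iterations Iteration cap; exceeding it yields a result flagged
#'   `converged = FALSE`, not an error.
#' @return An object of class `firth_fit` with components `coefficients`,
#'   `vcov` (inverse penalized Fisher information at the maximum), `loglik`
#'   (penalized), `converged`, `iterations`, `n`, `p`.
#' @examples
#' x <- cbind(1, c(rep(0, 5), rep(1, 5)))
#' y <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
#' fit <- fit_firth(x, y)
#' coef(fit)
#' @export
fit_firth <- function(x, y, tolerance = 1e-6, max_iterations = 50L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) abort("`x` and `y` have incompatible dimensions.")
  if (anyNA(x) || anyNA(y)) abort("Missing values must be imputed upstream.")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (0/1).")
  if (n < p) abort("More parameters than observations.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p) - 1L)
  qr_x <- qr(x)
  if (qr_x$rank < p) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):p]]
    abort(sprintf("Design matrix is rank deficient; collinear columns: %s.",
                  paste(dropped, collapse = ", ")))
  }

  beta <- rep(0, p)
  ll <- firth_loglik(x, y, beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(x %*% beta)
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(x * w, x)
    inv_info <- chol2inv(chol(info))
    h <- rowSums((x %*% inv_info) * x) * w
    score <- drop(crossprod(x, y - pi + h * (0.5 - pi)))
    if (max(abs(score)) <= tolerance) {
      converged <- TRUE
      break
    }
    if (iter >= max_iterations) break
    iter <- iter + 1L
    delta <- drop(inv_info %*% score)
    # step-halving on penalized-likelihood decrease
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_cand <- firth_loglik(x, y, cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    ll <- firth_loglik(x, y, beta)
  }

  pi <- plogis(drop(x %*% beta))
  info <- crossprod(x * (pi * (1 - pi)), x)
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(
    list(
      coefficients = setNames(beta, colnames(x)),
      vcov = vcov,
      loglik = firth_loglik(x, y, beta),
      converged = converged,
      iterations = iter,
      n = n,
      p = p
    ),
    class = "firth_fit"
  )
}

#' Penalized log-likelihood of the Firth logistic model
#'
#' @param x Design matrix, `y` binary outcomes, `beta` coefficient vector.
#' @param y,beta See above.
#' @return The scalar \eqn{\ell(\beta) + \frac12 \log|I(\beta)|}.
#' @export
firth_loglik <- function(x, y, beta) {
  eta <- drop(as.matrix(x) %*% beta)
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  w <- plogis(eta) * (1 - plogis(eta))
  info <- crossprod(as.matrix(x) * w, as.matrix(x))
  ld <- determinant(info, logarithm = TRUE)
  ll + 0.5 * as.numeric(ld$modulus)
}

#' Firth logistic regression with a formula interface
#'
#' Data-frame-first wrapper around [fit_firth()]. Categorical covariates
#' enter as reference-coded indicators (the first factor level is the
#' reference; the feature pipeline orders `solid_component` with `none`
#' first and `locularity` with `absent` first).
#'
#' @param data A data frame containing the outcome and covariates.
#' @param formula Model formula, e.g. `outcome ~ age + log_ca125`.
#' @param ... Passed to [fit_firth()].
#' @return A `firth_fit` with the `terms` object attached for prediction.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 300, seed = 11))
#' feats <- build_features(cohort)
#' firth_logit(feats, outcome ~ age + log_ca125)
#' @export
firth_logit <- function(data, formula, ...) {
  mf <- stats::model.frame(formula, data = prepare_model_data(data),
                           na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- model.matrix(attr(mf, "terms"), mf)
  colnames(x)[colnames(x) == "(Intercept)"] <- "(Intercept)"
  fit <- fit_firth(x, y, ...)
  fit$terms <- attr(mf, "terms")
  fit$formula <- formula
  fit
}

# Order the categorical features so reference coding has the clinically
# neutral level as baseline.
prepare_model_data <- function(data) {
  if ("solid_component" %in% names(data) &&
      !is.factor(data$solid_component)) {
    data$solid_component <- factor(data$solid_component,
                                   levels = c("none", "unilateral",
                                              "bilateral"))
  }
  if ("locularity" %in% names(data) && !is.factor(data$locularity)) {
    data$locularity <- factor(data$locularity,
                              levels = c("absent", "present"))
  }
  data
}

#' Predicted risks from logistic-model coefficients
#'
#' Inverse-logit of the linear predictor; strictly inside (0, 1).
#'
#' @param coefficients Named or plain coefficient vector (intercept first).
#' @param x Feature matrix with columns matching the coefficients.
#' @return Numeric vector of risks.
#' @examples
#' predict_risk(c(log(9)), matrix(1, 2, 1))
#' @export
predict_risk <- function(coefficients, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(coefficients)) {
    abort("Coefficient and feature dimensions disagree.")
  }
  plogis(drop(x %*% coefficients))
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
vcov.firth_fit <- function(object, ...) object$vcov

#' @export
predict.firth_fit <- function(object, newdata, ...) {
  if (is.null(object$terms)) {
    abort("Fit has no terms; use `predict_risk()` with a design matrix.")
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, data = prepare_model_data(newdata),
                           na.action = stats::na.fail)
  x <- model.matrix(tt, mf)
  predict_risk(object$coefficients, x)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic regression\n")
  cat(sprintf("  n = %d, p = %d, converged: %s (%d iterations)\n",
              x$n, x$p, x$converged, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_firth
#' @param x,object A `firth_fit`.
#' @param ... Unused.
#' @export
tidy.firth_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat)))
  )
}

#' @rdname fit_firth
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, converged = x$converged,
    iterations = x$iterations, nobs = x$n, df = x$p
  )
}
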