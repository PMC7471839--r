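#' Multiple imputation by chained equations
#'
#' Fills missing values by cycling conditional models over the incomplete
#' columns: continuous variables by predictive mean matching (a Bayesian
#' linear-regression draw followed by sampling one of the 5 nearest observed
#' donors), categorical variables by a multinomial draw from a fitted
#' multinomial logit ([nnet::multinom()]). Each of the `m` completed copies
#' comes from an independent chain; everything is deterministic given
#' `seed`. Observed cells are never altered, and categorical imputations
#' can only take values observed in the data.
#'
#' @param data A data frame; columns with missing values are imputed, all
#'   others (including the outcome, deliberately) serve as predictors.
#' @param m Number of completed datasets.
#' @param iterations Gibbs iterations per chain.
#' @param seed Integer seed.
#' @param predictors Optional character vector restricting the predictor
#'   set; defaults to every column other than `exclude`.
#' @param exclude Columns to leave out of both roles (identifiers, labels).
#' @param donors Donor-pool size for predictive mean matching.
#' @return An object of class `imputation_set`: a list with `imputations`
#'   (list of `m` completed tibbles), `m`, `iterations`, `seed`,
#'   `imputed_variables` and `predictors`.
#' @examples
#' df <- tibble::tibble(y = rnorm(50), x = rnorm(50), out = rbinom(50, 1, .3))
#' df$x[1:10] <- NA
#' chained_impute(df, m = 2, iterations = 3, seed = 1)
#' @export
chained_impute <- function(data, m = 20L, iterations = 10L, seed = 1L,
                           predictors = NULL, exclude = character(),
                           donors = 5L) {
  stopifnot(is.data.frame(data), m >= 1, iterations >= 1)
  work_cols <- setdiff(names(data), exclude)
  target_cols <- work_cols[vapply(data[work_cols], anyNA, logical(1))]
  fully_missing <- target_cols[
    vapply(data[target_cols], function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing) > 0) {
    abort(sprintf("Cannot impute entirely missing column(s): %s.",
                  paste(fully_missing, collapse = ", ")))
  }
  predictors <- predictors %||% work_cols
  complete_preds <- setdiff(predictors, exclude)
  if (length(setdiff(complete_preds, target_cols)) == 0 &&
      length(target_cols) > 0) {
    abort("At least one fully observed predictor is required.")
  }

  out <- structure(
    list(imputations = NULL, m = as.integer(m),
         iterations = as.integer(iterations), seed = as.integer(seed),
         imputed_variables = target_cols,
         predictors = complete_preds),
    class = "imputation_set"
  )
  if (length(target_cols) == 0) {
    out$imputations <- replicate(m, tibble::as_tibble(data), simplify = FALSE)
    return(out)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  miss_idx <- lapply(data[target_cols], function(x) which(is.na(x)))
  out$imputations <- lapply(seq_len(m), function(chain) {
    set.seed(derive_seed(seed, chain))
    imp <- data
    # initialize by sampling observed values
    for (v in target_cols) {
      obs <- imp[[v]][!is.na(imp[[v]])]
      imp[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                        replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in target_cols) {
        mis <- miss_idx[[v]]
        if (length(mis) == 0) next
        preds <- setdiff(complete_preds, v)
        imp[[v]][mis] <- impute_one(
          y = data[[v]], current = imp[[v]],
          x = imp[preds], mis = mis, donors = donors
        )
      }
    }
    tibble::as_tibble(imp)
  })
  out
}

# one Gibbs update for a single variable
impute_one <- function(y, current, x, mis, donors) {
  obs <- which(!is.na(y))
  xm <- model.matrix(~ ., data = as.data.frame(x))
  if (is.numeric(y)) {
    pmm_draw(y, xm, obs, mis, donors)
  } else {
    categorical_draw(y, x, obs, mis)
  }
}

# predictive mean matching with a Bayesian regression draw (donor pool 5)
pmm_draw <- function(y, xm, obs, mis, donors) {
  x_obs <- xm[obs, , drop = FALSE]
  keep <- qr(x_obs)$rank
  if (keep < ncol(x_obs)) {
    qx <- qr(x_obs)
    cols <- qx$pivot[seq_len(qx$rank)]
    x_obs <- x_obs[, cols, drop = FALSE]
    xm <- xm[, cols, drop = FALSE]
  }
  fit <- lm.fit(x_obs, y[obs])
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(obs) - length(beta_hat), 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  xtx_inv <- chol2inv(chol(crossprod(x_obs) +
                             diag(1e-8, ncol(x_obs))))
  beta_star <- beta_hat + drop(chol(xtx_inv) %*% rnorm(length(beta_hat))) *
    sqrt(sigma2_star)
  yhat_obs <- drop(x_obs %*% beta_hat)
  yhat_mis <- drop(xm[mis, , drop = FALSE] %*% beta_star)
  vapply(yhat_mis, function(target) {
    pool <- order(abs(yhat_obs - target))[seq_len(min(donors, length(obs)))]
    y[obs][sample(pool, 1L)]
  }, numeric(1))
}

# multinomial draw restricted to observed categories
categorical_draw <- function(y, x, obs, mis) {
  df <- as.data.frame(x)
  df$.y <- factor(y)
  fit_df <- droplevels(df[obs, , drop = FALSE])
  levels_obs <- levels(fit_df$.y)
  if (length(levels_obs) == 1L) {
    return(rep(levels_obs, length(mis)))
  }
  capture.output(
    fit <- nnet::multinom(.y ~ ., data = fit_df, trace = FALSE, maxit = 200)
  )
  probs <- predict(fit, newdata = df[mis, , drop = FALSE], type = "probs")
  if (is.null(dim(probs))) {
    if (length(levels_obs) == 2L) {
      probs <- cbind(1 - probs, probs)
    } else {
      probs <- matrix(probs, nrow = 1)
    }
  }
  drawn <- apply(probs, 1L, function(p) sample(levels_obs, 1L, prob = p))
  as.character(drawn)
}

#' Impute missing ultrasound variables of a feature table
#'
#' Cohort-specific wrapper around [chained_impute()]: imputes the per-ovary
#' morphology categories (multinomial draws) and log volumes (predictive
#' mean matching, i.e. on the log scale) using age, ascites, the log
#' markers, the outcome and each other as predictors, then rebuilds the
#' derived features (solid component, locularity, log dominant volume) in
#' every completed copy so each is fully analysable.
#'
#' @param features Feature tibble from [build_features()].
#' @inheritParams chained_impute
#' @return An `imputation_set` whose `imputations` are completed feature
#'   tibbles.
#' @export
impute_cohort <- function(features, m = 20L, iterations = 10L, seed = 1L) {
  raw_cols <- c("morphology_left", "morphology_right",
                "log_volume_left", "log_volume_right")
  pred_cols <- c("age", "ascites_ml", "log_ca125", "log_he4", "outcome")
  set <- chained_impute(
    features[c(raw_cols, pred_cols)],
    m = m, iterations = iterations, seed = seed
  )
  set$imputations <- lapply(set$imputations, function(imp) {
    done <- features
    done[raw_cols] <- imp[raw_cols]
    refresh_derived_features(done)
  })
  set
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf(
    "Imputation set: m = %d, %d iteration(s), seed %d\n  imputed: %s\n",
    x$m, x$iterations, x$seed,
    if (length(x$imputed_variables)) paste(x$imputed_variables, collapse = ", ")
    else "(nothing was missing)"
  ))
  invisible(x)
}

#' Serialize an imputation set
#'
#' Writes the `m` completed tables as `imputation_01.csv`, ... plus a JSON
#' manifest (`manifest.json`) recording `m`, iterations, seed, imputed
#' variables and predictors.
#'
#' @param set An `imputation_set`.
#' @param dir Output directory (created if needed).
#' @return `read_imputation_set()` returns the reassembled set.
#' @export
write_imputation_set <- function(set, dir) {
  stopifnot(inherits(set, "imputation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(set$m)) {
    readr::write_csv(set$imputations[[i]],
                     file.path(dir, sprintf("imputation_%02d.csv", i)),
                     na = "")
  }
  manifest <- set[c("m", "iterations", "seed", "imputed_variables",
                    "predictors")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_imputation_set
#' @export
read_imputation_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  imputations <- lapply(seq_len(manifest$m), function(i) {
    readr::read_csv(file.path(dir, sprintf("imputation_%02d.csv", i)),
                    na = "", show_col_types = FALSE)
  })
  structure(
    c(list(imputations = imputations), manifest),
    class = "imputation_set"
  )
}

#' Pool per-imputation fits by Rubin's Rules
#'
#' Combines `m` repeated-analysis fits: the pooled estimate is the mean of
#' the per-imputation estimates, the within-imputation variance the mean of
#' the per-imputation variances, the between-imputation variance the sample
#' variance of the estimates, and the total variance
#' \eqn{T = \bar U + (1 + 1/m) B}. Degrees of freedom for inference use the
#' Barnard-Rubin small-sample formula when the complete-data degrees of
#' freedom are known.
#'
#' @param fits A list of at least two fits with identical covariate sets:
#'   either `firth_fit` objects or lists with elements `coefficients` and
#'   `vcov`.
#' @return An object of class `pooled_fit` with components `estimates`,
#'   `ubar`, `b`, `t` (per-covariate vectors), `m`, `df`.
#' @examples
#' f <- list(
#'   list(coefficients = c(a = 0), vcov = matrix(1)),
#'   list(coefficients = c(a = 2), vcov = matrix(1))
#' )
#' pool_rubin(f)$t
#' @export
pool_rubin <- function(fits) {
  if (!is.list(fits) || length(fits) < 2) {
    abort("Rubin pooling needs at least two per-imputation fits.")
  }
  coefs <- lapply(fits, function(f) {
    if (inherits(f, "firth_fit")) f$coefficients else f$coefficients
  })
  nm <- names(coefs[[1]])
  same <- vapply(coefs, function(cf) identical(names(cf), nm), logical(1))
  if (!all(same)) abort("Per-imputation fits have mismatched covariate sets.")
  m <- length(fits)
  q <- do.call(cbind, coefs)
  u <- do.call(cbind, lapply(fits, function(f) diag(as.matrix(f$vcov))))
  qbar <- rowMeans(q)
  ubar <- rowMeans(u)
  b <- apply(q, 1L, var)
  t <- ubar + (1 + 1 / m) * b

  n <- tryCatch(fits[[1]]$n, error = function(e) NULL)
  p <- length(qbar)
  riv <- (1 + 1 / m) * b / ubar
  df <- ifelse(riv > 0, (m - 1) * (1 + 1 / riv)^2, Inf)
  if (!is.null(n) && length(n) == 1 && is.finite(n)) {
    # Barnard-Rubin small-sample adjustment
    nu_com <- n - p
    lambda <- (1 + 1 / m) * b / t
    df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    df <- ifelse(is.finite(df), 1 / (1 / df + 1 / df_obs), df_obs)
  }
  structure(
    list(estimates = setNames(qbar, nm), ubar = setNames(ubar, nm),
         b = setNames(b, nm), t = setNames(t, nm), m = m,
         df = setNames(df, nm)),
    class = "pooled_fit"
  )
}

#' @export
coef.pooled_fit <- function(object, ...) object$estimates

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Rubin-pooled fit over m = %d imputations\n", x$m))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @rdname pool_rubin
#' @param x A `pooled_fit`.
#' @param ... Unused.
#' @export
tidy.pooled_fit <- function(x, ...) {
  se <- sqrt(x$t)
  stat <- x$estimates / se
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(se),
    statistic = unname(stat),
    df = unname(x$df),
    p.value = 2 * pt(-abs(unname(stat)), df = unname(x$df))
  )
}

#' @rdname pool_rubin
#' @export
glance.pooled_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    mean_riv = mean((1 + 1 / x$m) * x$b / x$ubar),
    max_fmi = max((1 + 1 / x$m) * x$b / x$t)
  )
}
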