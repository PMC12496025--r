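#' Linear probability model with absorbed fixed effects and cluster-robust
#' covariance
#'
#' Least squares on a binary (or count) outcome with a high-dimensional group
#' intercept absorbed by within-group demeaning, and a cluster sandwich
#' covariance.  This is the estimation core shared by every policy-evaluation
#' specification in the package.
#'
#' The covariance is `bread %*% meat %*% bread` with
#' `meat = sum_g (X_g' u_g)(X_g' u_g)'` assembled cluster by cluster.  With
#' `vcov_type = "CR1"` (default) the small-sample factor
#' `G/(G-1) * (N-1)/(N-K)` is applied, where `K` counts the regression
#' columns plus the absorbed group intercepts; `"CR0"` applies no
#' correction.  Reported p-values use a t distribution with `G - 1` degrees
#' of freedom, the conventional choice when one arm of the design has few
#' clusters.
#'
#' Columns that are collinear after the within transformation (including
#' regressors constant within groups, such as a country dummy when hospital
#' effects are absorbed) raise an error naming the offending columns rather
#' than being dropped silently.
#'
#' @param data A data frame.
#' @param formula One-sided or two-sided formula for outcome and regressors,
#'   e.g. `bundle_met ~ att + fy_f + covariates...`.  Factor regressors use
#'   their first level as reference.
#' @param fe Name of the column whose levels are absorbed as fixed effects,
#'   or `NULL` for plain (intercept) least squares.
#' @param cluster Name of the clustering column (default: the `fe` column,
#'   or required explicitly when `fe` is `NULL`).
#' @param vcov_type `"CR1"` or `"CR0"`.
#' @return An object of class `"cb_fit"`: coefficient table, covariance
#'   matrix, observation/cluster counts, within-R-squared, and the count of
#'   singleton groups (retained; they contribute no within variation).
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.5), x = rnorm(100),
#'                 h = rep(letters[1:5], each = 20))
#' fit_fe_lpm(d, y ~ x, fe = "h")
#' @export
fit_fe_lpm <- function(data, formula, fe = "hospital", cluster = fe,
                       vcov_type = c("CR1", "CR0")) {
  vcov_type <- match.arg(vcov_type)
  if (is.null(cluster)) abort("a `cluster` column is required")
  data <- as.data.frame(data)
  for (v in all.vars(formula)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  g_cl <- factor(data[[cluster]])
  G <- nlevels(g_cl)
  if (G < 2) abort("need at least 2 clusters")
  N <- length(y)

  n_fe <- 0L; singletons <- 0L
  if (!is.null(fe)) {
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    g_fe <- factor(data[[fe]])
    n_fe <- nlevels(g_fe)
    cnt <- tabulate(g_fe)
    singletons <- sum(cnt == 1L)
    demean <- function(M) M - (rowsum(M, g_fe) / cnt)[as.integer(g_fe), , drop = FALSE]
    Xd <- demean(X)
    yd <- as.numeric(y - (rowsum(y, g_fe) / cnt)[as.integer(g_fe)])
  } else {
    Xd <- X
    yd <- as.numeric(y)
  }

  qrX <- qr(Xd)
  K <- ncol(Xd)
  if (qrX$rank < K) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):K]]
    abort(paste0("design matrix is rank deficient after the within transformation; ",
                 "collinear columns: ", paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, yd)
  u <- yd - as.numeric(Xd %*% beta)

  # (X'X)^{-1} with column pivoting: X P = QR  =>  (X'X)^{-1} = P (R'R)^{-1} P'
  o <- order(qrX$pivot)
  bread <- chol2inv(qr.R(qrX))[o, o, drop = FALSE]
  scores <- rowsum(Xd * u, g_cl)
  meat <- crossprod(scores)
  K_tot <- K + n_fe
  adj <- switch(vcov_type,
                CR1 = (G / (G - 1)) * ((N - 1) / (N - K_tot)),
                CR0 = 1)
  V <- adj * (bread %*% meat %*% bread)
  dimnames(V) <- list(names(beta), names(beta))

  se <- sqrt(diag(V))
  tstat <- beta / se
  df <- G - 1
  coefs <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    statistic = unname(tstat),
    p.value = 2 * pt(-abs(unname(tstat)), df)
  )
  tss <- sum((yd - mean(yd))^2)
  structure(list(coefficients = coefs, vcov = V, nobs = N, n_clusters = G,
                 df = df, k = K, k_absorbed = n_fe, singletons = singletons,
                 r2_within = if (tss > 0) 1 - sum(u^2) / tss else NA_real_,
                 outcome = deparse(formula[[2]]), fe = fe, cluster = cluster,
                 vcov_type = vcov_type, formula = formula),
            class = "cb_fit")
}

#' @export
print.cb_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects LPM: %s (%s clustered SEs, %d obs, %d clusters%s)\n",
              x$outcome, x$vcov_type, x$nobs, x$n_clusters,
              if (!is.null(x$fe)) paste0(", FE: ", x$fe) else ""))
  print(x$coefficients, n = 20)
  invisible(x)
}

#' @export
coef.cb_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.cb_fit <- function(object, ...) object$vcov

#' Tidy a fitted policy model
#'
#' @param x A `cb_fit` object.
#' @param conf.int Add a confidence interval (t critical values with
#'   `G - 1` degrees of freedom)?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @method tidy cb_fit
#' @export
tidy.cb_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$coefficients
  if (conf.int) {
    crit <- stats::qt(1 - (1 - conf.level) / 2, x$df)
    out$conf.low <- out$estimate - crit * out$std.error
    out$conf.high <- out$estimate + crit * out$std.error
  }
  out
}

#' One-row model summary
#'
#' @param x A `cb_fit` object.
#' @param ... Unused.
#' @method glance cb_fit
#' @export
glance.cb_fit <- function(x, ...) {
  tibble::tibble(nobs = x$nobs, n_clusters = x$n_clusters, df = x$df,
                 r2_within = x$r2_within, singletons = x$singletons,
                 vcov_type = x$vcov_type)
}

#' Wald joint test on a set of coefficients
#'
#' Tests the joint null that the named coefficients are all zero, using the
#' cluster-robust covariance.  Reports the chi-square statistic with both its
#' asymptotic chi-square p-value and an F p-value on `(q, G - 1)` degrees of
#' freedom (statistic / q against F), the latter being the more reliable
#' reference with few clusters.
#'
#' @param fit A `cb_fit`.
#' @param terms Character vector of coefficient names.
#' @return A one-row tibble: `statistic`, `df`, `p.value` (F-based),
#'   `p.chisq`.
#' @export
wald_joint <- function(fit, terms) {
  miss <- setdiff(terms, fit$coefficients$term)
  if (length(miss)) abort(paste("unknown coefficients:", paste(miss, collapse = ", ")))
  b <- coef(fit)[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    abort("singular subcovariance in joint test"))
  stat <- as.numeric(t(b) %*% Vi %*% b)
  q <- length(terms)
  tibble::tibble(statistic = stat, df = q,
                 p.value = pf(stat / q, q, fit$df, lower.tail = FALSE),
                 p.chisq = pchisq(stat, q, lower.tail = FALSE))
}

#' Linear combination of coefficients
#'
#' Estimate and cluster-robust standard error of `sum(w * beta[terms])`,
#' e.g. the summed pre-trend deviations reported alongside the joint test.
#'
#' @param fit A `cb_fit`.
#' @param terms Coefficient names.
#' @param weights Combination weights (default 1 for each term).
#' @return A one-row tibble with `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
lin_comb <- function(fit, terms, weights = rep(1, length(terms))) {
  b <- coef(fit)[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  est <- sum(weights * b)
  se <- sqrt(as.numeric(t(weights) %*% V %*% weights))
  tstat <- est / se
  tibble::tibble(estimate = est, std.error = se, statistic = tstat,
                 p.value = 2 * pt(-abs(tstat), fit$df))
}
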