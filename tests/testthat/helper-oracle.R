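# Independent brute-force OLS oracle: explicit normal equations and the
# textbook formulas for se, t, p, R^2, sigma-hat and F. Deliberately avoids
# lm()/qr-based shortcuts so it can serve as a cross-check of the fitting
# code.
ols_oracle <- function(X, y) {
  dimnames(X) <- NULL
  n <- length(y)
  p <- ncol(X)
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% (t(X) %*% y))
  res <- y - drop(X %*% beta)
  sse <- sum(res^2)
  df <- n - p
  s2 <- sse / df
  se <- sqrt(s2 * diag(XtXinv))
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  f <- (r2 / (p - 1)) / ((1 - r2) / df)
  list(coef = beta, se = se, tstat = tstat, pvalue = pval, r_squared = r2,
       sigma_hat = sqrt(s2), f_stat = f, df_resid = df)
}

# Design matrices for each model tag, built independently of the package.
oracle_design <- function(data, tag) {
  with(data, switch(tag,
    cusp = cbind(1, z1^3, z1^2, y * z1, x, y),
    linear_diff_1 = cbind(1, z1, x, y),
    linear_diff_2 = cbind(1, z1, y * z1, x, y),
    linear_pre_post_1 = cbind(1, z1, x, y),
    linear_pre_post_2 = cbind(1, z1, y * z1, x, y)
  ))
}

oracle_response <- function(data, tag) {
  if (tag %in% c("linear_pre_post_1", "linear_pre_post_2")) data$z2
  else data$dz
}

# Random observational dataset (no cusp structure imposed) for oracle
# comparisons.
random_dataset <- function(n, seed) {
  set.seed(seed)
  cusp_data(x = rnorm(n), y = rnorm(n), z1 = rnorm(n), dz = rnorm(n))
}

# Published four-scenario fitted specifications (coefficient estimates and
# residual sd), used as generating truths for sample-size back-calculation
# checks.
scenario_fitted_specs <- list(
  list(beta = c(0.487, 0.540, 0.456, 0.360, 0.563, 0.468), sigma = 1.053,
       n_expected = 36),
  list(beta = c(0.473, 0.581, 0.411, 0.221, 0.626, 0.435), sigma = 2.107,
       n_expected = 101),
  list(beta = c(0.459, 0.621, 0.367, 0.081, 0.689, 0.403), sigma = 3.160,
       n_expected = 195),
  list(beta = c(0.446, 0.661, 0.323, -0.058, 0.753, 0.371), sigma = 4.214,
       n_expected = 293)
)

# Published early-sexual-initiation example: coefficient vector and residual
# sd from the original modeling records.
sexual_initiation_spec <- list(
  beta = c(-0.0309, 0.0726, -0.4819, -0.1236, 0.0613, -0.2693),
  sigma = 0.5033, n_expected = 153
)
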