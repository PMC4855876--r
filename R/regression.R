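# Least-squares fitting of the cusp polynomial regression and the four
# alternative linear models, with classical t/F inference.

# Model registry: response and design-matrix term set for each model tag.
# Terms are built from the dataset columns; intercept always first.
cusp_model_terms <- function(tag) {
  switch(tag,
    cusp = list(response = "dz",
                terms = c("z1^3", "z1^2", "y:z1", "x", "y")),
    linear_diff_1 = list(response = "dz", terms = c("z1", "x", "y")),
    linear_diff_2 = list(response = "dz", terms = c("z1", "y:z1", "x", "y")),
    linear_pre_post_1 = list(response = "z2", terms = c("z1", "x", "y")),
    linear_pre_post_2 = list(response = "z2",
                             terms = c("z1", "y:z1", "x", "y")),
    stop("unknown model tag: ", tag, call. = FALSE)
  )
}

cusp_model_tags <- c("cusp", "linear_diff_1", "linear_diff_2",
                     "linear_pre_post_1", "linear_pre_post_2")

# Short aliases accepted from the command line / casual use.
resolve_model_tag <- function(which) {
  aliases <- c(cusp = "cusp", eq3 = "linear_diff_1", eq4 = "linear_diff_2",
               eq5 = "linear_pre_post_1", eq6 = "linear_pre_post_2")
  if (which %in% cusp_model_tags) return(which)
  if (which %in% names(aliases)) return(unname(aliases[which]))
  stop("unknown model: '", which, "' (expected one of ",
       paste(c(cusp_model_tags, names(aliases)[-1]), collapse = ", "), ")",
       call. = FALSE)
}

build_design_matrix <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    switch(tm,
      "z1^3" = data$z1^3,
      "z1^2" = data$z1^2,
      "y:z1" = data$y * data$z1,
      "z1" = data$z1,
      "x" = data$x,
      "y" = data$y,
      stop("unknown term: ", tm, call. = FALSE)
    )
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

# Rank check via relative singular values; names the columns implicated in
# the deficiency so the error message is actionable.
check_full_rank <- function(X, tol = 1e-10) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[length(d)] <= tol * d[1L]) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient (collinear columns: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

new_cusp_fit <- function(model_tag, coef, se, tstat, pvalue, r_squared,
                         sigma_hat, f_stat, df_model, df_resid, n,
                         lm_fit = NULL) {
  structure(
    list(model_tag = model_tag, coef = coef, se = se, tstat = tstat,
         pvalue = pvalue, r_squared = r_squared, sigma_hat = sigma_hat,
         f_stat = f_stat, df_model = df_model, df_resid = df_resid, n = n,
         lm = lm_fit),
    class = "cusp_fit"
  )
}

# Shared OLS engine behind the public fitting functions: builds the design,
# delegates the fit to stats::lm, and extracts the classical summaries.
ols_cusp_fit <- function(data, tag) {
  data <- as_cusp_data(data)
  mt <- cusp_model_terms(tag)
  p <- length(mt$terms) + 1L
  n <- nrow(data)
  if (n < p + 1L) {
    stop("insufficient observations: the ", tag, " model has ", p,
         " coefficients and needs n >= ", p + 1L, " (got n = ", n, ")",
         call. = FALSE)
  }
  X <- build_design_matrix(data, mt$terms)
  check_full_rank(X)
  yv <- data[[mt$response]]
  df_fit <- as.data.frame(X[, -1L, drop = FALSE])
  names(df_fit) <- paste0("V", seq_along(mt$terms))
  df_fit$.response <- yv
  fml <- stats::as.formula(paste(".response ~",
                                 paste(names(df_fit)[seq_along(mt$terms)],
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = df_fit)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- ct[, 1L]
  names(coefs) <- colnames(X)
  new_cusp_fit(
    model_tag = tag,
    coef = coefs,
    se = stats::setNames(ct[, 2L], colnames(X)),
    tstat = stats::setNames(ct[, 3L], colnames(X)),
    pvalue = stats::setNames(ct[, 4L], colnames(X)),
    r_squared = sm$r.squared,
    sigma_hat = sm$sigma,
    f_stat = unname(sm$fstatistic[1L]),
    df_model = p - 1L,
    df_resid = fit$df.residual,
    n = n,
    lm_fit = fit
  )
}

#' Fit the cusp catastrophe polynomial regression
#'
#' Regresses the change score \eqn{\Delta z = z_2 - z_1} on the design
#' \eqn{[1, z_1^3, z_1^2, y z_1, x, y]} by ordinary least squares. This is
#' Guastello's polynomial operationalization of the cusp catastrophe model:
#' the cubic term carries the folded equilibrium structure, the
#' \eqn{y z_1} interaction the bifurcation effect, and \eqn{x} the asymmetry
#' effect; the quadratic term and the main effect of \eqn{y} absorb
#' deviations of the data from the equilibrium surface. Inference is
#' classical: two-sided t tests on each coefficient with \eqn{n - 6} residual
#' degrees of freedom, and the overall F statistic with (5, n - 6) degrees of
#' freedom.
#'
#' @param data a [cusp_data()] frame (or a data frame with columns `x`, `y`,
#'   `z1` and `z2` and/or `dz`). Variables are used on the scale supplied;
#'   standardize observed data first (see [standardize()]).
#' @return An object of class `"cusp_fit"`: a list with elements `model_tag`,
#'   `coef`, `se`, `tstat`, `pvalue` (each a named length-6 vector, intercept
#'   first), `r_squared`, `sigma_hat` (residual standard deviation),
#'   `f_stat`, `df_model`, `df_resid`, `n`, and the underlying `lm` fit.
#' @seealso [fit_cusp_alternative()], [compare_cusp_models()],
#'   [detect_cusp()]
#' @examples
#' d <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1, n = 100),
#'                         seed = 42)
#' fit <- fit_cusp(d)
#' fit
#' detect_cusp(fit)
#' @export
fit_cusp <- function(data) {
  ols_cusp_fit(data, "cusp")
}

#' Fit one of the four alternative linear models
#'
#' The comparative-fit strategy for cusp regression pits the cusp polynomial
#' against four linear competitors built from the same variables: two
#' change-score models (`linear_diff_1`: \eqn{\Delta z} on \eqn{z_1, x, y};
#' `linear_diff_2`: adds the \eqn{y z_1} interaction) and two pre/post models
#' (`linear_pre_post_1`: \eqn{z_2} on \eqn{z_1, x, y}; `linear_pre_post_2`:
#' adds \eqn{y z_1}). A larger \eqn{R^2} for the cusp polynomial than for all
#' four is taken as supporting evidence that the dynamics are cusp rather
#' than linear.
#'
#' @inheritParams fit_cusp
#' @param which model tag: one of `"linear_diff_1"`, `"linear_diff_2"`,
#'   `"linear_pre_post_1"`, `"linear_pre_post_2"` (aliases `"eq3"` to
#'   `"eq6"` in the same order are accepted).
#' @return A `"cusp_fit"` object (see [fit_cusp()]); coefficient vectors have
#'   the model's own term count.
#' @export
fit_cusp_alternative <- function(data, which) {
  tag <- resolve_model_tag(which)
  if (tag == "cusp") {
    stop("`which` must name one of the alternative linear models; ",
         "use fit_cusp() for the cusp polynomial", call. = FALSE)
  }
  ols_cusp_fit(data, tag)
}

#' Fit the cusp model and all four linear alternatives
#'
#' Convenience wrapper running [fit_cusp()] and the four
#' [fit_cusp_alternative()] models on the same dataset, and reporting whether
#' the cusp polynomial attains the largest \eqn{R^2} (the comparative-fit
#' evidence rule).
#'
#' @inheritParams fit_cusp
#' @return An object of class `"cusp_model_comparison"`: list with `fits`
#'   (named list of five `"cusp_fit"` objects), `table` (data frame of model
#'   tag, number of terms, \eqn{R^2}, residual sd, F), and the logical flag
#'   `cusp_r2_dominates`.
#' @export
compare_cusp_models <- function(data) {
  data <- as_cusp_data(data)
  fits <- stats::setNames(
    lapply(cusp_model_tags, function(tag) ols_cusp_fit(data, tag)),
    cusp_model_tags
  )
  tab <- data.frame(
    model = cusp_model_tags,
    terms = vapply(fits, function(f) f$df_model, integer(1L)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1L)),
    sigma_hat = vapply(fits, function(f) f$sigma_hat, numeric(1L)),
    f_stat = vapply(fits, function(f) f$f_stat, numeric(1L)),
    row.names = NULL
  )
  dominates <- tab$r_squared[1L] > max(tab$r_squared[-1L])
  structure(list(fits = fits, table = tab,
                 cusp_r2_dominates = dominates),
            class = "cusp_model_comparison")
}

#' @export
print.cusp_fit <- function(x, ...) {
  cat("Cusp regression fit: model =", x$model_tag,
      sprintf("(n = %d)\n", x$n))
  tab <- data.frame(
    Estimate = x$coef, `Std.Error` = x$se, t = x$tstat,
    `p.value` = x$pvalue, ` ` = signif_stars(x$pvalue),
    check.names = FALSE
  )
  print(format(tab, digits = 4))
  cat(sprintf("R-squared = %.4f, residual sd = %.4f\n",
              x$r_squared, x$sigma_hat))
  cat(sprintf("F = %.4g on (%d, %d) df\n", x$f_stat, x$df_model,
              x$df_resid))
  cat("Signif. codes: '***' p<0.00001, '**' p<0.001, '*' p<0.01,",
      "'.' p<0.05\n")
  invisible(x)
}

#' @export
coef.cusp_fit <- function(object, ...) object$coef

#' @export
print.cusp_model_comparison <- function(x, ...) {
  cat("Comparative model fits (cusp polynomial vs linear alternatives)\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("cusp R-squared exceeds all alternatives:",
      if (x$cusp_r2_dominates) "yes" else "no", "\n")
  invisible(x)
}

# ---- fast path used by the Monte-Carlo power engine ------------------------
# Minimal OLS via Cholesky on the normal equations; returns NULL when the
# design is (numerically) rank deficient so the caller can redraw. Produces
# exactly the quantities the decision rule needs. Agreement with the
# lm()-backed fit_cusp() is covered by the test suite.
fast_cusp_pvalues <- function(x, y, z1, dz) {
  X <- cbind(1, z1^3, z1^2, y * z1, x, y)
  n <- length(dz)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  dch <- diag(ch)
  if (min(dch) <= 1e-8 * max(dch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, crossprod(X, dz), transpose = TRUE))
  res <- dz - drop(X %*% beta)
  df <- n - 6L
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(chol2inv(ch)))
  p <- 2 * stats::pt(abs(drop(beta) / se), df, lower.tail = FALSE)
  # order: (Intercept), z1^3, z1^2, y:z1, x, y
  list(coef = drop(beta), se = se, pvalue = p, df = df, sigma2 = s2)
}
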