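#' Specify a cusp polynomial regression study design
#'
#' A design bundles the generative truth used by the simulation engine: the
#' six regression effect sizes of the cusp polynomial model, the residual
#' noise level, and (optionally) the number of observations per simulated
#' dataset. The change score \eqn{\Delta z = z_2 - z_1} is generated as
#' \deqn{\Delta z = \beta_0 + \beta_1 z_1^3 + \beta_2 z_1^2 +
#'       \beta_3 y z_1 + \beta_4 x + \beta_5 y + \epsilon,
#'       \quad \epsilon \sim N(0, \sigma^2),}
#' with the asymmetry variable \eqn{x}, the bifurcation variable \eqn{y} and
#' the time-1 outcome \eqn{z_1} drawn independently from normal
#' distributions (standard normal by default, matching the convention that
#' all variables are standardized before a cusp regression analysis).
#'
#' @param beta numeric vector of length 6: effect sizes
#'   \eqn{(\beta_0, \beta_1, \beta_2, \beta_3, \beta_4, \beta_5)} for the
#'   intercept, cubic term \eqn{z_1^3}, quadratic term \eqn{z_1^2},
#'   bifurcation interaction \eqn{y z_1}, asymmetry variable \eqn{x} and
#'   bifurcation variable \eqn{y}, on the standardized-variable scale.
#' @param sigma residual standard deviation of the error term, > 0 for any
#'   stochastic use (0 is tolerated so noiseless exact-recovery checks can be
#'   expressed).
#' @param n observations per dataset, integer >= 1, or `NULL` when the design
#'   is used with a grid of sample sizes (as in [power_curve()]).
#' @param means,sds optional length-3 numeric vectors giving the means and
#'   standard deviations of \eqn{(x, y, z_1)}; default standard normal.
#' @return An object of class `"cusp_design"`.
#' @seealso [simulate_cusp_data()], [estimate_power()], [find_sample_size()]
#' @examples
#' cusp_design(beta = rep(0.5, 6), sigma = 1, n = 100)
#' @export
cusp_design <- function(beta, sigma, n = NULL, means = c(0, 0, 0),
                        sds = c(1, 1, 1)) {
  beta <- as.numeric(beta)
  if (length(beta) != 6L || any(!is.finite(beta))) {
    stop("`beta` must be a finite numeric vector of length 6 ",
         "(b0, b1, b2, b3, b4, b5)", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single finite number >= 0", call. = FALSE)
  }
  if (!is.null(n)) {
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
        n != round(n)) {
      stop("`n` must be a positive integer", call. = FALSE)
    }
    n <- as.integer(n)
  }
  means <- as.numeric(means)
  sds <- as.numeric(sds)
  if (length(means) != 3L || length(sds) != 3L || any(!is.finite(means)) ||
      any(!is.finite(sds)) || any(sds <= 0)) {
    stop("`means` and `sds` must be finite length-3 vectors with sds > 0",
         call. = FALSE)
  }
  structure(
    list(beta = beta, sigma = as.numeric(sigma), n = n,
         means = means, sds = sds),
    class = "cusp_design"
  )
}

#' @export
print.cusp_design <- function(x, ...) {
  cat("Cusp regression study design\n")
  cat("  beta  (b0..b5):", paste(format(x$beta, digits = 4), collapse = ", "),
      "\n")
  cat("  sigma (residual sd):", format(x$sigma, digits = 4), "\n")
  cat("  n:", if (is.null(x$n)) "<unset>" else x$n, "\n")
  if (any(x$means != 0) || any(x$sds != 1)) {
    cat("  control-variable distributions: means",
        paste(format(x$means), collapse = "/"), "sds",
        paste(format(x$sds), collapse = "/"), "\n")
  }
  invisible(x)
}

# Coerce/validate; requires n when require_n = TRUE.
as_cusp_design <- function(spec, require_n = TRUE) {
  if (!inherits(spec, "cusp_design")) {
    stop("expected a `cusp_design` object; see ?cusp_design", call. = FALSE)
  }
  if (require_n && is.null(spec$n)) {
    stop("this operation needs a design with a sample size `n`",
         call. = FALSE)
  }
  spec
}
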