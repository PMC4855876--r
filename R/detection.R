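# Guastello's cusp-detection decision rule.

#' The cusp-detection decision rule on three p-values
#'
#' A cusp is indicated only when the cubic-term coefficient \eqn{\beta_1} is
#' statistically significant AND at least one of the bifurcation-interaction
#' coefficient \eqn{\beta_3} or the asymmetry coefficient \eqn{\beta_4} is.
#' Significance is the strict comparison `p < alpha`; coefficient signs play
#' no role in the rule as classically stated.
#'
#' @param p_beta1,p_beta3,p_beta4 two-sided p-values for the cubic term
#'   \eqn{z_1^3}, the interaction \eqn{y z_1}, and the asymmetry variable
#'   \eqn{x}.
#' @param alpha per-coefficient significance level, in (0, 1).
#' @return Logical: does the rule fire?
#' @seealso [detect_cusp()]
#' @export
cusp_rule <- function(p_beta1, p_beta3, p_beta4, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  (p_beta1 < alpha) & ((p_beta3 < alpha) | (p_beta4 < alpha))
}

#' Apply the cusp-detection decision rule to a fitted cusp regression
#'
#' Extracts the two-sided p-values of the cubic term, the bifurcation
#' interaction and the asymmetry variable from a [fit_cusp()] result and
#' evaluates [cusp_rule()]. This compound rule is the test whose rejection
#' rate the Monte-Carlo power engine estimates.
#'
#' @param fit a `"cusp_fit"` object with `model_tag == "cusp"`.
#' @param alpha per-coefficient significance level (default 0.05).
#' @return An object of class `"cusp_detection"`: list with `detected`
#'   (logical), the three p-values `p_beta1`, `p_beta3`, `p_beta4`, and
#'   `alpha`.
#' @examples
#' d <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1, n = 100),
#'                         seed = 7)
#' detect_cusp(fit_cusp(d))
#' @export
detect_cusp <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "cusp_fit") || !identical(fit$model_tag, "cusp")) {
    stop("`fit` must be a cusp-model fit from fit_cusp(); the decision ",
         "rule is not defined for the alternative linear models",
         call. = FALSE)
  }
  p1 <- unname(fit$pvalue[["z1^3"]])
  p3 <- unname(fit$pvalue[["y:z1"]])
  p4 <- unname(fit$pvalue[["x"]])
  structure(
    list(detected = cusp_rule(p1, p3, p4, alpha),
         p_beta1 = p1, p_beta3 = p3, p_beta4 = p4, alpha = alpha),
    class = "cusp_detection"
  )
}

#' @export
print.cusp_detection <- function(x, ...) {
  cat("Cusp detection (decision rule at alpha =", x$alpha, ")\n")
  cat(sprintf("  p[z1^3] = %.4g, p[y:z1] = %.4g, p[x] = %.4g\n",
              x$p_beta1, x$p_beta3, x$p_beta4))
  cat("  cusp detected:", if (x$detected) "yes" else "no", "\n")
  invisible(x)
}
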