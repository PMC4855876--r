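# End-to-end simulation-study driver: four noise scenarios, fitted summary
# table, per-scenario sample-size back-calculation, and the subsampling
# reverse verification of the first scenario.

#' Run the four-scenario cusp power simulation study
#'
#' Reproduces a complete simulation-study workflow in one call. One
#' realization of the control variables \eqn{(x, y, z_1)} and of a
#' unit-variance residual vector \eqn{\epsilon_0} of size `n` is drawn; the
#' scenario for noise level \eqn{\sigma} then observes the shared cusp
#' polynomial signal (effect sizes `beta`) under residual
#' \eqn{\sigma \epsilon_0}. Each scenario is fitted by [fit_cusp()] and the
#' coefficient table, \eqn{R^2}, residual sd and F statistic are collected;
#' holding the signal and noise realization fixed across scenarios isolates
#' the effect of the noise *level* on fit quality, so \eqn{R^2} decreases
#' and \eqn{\hat\sigma} increases essentially deterministically in
#' \eqn{\sigma}. Optionally it then (a) back-calculates, from each
#' scenario's *fitted* coefficients and residual sd, the sample size needed
#' to reach `target_power` ([find_sample_size()]), and (b) reverse-verifies
#' the first scenario by subsampling its dataset at the back-calculated
#' sample size and measuring the detection rate ([subsample_power()]).
#'
#' @param seed master integer seed governing every stage; the whole suite is
#'   bit-reproducible given the seed.
#' @param n observations per simulated scenario dataset.
#' @param sigmas residual noise standard deviations, one scenario each.
#' @param beta length-6 effect-size vector of the generating truth.
#' @param target_power target power for the back-calculation stage.
#' @param alpha significance level of the decision rule.
#' @param replicates Monte-Carlo replicates for power estimation and reverse
#'   verification.
#' @param back_calculate run the sample-size and reverse-verification
#'   stages? Fitting-only runs (`FALSE`) are cheap and useful for studying
#'   the noise-level orderings of \eqn{R^2} and \eqn{\hat\sigma}.
#' @return An object of class `"cusp_scenario_suite"`: list with `designs`,
#'   `datasets`, `fits`, `table` (coefficient estimates and fit summaries,
#'   scenarios in columns), and when `back_calculate = TRUE` also
#'   `sample_sizes` (list of `"cusp_samplesize"`) and `reverse_verification`
#'   (a `"cusp_power_estimate"` for scenario 1).
#' @examples
#' \donttest{
#' suite <- run_scenario_suite(seed = 11, replicates = 100)
#' suite
#' }
#' @export
run_scenario_suite <- function(seed, n = 100, sigmas = c(1, 2, 3, 4),
                               beta = rep(0.5, 6), target_power = 0.85,
                               alpha = 0.05, replicates = 1000,
                               back_calculate = TRUE) {
  k <- length(sigmas)
  designs <- lapply(sigmas, function(s) cusp_design(beta, s, n))
  # The scenarios share one realization of the control variables and of a
  # unit-variance residual vector; scenario i observes the same signal under
  # residual sigma_i * eps0. Moving along the sigma grid therefore isolates
  # the effect of measurement noise: fit quality degrades monotonically in
  # sigma instead of being confounded with the (heavy-tailed) sampling
  # variation of z1^3 or with independent noise draws.
  base <- with_seed(derive_seed(seed, 1),
                    list(x = stats::rnorm(n), y = stats::rnorm(n),
                         z1 = stats::rnorm(n), eps0 = stats::rnorm(n)))
  signal <- beta[1L] + beta[2L] * base$z1^3 + beta[3L] * base$z1^2 +
    beta[4L] * base$y * base$z1 + beta[5L] * base$x + beta[6L] * base$y
  datasets <- lapply(seq_len(k), function(i) {
    cusp_data(base$x, base$y, base$z1,
              dz = signal + sigmas[i] * base$eps0)
  })
  fits <- lapply(datasets, fit_cusp)

  coef_mat <- vapply(fits, function(f) f$coef, numeric(6L))
  tab <- rbind(coef_mat,
               r_squared = vapply(fits, function(f) f$r_squared,
                                  numeric(1L)),
               sigma_hat = vapply(fits, function(f) f$sigma_hat,
                                  numeric(1L)),
               f_stat = vapply(fits, function(f) f$f_stat, numeric(1L)))
  colnames(tab) <- paste0("sigma=", sigmas)

  out <- list(seed = seed, alpha = alpha, target_power = target_power,
              replicates = replicates, designs = designs,
              datasets = datasets, fits = fits, table = tab)

  if (back_calculate) {
    out$sample_sizes <- lapply(seq_len(k), function(i) {
      fitted_design <- cusp_design(fits[[i]]$coef, fits[[i]]$sigma_hat)
      find_sample_size(fitted_design, target_power = target_power,
                       alpha = alpha, replicates = replicates,
                       seed = derive_seed(seed, 100 + i))
    })
    n1 <- out$sample_sizes[[1L]]$n_required
    if (!is.na(n1) && n1 <= n) {
      out$reverse_verification <- subsample_power(
        datasets[[1L]], m = n1, alpha = alpha, replicates = replicates,
        seed = derive_seed(seed, 200))
    }
  }
  class(out) <- "cusp_scenario_suite"
  out
}

#' @export
print.cusp_scenario_suite <- function(x, ...) {
  cat("Cusp regression simulation suite (seed", x$seed, ")\n\n")
  cat("Fitted cusp regressions, one scenario per column:\n")
  print(round(x$table, 4))
  if (!is.null(x$sample_sizes)) {
    ns <- vapply(x$sample_sizes, function(s) {
      if (is.na(s$n_required)) NA_integer_ else s$n_required
    }, integer(1L))
    cat(sprintf("\nSample size for target power %.2f, per scenario: %s\n",
                x$target_power, paste(ns, collapse = ", ")))
  }
  if (!is.null(x$reverse_verification)) {
    rv <- x$reverse_verification
    cat(sprintf(
      "Reverse verification (scenario 1, subsamples of m = %d): power %.3f\n",
      rv$n, rv$power))
  }
  invisible(x)
}
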