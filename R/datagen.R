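# Synthetic-data generation for the cusp polynomial regression model.

# Raw generator: draws x, y, z1, eps in that fixed order from the current
# RNG stream and assembles the change score. Returns plain vectors; callers
# wrap into a cusp_data frame as needed. The fixed draw order is part of the
# reproducibility contract.
gen_cusp_raw <- function(n, beta, sigma, means = c(0, 0, 0),
                         sds = c(1, 1, 1)) {
  x <- stats::rnorm(n, means[1L], sds[1L])
  y <- stats::rnorm(n, means[2L], sds[2L])
  z1 <- stats::rnorm(n, means[3L], sds[3L])
  eps <- if (sigma > 0) stats::rnorm(n, 0, sigma) else numeric(n)
  dz <- beta[1L] + beta[2L] * z1^3 + beta[3L] * z1^2 + beta[4L] * y * z1 +
    beta[5L] * x + beta[6L] * y + eps
  list(x = x, y = y, z1 = z1, z2 = z1 + dz, dz = dz)
}

#' Construct a cusp change-score dataset
#'
#' Builds and validates the data container used throughout the package: a
#' data frame with columns `x` (asymmetry control variable), `y` (bifurcation
#' control variable), `z1` and `z2` (the outcome at times 1 and 2) and the
#' change score `dz`. The change-score definition `dz = z2 - z1` is enforced:
#' `dz` is always recomputed from `z2 - z1` when both outcome columns are
#' supplied, with a warning if a supplied `dz` disagrees by more than `1e-8`.
#'
#' @param x,y,z1 numeric vectors of equal length: the asymmetry variable, the
#'   bifurcation variable, and the outcome at time 1.
#' @param z2 outcome at time 2; may be omitted when `dz` is given.
#' @param dz change score; may be omitted when `z2` is given.
#' @return A data frame of class `c("cusp_data", "data.frame")`.
#' @examples
#' d <- cusp_data(x = rnorm(10), y = rnorm(10), z1 = rnorm(10),
#'                dz = rnorm(10))
#' stopifnot(all(d$z2 - d$z1 == d$dz))
#' @export
cusp_data <- function(x, y, z1, z2 = NULL, dz = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z1 <- as.numeric(z1)
  if (is.null(z2) && is.null(dz)) {
    stop("supply at least one of `z2` and `dz`", call. = FALSE)
  }
  if (is.null(dz)) {
    z2 <- as.numeric(z2)
    dz <- z2 - z1
  } else if (is.null(z2)) {
    dz <- as.numeric(dz)
    z2 <- z1 + dz
  } else {
    z2 <- as.numeric(z2)
    dz_given <- as.numeric(dz)
    dz <- z2 - z1
    if (max(abs(dz_given - dz)) > 1e-8) {
      warning("supplied `dz` disagrees with z2 - z1 by more than 1e-8; ",
              "recomputed as z2 - z1", call. = FALSE)
    }
  }
  n <- length(x)
  lens <- c(length(y), length(z1), length(z2), length(dz))
  if (n < 1L || any(lens != n)) {
    stop("x, y, z1, z2/dz must all have the same positive length",
         call. = FALSE)
  }
  dat <- data.frame(x = x, y = y, z1 = z1, z2 = z2, dz = dz)
  if (!all(vapply(dat, function(v) all(is.finite(v)), logical(1L)))) {
    stop("all entries of a cusp dataset must be finite", call. = FALSE)
  }
  class(dat) <- c("cusp_data", "data.frame")
  dat
}

# Accept a cusp_data frame or any data frame carrying the needed columns.
as_cusp_data <- function(data) {
  if (inherits(data, "cusp_data")) return(data)
  if (!is.data.frame(data)) {
    stop("expected a data frame with columns x, y, z1 and z2 and/or dz",
         call. = FALSE)
  }
  need <- c("x", "y", "z1")
  if (!all(need %in% names(data)) ||
      !any(c("z2", "dz") %in% names(data))) {
    stop("data must contain columns x, y, z1 and at least one of z2, dz",
         call. = FALSE)
  }
  cusp_data(data$x, data$y, data$z1,
            z2 = if ("z2" %in% names(data)) data$z2 else NULL,
            dz = if ("dz" %in% names(data)) data$dz else NULL)
}

#' Simulate a dataset from a cusp regression design
#'
#' Draws `x`, `y` and `z1` independently from their control distributions
#' (standard normal by default) and the residual from \eqn{N(0, \sigma^2)},
#' then computes the change score from the cusp polynomial
#' \eqn{\Delta z = \beta_0 + \beta_1 z_1^3 + \beta_2 z_1^2 + \beta_3 y z_1 +
#' \beta_4 x + \beta_5 y + \epsilon} and sets \eqn{z_2 = z_1 + \Delta z}.
#' Draws happen in the fixed order `x`, `y`, `z1`, `eps`, so a given
#' `(design, seed)` pair always reproduces the identical dataset.
#'
#' Generated control variables are used as drawn; they are not re-standardized
#' within each sample. [standardize()] is provided separately for observed-data
#' workflows where variables arrive on arbitrary scales.
#'
#' @param design a [cusp_design()] with `n` set.
#' @param seed integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream. When a seed is given the caller's RNG state is left
#'   untouched.
#' @return A [cusp_data()] frame with `design$n` rows.
#' @examples
#' d <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1, n = 100),
#'                         seed = 1)
#' head(d)
#' @export
simulate_cusp_data <- function(design, seed = NULL) {
  design <- as_cusp_design(design, require_n = TRUE)
  g <- with_seed(seed, gen_cusp_raw(design$n, design$beta, design$sigma,
                                    design$means, design$sds))
  cusp_data(g$x, g$y, g$z1, z2 = g$z2)
}

#' Standardize a variable to zero mean and unit variance
#'
#' Centers and scales by the sample mean and sample standard deviation
#' (denominator \eqn{n - 1}). Cusp polynomial regression is conventionally
#' run on standardized variables, so observed data should pass through this
#' before fitting; simulated data from [simulate_cusp_data()] is already on
#' the standard-normal scale.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return Numeric vector with sample mean 0 and sample sd 1.
#' @examples
#' standardize(c(1, 2, 3)) # -1, 0, 1
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("`values` must be a finite vector of length >= 2", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("cannot standardize a constant vector (zero variance)",
         call. = FALSE)
  }
  (values - mean(values)) / s
}
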