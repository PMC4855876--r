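# Monte-Carlo power estimation, power curves, and sample-size
# back-calculation for the cusp-detection decision rule.

new_power_estimate <- function(n, replicates, detections, alpha, seed,
                               degenerate_redraws = 0L) {
  power <- detections / replicates
  structure(
    list(n = as.integer(n), replicates = as.integer(replicates),
         detections = as.integer(detections), power = power,
         mc_se = sqrt(power * (1 - power) / replicates),
         alpha = alpha, seed = seed,
         degenerate_redraws = as.integer(degenerate_redraws)),
    class = "cusp_power_estimate"
  )
}

#' @export
print.cusp_power_estimate <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power estimate: n = %d, power = %.3f (%d/%d, MC se %.4f)\n",
    x$n, x$power, x$detections, x$replicates, x$mc_se))
  if (x$degenerate_redraws > 0L) {
    cat("  (", x$degenerate_redraws,
        "rank-deficient replicate(s) redrawn )\n")
  }
  invisible(x)
}

# Core replicate loop shared by estimate_power() and subsample_power():
# `draw` returns list(x, y, z1, dz) for one replicate, using the current RNG
# stream. Rank-deficient draws are redrawn (not counted as non-detections)
# up to a hard cap.
mc_detection_loop <- function(draw, replicates, alpha) {
  detections <- 0L
  redraws <- 0L
  max_attempts <- 100L * replicates
  attempts <- 0L
  r <- 0L
  while (r < replicates) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("too many rank-deficient replicates (", redraws, " redraws); ",
           "check the design for degenerate settings", call. = FALSE)
    }
    g <- draw()
    f <- fast_cusp_pvalues(g$x, g$y, g$z1, g$dz)
    if (is.null(f)) {
      redraws <- redraws + 1L
      next
    }
    r <- r + 1L
    if (cusp_rule(f$pvalue[2L], f$pvalue[4L], f$pvalue[5L], alpha)) {
      detections <- detections + 1L
    }
  }
  list(detections = detections, redraws = redraws)
}

#' Estimate the power of the cusp-detection procedure by simulation
#'
#' For each replicate a fresh dataset of `design$n` observations is simulated
#' from the design's cusp polynomial truth, the cusp regression is fitted by
#' least squares, and the detection decision rule is applied at level
#' `alpha`. The estimated power is the proportion of replicates on which the
#' rule fires; its Monte-Carlo standard error is
#' \eqn{\sqrt{p(1-p)/\mathrm{replicates}}}. Replicates whose design matrix is
#' numerically rank deficient are redrawn (and counted separately) rather
#' than scored as non-detections, up to a cap of 100 times the replicate
#' count.
#'
#' @param design a [cusp_design()] with `n` set (`n >= 7`).
#' @param alpha per-coefficient significance level for the decision rule.
#' @param replicates number of simulated datasets (the classical
#'   recommendation is 1000).
#' @param seed integer seed; the same `(design, alpha, replicates, seed)`
#'   always reproduces the identical estimate. `NULL` uses the current
#'   stream.
#' @return An object of class `"cusp_power_estimate"`: list with `n`,
#'   `replicates`, `detections`, `power`, `mc_se`, `alpha`, `seed` and
#'   `degenerate_redraws`.
#' @seealso [power_curve()], [find_sample_size()], [subsample_power()]
#' @examples
#' estimate_power(cusp_design(rep(0.5, 6), sigma = 1, n = 50),
#'                replicates = 200, seed = 1)
#' @export
estimate_power <- function(design, alpha = 0.05, replicates = 1000,
                           seed = NULL) {
  design <- as_cusp_design(design, require_n = TRUE)
  if (design$n < 7L) {
    stop("power estimation needs n >= 7 (six coefficients plus at least ",
         "one residual degree of freedom)", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates < 1 || replicates != round(replicates)) {
    stop("`replicates` must be a positive integer", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  draw <- function() gen_cusp_raw(design$n, design$beta, design$sigma,
                                  design$means, design$sds)
  out <- with_seed(seed, mc_detection_loop(draw, replicates, alpha))
  new_power_estimate(design$n, replicates, out$detections, alpha, seed,
                     out$redraws)
}

#' Estimate detection power by subsampling a fixed dataset
#'
#' The reverse-verification device: instead of simulating fresh data, each
#' replicate draws `m` observations (without replacement by default) from one
#' fixed dataset, fits the cusp regression to the subsample and applies the
#' decision rule. The resulting proportion estimates the power available at
#' sample size `m`, conditional on the particular realization in `data`.
#'
#' @param data a [cusp_data()] frame.
#' @param m subsample size, `7 <= m <= nrow(data)` (when
#'   `replace = FALSE`).
#' @param alpha,replicates,seed as in [estimate_power()].
#' @param replace draw subsamples with replacement? Default `FALSE`, the
#'   natural reading of "randomly sample m observations from the data".
#' @return A `"cusp_power_estimate"` (see [estimate_power()]).
#' @export
subsample_power <- function(data, m, alpha = 0.05, replicates = 1000,
                            seed = NULL, replace = FALSE) {
  data <- as_cusp_data(data)
  n <- nrow(data)
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 7L) {
    stop("`m` must be an integer >= 7", call. = FALSE)
  }
  if (!replace && m > n) {
    stop("subsample size m = ", m, " exceeds the dataset size n = ", n,
         call. = FALSE)
  }
  m <- as.integer(m)
  replicates <- as.integer(replicates)
  draw <- function() {
    idx <- sample.int(n, m, replace = replace)
    list(x = data$x[idx], y = data$y[idx], z1 = data$z1[idx],
         dz = data$dz[idx])
  }
  out <- with_seed(seed, mc_detection_loop(draw, replicates, alpha))
  new_power_estimate(m, replicates, out$detections, alpha, seed, out$redraws)
}

#' Power curve over a grid of sample sizes
#'
#' Runs [estimate_power()] at each sample size of a strictly increasing grid,
#' holding the effect sizes, noise level and significance level fixed, and
#' adds a monotone (isotonic least-squares) smooth of the raw power
#' estimates. The per-grid-point seed is derived deterministically from the
#' master seed and the sample size itself, so extending the grid never
#' perturbs existing estimates.
#'
#' @param design a [cusp_design()]; its `n` slot, if any, is ignored in
#'   favour of the grid.
#' @param n_grid integer vector of sample sizes, strictly increasing, all
#'   `>= 7`.
#' @param alpha,replicates as in [estimate_power()].
#' @param seed master integer seed, or `NULL`.
#' @return An object of class `"cusp_power_curve"`: list with `spec` (the
#'   design), `alpha`, `replicates`, `seed` and `grid`, a data frame with
#'   columns `n`, `replicates`, `detections`, `power`, `mc_se`,
#'   `power_smoothed`.
#' @seealso [required_sample_size()], [find_sample_size()]
#' @export
power_curve <- function(design, n_grid, alpha = 0.05, replicates = 1000,
                        seed = NULL) {
  design <- as_cusp_design(design, require_n = FALSE)
  n_grid <- as.integer(n_grid)
  if (length(n_grid) == 0L || any(n_grid < 7L) ||
      is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be a nonempty strictly increasing vector of ",
         "integers >= 7", call. = FALSE)
  }
  ests <- lapply(n_grid, function(n_i) {
    d_i <- design
    d_i$n <- n_i
    estimate_power(d_i, alpha = alpha, replicates = replicates,
                   seed = derive_seed(seed, n_i))
  })
  powers <- vapply(ests, function(e) e$power, numeric(1L))
  smoothed <- if (length(powers) > 1L) {
    stats::isoreg(n_grid, powers)$yf
  } else {
    powers
  }
  grid <- data.frame(
    n = n_grid,
    replicates = vapply(ests, function(e) e$replicates, integer(1L)),
    detections = vapply(ests, function(e) e$detections, integer(1L)),
    power = powers,
    mc_se = vapply(ests, function(e) e$mc_se, numeric(1L)),
    power_smoothed = smoothed
  )
  structure(list(spec = design, alpha = alpha, replicates = replicates,
                 seed = seed, grid = grid),
            class = "cusp_power_curve")
}

#' @export
print.cusp_power_curve <- function(x, ...) {
  cat(sprintf(
    "Power curve: %d grid points, %d replicates each, alpha = %g\n",
    nrow(x$grid), x$replicates, x$alpha))
  print(format(x$grid, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Plot a power curve
#'
#' Raw Monte-Carlo power estimates (points) with the monotone smooth (line)
#' against sample size.
#'
#' @param x a `"cusp_power_curve"`.
#' @param target optional target power to mark with a horizontal reference
#'   line.
#' @param ... passed to [plot()].
#' @export
plot.cusp_power_curve <- function(x, target = NULL, ...) {
  plot(x$grid$n, x$grid$power, xlab = "sample size n",
       ylab = "estimated power", ylim = c(0, 1), pch = 19, ...)
  graphics::lines(x$grid$n, x$grid$power_smoothed, col = "steelblue",
                  lwd = 2)
  if (!is.null(target)) graphics::abline(h = target, lty = 2)
  invisible(x)
}

#' Back-calculate the sample size achieving a target power
#'
#' Inverts the monotone-smoothed power curve at the requested target: the
#' required `n` is the smallest integer at which the piecewise-linear
#' interpolation of the isotonic smooth reaches the target. When even the
#' smallest grid point exceeds the target the minimum grid `n` is returned
#' with `boundary = TRUE`; when the smoothed curve never reaches the target,
#' `out_of_range = TRUE` and `n_required` is `NA`.
#'
#' @param curve a `"cusp_power_curve"` from [power_curve()].
#' @param target_power target power in (0, 1), e.g. 0.85.
#' @return An object of class `"cusp_samplesize"`: list with `target_power`,
#'   `n_required`, `achieved_power_at_n` (smoothed power interpolated at the
#'   required `n`), flags `boundary` and `out_of_range`, and the `curve`.
#' @export
required_sample_size <- function(curve, target_power) {
  if (!inherits(curve, "cusp_power_curve") || nrow(curve$grid) == 0L) {
    stop("`curve` must be a nonempty cusp_power_curve", call. = FALSE)
  }
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= 0 || target_power >= 1) {
    stop("`target_power` must be a single number in (0, 1)", call. = FALSE)
  }
  ns <- curve$grid$n
  sp <- curve$grid$power_smoothed
  boundary <- FALSE
  out_of_range <- FALSE
  if (sp[1L] >= target_power) {
    n_req <- as.integer(ns[1L])
    boundary <- TRUE
  } else if (max(sp) < target_power) {
    n_req <- NA_integer_
    out_of_range <- TRUE
  } else {
    k <- which(sp >= target_power)[1L]
    frac <- (target_power - sp[k - 1L]) / (sp[k] - sp[k - 1L])
    n_req <- as.integer(ceiling(ns[k - 1L] + frac * (ns[k] - ns[k - 1L])))
  }
  achieved <- if (is.na(n_req)) {
    max(sp)
  } else if (length(ns) > 1L) {
    stats::approx(ns, sp, xout = n_req, rule = 2)$y
  } else {
    sp[1L]
  }
  structure(
    list(target_power = target_power, n_required = n_req,
         achieved_power_at_n = achieved, boundary = boundary,
         out_of_range = out_of_range, curve = curve),
    class = "cusp_samplesize"
  )
}

#' @export
print.cusp_samplesize <- function(x, ...) {
  cat(sprintf("Sample-size back-calculation at target power %.2f\n",
              x$target_power))
  if (x$out_of_range) {
    cat(sprintf(
      "  target not reached on the grid (max smoothed power %.3f at n = %d)\n",
      x$achieved_power_at_n, max(x$curve$grid$n)))
  } else {
    cat(sprintf("  required n = %d (smoothed power there: %.3f)%s\n",
                x$n_required, x$achieved_power_at_n,
                if (x$boundary) " [at grid boundary]" else ""))
  }
  invisible(x)
}

#' Determine the sample size for a target power, end to end
#'
#' One-call driver for study planning: given the effect-size vector and
#' residual noise level, it locates a sample-size range whose power brackets
#' the target (doubling an upper bound, probed with a reduced pilot replicate
#' count, until the target is exceeded or `n_cap` is reached), lays an evenly
#' spaced integer grid over that range, estimates power at every grid point
#' with the full replicate count, and inverts the monotone-smoothed curve at
#' the target ([required_sample_size()]).
#'
#' @param design a [cusp_design()] (the `n` slot is ignored); typically the
#'   fitted coefficients and residual sd of a pilot or published cusp
#'   regression.
#' @param target_power target power in (0, 1); the conventional design value
#'   is 0.85.
#' @param alpha per-coefficient significance level of the decision rule.
#' @param replicates replicates per grid point for the final curve.
#' @param seed master integer seed, or `NULL`.
#' @param n_min smallest sample size considered (>= 7).
#' @param n_cap largest sample size the bracketing search will try.
#' @param grid_size number of grid points of the final curve.
#' @param pilot_replicates replicate count for the bracketing probes
#'   (default: `replicates / 5`, at least 100).
#' @return A `"cusp_samplesize"` object (see [required_sample_size()]);
#'   `out_of_range = TRUE` if the target is unreachable below `n_cap`.
#' @examples
#' \donttest{
#' des <- cusp_design(rep(0.5, 6), sigma = 1)
#' find_sample_size(des, target_power = 0.85, replicates = 200, seed = 1)
#' }
#' @export
find_sample_size <- function(design, target_power = 0.85, alpha = 0.05,
                             replicates = 1000, seed = NULL, n_min = 10,
                             n_cap = 5000, grid_size = 15,
                             pilot_replicates = max(100L,
                                                    replicates %/% 5L)) {
  design <- as_cusp_design(design, require_n = FALSE)
  if (n_min < 7L) stop("`n_min` must be >= 7", call. = FALSE)
  upper <- max(2L * as.integer(n_min), 80L)
  probe <- 0L
  repeat {
    d_u <- design
    d_u$n <- upper
    probe <- probe + 1L
    pe <- estimate_power(d_u, alpha = alpha,
                         replicates = pilot_replicates,
                         seed = derive_seed(seed, 1000000 + probe))
    if (pe$power >= target_power || upper >= n_cap) break
    upper <- min(2L * upper, as.integer(n_cap))
  }
  repeat {
    grid <- unique(as.integer(round(seq(n_min, upper,
                                        length.out = grid_size))))
    curve <- power_curve(design, grid, alpha = alpha,
                         replicates = replicates, seed = seed)
    res <- required_sample_size(curve, target_power)
    if (!res$out_of_range || upper >= n_cap) return(res)
    upper <- min(2L * upper, as.integer(n_cap))
  }
}
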