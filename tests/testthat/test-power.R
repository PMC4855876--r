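scenario1 <- cusp_design(rep(0.5, 6), sigma = 1, n = 100)

test_that("power estimates satisfy their accounting invariants", {
  pe <- estimate_power(cusp_design(rep(0.5, 6), 2, 40), replicates = 150,
                       seed = 1)
  expect_identical(pe$power, pe$detections / pe$replicates)
  expect_equal(pe$mc_se, sqrt(pe$power * (1 - pe$power) / pe$replicates))
  expect_true(pe$detections >= 0 && pe$detections <= pe$replicates)
})

test_that("power estimation is bit-reproducible and leaves the RNG alone", {
  des <- cusp_design(rep(0.5, 6), 1.5, 50)
  set.seed(4242)
  before <- .Random.seed
  p1 <- estimate_power(des, replicates = 100, seed = 9)
  expect_identical(.Random.seed, before)
  p2 <- estimate_power(des, replicates = 100, seed = 9)
  expect_identical(p1$detections, p2$detections)
})

test_that("under the no-cusp null the compound rule rejects at most alpha", {
  pe <- estimate_power(cusp_design(rep(0, 6), sigma = 1, n = 100),
                       alpha = 0.05, replicates = 2000, seed = 11)
  # conjunction of tests: strictly more stringent than one 0.05-level test
  expect_lte(pe$power, 0.05)
})

test_that("power approaches one at large n under the standard signal", {
  pe <- estimate_power(cusp_design(rep(0.5, 6), sigma = 1, n = 300),
                       replicates = 200, seed = 12)
  expect_gte(pe$power, 0.98)
})

test_that("a small run's 99% binomial interval brackets a 10x oracle run", {
  specs <- list(cusp_design(rep(0.5, 6), 2, 60),
                cusp_design(rep(0.5, 6), 3, 120))
  for (i in seq_along(specs)) {
    small <- estimate_power(specs[[i]], replicates = 150, seed = 20 + i)
    big <- estimate_power(specs[[i]], replicates = 1500, seed = 520 + i)
    ci <- binom.test(small$detections, small$replicates,
                     conf.level = 0.99)$conf.int
    expect_gte(big$power, ci[1])
    expect_lte(big$power, ci[2])
  }
})

test_that("estimated power decreases with the noise level", {
  powers <- vapply(c(1, 2, 3, 4), function(s) {
    estimate_power(cusp_design(rep(0.5, 6), s, 100), replicates = 500,
                   seed = 30)$power
  }, numeric(1))
  expect_true(all(diff(powers) < 0))
})

test_that("power curves carry a monotone smooth and stable per-n seeds", {
  des <- cusp_design(rep(0.5, 6), sigma = 2)
  pc <- power_curve(des, c(20, 40, 80), replicates = 200, seed = 41)
  expect_true(all(diff(pc$grid$power_smoothed) >= 0))
  # extending the grid must not perturb estimates at existing sample sizes
  pc2 <- power_curve(des, c(20, 30, 40, 80, 120), replicates = 200,
                     seed = 41)
  expect_identical(pc$grid$detections,
                   pc2$grid$detections[pc2$grid$n %in% c(20, 40, 80)])
  # degenerate one-point grid equals a single estimate_power call
  pc1 <- power_curve(des, 40, replicates = 200, seed = 41)
  one <- estimate_power(cusp_design(rep(0.5, 6), 2, 40), replicates = 200,
                        seed = cusppower:::derive_seed(41, 40))
  expect_identical(pc1$grid$detections, one$detections)
  expect_error(power_curve(des, c(40, 20), replicates = 10),
               "strictly increasing")
  expect_error(power_curve(des, integer(0)), "nonempty")
})

test_that("back-calculation inverts the smoothed curve by linear interpolation", {
  fake_curve <- function(ns, smoothed) {
    structure(list(spec = cusp_design(rep(0.5, 6), 1), alpha = 0.05,
                   replicates = 1000, seed = 1,
                   grid = data.frame(n = ns, replicates = 1000,
                                     detections = round(1000 * smoothed),
                                     power = smoothed,
                                     mc_se = 0.01,
                                     power_smoothed = smoothed)),
              class = "cusp_power_curve")
  }
  # hand interpolation: 20 + (0.85-0.5)/(0.9-0.5) * 20 = 37.5 -> 38
  res <- required_sample_size(fake_curve(c(20, 40), c(0.5, 0.9)), 0.85)
  expect_identical(res$n_required, 38L)
  expect_false(res$boundary)
  expect_false(res$out_of_range)
  # target below the smallest grid power: boundary case
  res_b <- required_sample_size(fake_curve(c(20, 40), c(0.5, 0.9)), 0.3)
  expect_identical(res_b$n_required, 20L)
  expect_true(res_b$boundary)
  # target never reached: out-of-range flag
  res_o <- required_sample_size(fake_curve(c(20, 40), c(0.2, 0.4)), 0.85)
  expect_true(res_o$out_of_range)
  expect_true(is.na(res_o$n_required))
  expect_error(required_sample_size(fake_curve(20, 0.5), 1.5),
               "target_power")
})

test_that("subsampling at m = n is degenerate and bounds are enforced", {
  d <- simulate_cusp_data(scenario1, seed = 50)
  pe <- subsample_power(d, m = 100, replicates = 20, seed = 51)
  expect_true(pe$power %in% c(0, 1))
  expect_error(subsample_power(d, m = 101, replicates = 10), "exceeds")
  expect_error(subsample_power(d, m = 5, replicates = 10), ">= 7")
})

test_that("tiny noiseless subsamples still detect a strong cusp", {
  d0 <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1e-8, n = 30),
                           seed = 52)
  pe <- subsample_power(d0, m = 8, replicates = 50, seed = 53)
  expect_identical(pe$power, 1)
})

test_that("subsample power is reproducible and supports replacement", {
  d <- simulate_cusp_data(scenario1, seed = 54)
  a <- subsample_power(d, 36, replicates = 200, seed = 55)
  b <- subsample_power(d, 36, replicates = 200, seed = 55)
  expect_identical(a$detections, b$detections)
  wr <- subsample_power(d, 36, replicates = 100, seed = 56, replace = TRUE)
  expect_true(wr$power >= 0 && wr$power <= 1)
})

test_that("the sample-size driver brackets, inverts, and reproduces bit-for-bit", {
  des <- cusp_design(rep(0.5, 6), sigma = 1)
  r1 <- find_sample_size(des, target_power = 0.85, replicates = 300,
                         seed = 60)
  r2 <- find_sample_size(des, target_power = 0.85, replicates = 300,
                         seed = 60)
  expect_identical(r1$n_required, r2$n_required)
  expect_identical(r1$curve$grid, r2$curve$grid)
  expect_false(r1$out_of_range)
  # reverse verification: fresh-seed power at n_required reaches the target
  # within Monte-Carlo error
  check <- estimate_power(
    cusp_design(rep(0.5, 6), 1, r1$n_required), replicates = 500,
    seed = 61)
  expect_gte(check$power, 0.85 - 3 * check$mc_se)
})

test_that("an easy target is reported at the grid boundary", {
  # power at n = 30 under the standard signal is already well above 0.5
  res <- find_sample_size(cusp_design(rep(0.5, 6), sigma = 1),
                          target_power = 0.5, replicates = 100, seed = 62,
                          n_min = 30)
  expect_true(res$boundary)
  expect_identical(res$n_required, res$curve$grid$n[1L])
})
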