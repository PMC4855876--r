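all_tags <- c("cusp", "linear_diff_1", "linear_diff_2",
              "linear_pre_post_1", "linear_pre_post_2")

fit_by_tag <- function(data, tag) {
  if (tag == "cusp") fit_cusp(data) else fit_cusp_alternative(data, tag)
}

test_that("every model matches the normal-equations oracle on random small instances", {
  for (seed in 1:12) {
    n <- sample(7:30, 1)
    d <- random_dataset(n, seed)
    for (tag in all_tags) {
      if (n < length(oracle_design(d, tag)[1, ]) + 2L) next
      f <- fit_by_tag(d, tag)
      o <- ols_oracle(oracle_design(d, tag), oracle_response(d, tag))
      expect_equal(unname(f$coef), o$coef, tolerance = 1e-8)
      expect_equal(unname(f$se), o$se, tolerance = 1e-8)
      expect_equal(unname(f$tstat), o$tstat, tolerance = 1e-8)
      expect_equal(unname(f$pvalue), o$pvalue, tolerance = 1e-8)
      expect_equal(f$r_squared, o$r_squared, tolerance = 1e-8)
      expect_equal(f$sigma_hat, o$sigma_hat, tolerance = 1e-8)
      expect_equal(f$f_stat, o$f_stat, tolerance = 1e-8)
      expect_identical(f$df_resid, o$df_resid)
    }
  }
})

test_that("fit results satisfy their internal invariants", {
  d <- random_dataset(25, 31)
  f <- fit_cusp(d)
  expect_equal(unname(f$tstat), unname(f$coef / f$se))
  expect_equal(f$f_stat,
               (f$r_squared / f$df_model) /
                 ((1 - f$r_squared) / f$df_resid))
  expect_identical(f$df_resid, f$n - f$df_model - 1L)
  expect_true(all(f$pvalue >= 0 & f$pvalue <= 1))
})

test_that("noiseless cusp data is recovered exactly", {
  d <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 0, n = 50),
                          seed = 8)
  f <- suppressWarnings(fit_cusp(d)) # perfect-fit warning is expected
  expect_equal(unname(f$coef), rep(0.5, 6), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$sigma_hat, 0, tolerance = 1e-8)
})

test_that("identity dynamics make the first pre/post model exact", {
  set.seed(5)
  d <- cusp_data(x = rnorm(20), y = rnorm(20), z1 = rnorm(20), dz = rep(0, 20))
  f <- suppressWarnings(fit_cusp_alternative(d, "linear_pre_post_1"))
  expect_equal(unname(f$coef), c(0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("adding the interaction term never lowers R-squared (nested pairs)", {
  for (seed in 1:10) {
    d <- random_dataset(sample(9:40, 1), 100 + seed)
    expect_gte(fit_cusp_alternative(d, "linear_diff_2")$r_squared + 1e-12,
               fit_cusp_alternative(d, "linear_diff_1")$r_squared)
    expect_gte(fit_cusp_alternative(d, "linear_pre_post_2")$r_squared + 1e-12,
               fit_cusp_alternative(d, "linear_pre_post_1")$r_squared)
  }
})

test_that("coefficients are consistent and sigma-hat is recovered at large n", {
  d <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1, n = 1e5),
                          seed = 12)
  f <- fit_cusp(d)
  expect_true(all(abs(f$coef - 0.5) < 0.05))
  for (sigma in c(1, 4)) {
    ds <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = sigma,
                                         n = 1e5), seed = 13)
    expect_equal(fit_cusp(ds)$sigma_hat, sigma, tolerance = 0.02)
  }
})

test_that("the comparative-fit rule favours the cusp model on cusp data", {
  # noiseless cusp truth: the polynomial fits perfectly, no linear model does
  d0 <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 0, n = 60),
                           seed = 21)
  cmp0 <- suppressWarnings(compare_cusp_models(d0))
  expect_true(cmp0$cusp_r2_dominates)
  expect_equal(cmp0$fits$cusp$r_squared, 1, tolerance = 1e-10)
  # the standard simulated-study condition
  d1 <- simulate_cusp_data(cusp_design(rep(0.5, 6), sigma = 1, n = 100),
                           seed = 22)
  cmp1 <- compare_cusp_models(d1)
  expect_true(cmp1$cusp_r2_dominates)
  expect_identical(cmp1$table$model, all_tags)
})

test_that("alias model names resolve and the cusp tag is rejected", {
  d <- random_dataset(20, 44)
  expect_equal(fit_cusp_alternative(d, "eq3")$coef,
               fit_cusp_alternative(d, "linear_diff_1")$coef)
  expect_equal(fit_cusp_alternative(d, "eq6")$model_tag,
               "linear_pre_post_2")
  expect_error(fit_cusp_alternative(d, "cusp"), "fit_cusp")
  expect_error(fit_cusp_alternative(d, "eq7"), "unknown model")
})

test_that("degenerate designs fail loudly", {
  set.seed(9)
  v <- rnorm(20)
  d_coll <- cusp_data(x = v, y = v, z1 = rnorm(20), dz = rnorm(20))
  expect_error(fit_cusp(d_coll), "rank deficient")
  d_small <- random_dataset(6, 50)
  expect_error(fit_cusp(d_small), "insufficient observations")
})

test_that("the power engine's fast fit agrees with the public fit", {
  for (seed in 1:5) {
    d <- random_dataset(sample(10:60, 1), 200 + seed)
    f <- fit_cusp(d)
    fast <- cusppower:::fast_cusp_pvalues(d$x, d$y, d$z1, d$dz)
    expect_equal(fast$coef, unname(f$coef), tolerance = 1e-9)
    expect_equal(fast$pvalue, unname(f$pvalue), tolerance = 1e-9)
  }
})
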