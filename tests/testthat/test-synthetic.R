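test_that("zero-noise surfaces are recovered exactly by the fit", {
  sp <- toy_surface(noise_sd = 0)
  ds <- simulate_bbd_dataset(sp, n_center = 3)
  fit <- fit_quadratic(ds, "y")
  truth <- c(sp$beta0, sp$beta_lin, sp$beta_quad, sp$beta_int)
  expect_equal(unname(fit$coef), truth, tolerance = 1e-8)
  expect_equal(rsm_anova(fit)$rmse, 0, tolerance = 1e-8)
  expect_equal(rsm_anova(fit)$r2, 1, tolerance = 1e-10)
})

test_that("simulation is seed-reproducible and noise-calibrated", {
  sp <- toy_surface(noise_sd = 2, seed = 77)
  d1 <- simulate_bbd_dataset(sp)
  d2 <- simulate_bbd_dataset(sp)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_bbd_dataset(toy_surface(noise_sd = 2, seed = 78))
  expect_false(isTRUE(all.equal(d1$y_mean, d3$y_mean)))
  # empirical replicate sd converges to noise_sd over many replicates
  sp_many <- synthetic_surface_spec(3, 10, c(1, 1, 1), c(0, 0, 0),
                                    rep(0, 3), noise_sd = 2,
                                    n_reps = 10000L, seed = 5)
  dm <- simulate_bbd_dataset(sp_many, n_center = 1)
  expect_lt(max(abs(dm$y_sd - 2) / 2), 0.05)
})

test_that("simulated datasets round-trip through the CSV dialect", {
  sp <- toy_surface(noise_sd = 1.5, seed = 12)
  ds <- simulate_bbd_dataset(sp, n_center = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bbd_csv(ds, path)
  back <- read_bbd_csv(path, spec = attr(ds, "spec"),
                       n_reps = attr(ds, "n_reps"))
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("95% confidence intervals attain near-nominal coverage", {
  truth <- c(100, -20, 5, 8, -15, -2, 3, 4, -6, 2)
  covered <- 0L; total <- 0L
  for (s in 1:50) {
    sp <- synthetic_surface_spec(3, truth[1], truth[2:4], truth[5:7],
                                 truth[8:10], noise_sd = 2, seed = 500 + s)
    fit <- fit_quadratic(simulate_bbd_dataset(sp, n_center = 3), "y")
    tcrit <- qt(0.975, fit$residual_df)
    lo <- unname(fit$coef) - tcrit * unname(fit$coef_se)
    hi <- unname(fit$coef) + tcrit * unname(fit$coef_se)
    covered <- covered + sum(truth >= lo & truth <= hi)
    total <- total + length(truth)
  }
  expect_gte(covered / total, 0.90)
  expect_lte(covered / total, 1.00)
})

test_that("named test surfaces expose their documented values", {
  sphere <- make_test_surface("sphere")
  expect_equal(sphere(c(0, 0, 0)), 0)
  expect_equal(sphere(c(3, 4)), 25)
  fc <- make_test_surface("table3_fcrc")
  expect_equal(fc(rep(0, 4)), 362.78)
  expect_equal(fc(c(1, 0, 1, 0)), 136.40, tolerance = 0.05 / 136.4)
  al <- make_test_surface("table3_alcl3")
  expect_equal(al(rep(0, 4)), 37.24)
  nq <- make_test_surface("neg_quadratic_known_max")
  expect_equal(nq(rep(0.3, 5)), 0)
  expect_error(make_test_surface("nope"), "unavailable fixture")
})
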