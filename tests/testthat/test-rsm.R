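test_that("the refit reproduces the published coefficient table", {
  f <- ofi_fcrc_fit
  expect_equal(f$beta0, 362.78, tolerance = 0.01 / 362.78)
  expect_equal(f$beta_lin, c(-109.01, 7.59, 12.63, 13.56), tolerance = 1e-3)
  expect_equal(f$beta_quad, c(-105.74, -5.19, -13.87, -15.98),
               tolerance = 1e-3)
  expect_equal(unname(f$beta_int["3:4"]), 6.53, tolerance = 1e-2)
  expect_equal(unname(ofi_alcl3_fit$beta_int["1:2"]), -8.45,
               tolerance = 1e-3)
  expect_identical(f$p, 15L)
  expect_identical(f$residual_df, 12L)
})

test_that("ANOVA statistics match the published fit summary", {
  a <- rsm_anova(ofi_fcrc_fit)
  expect_equal(a$rmse, 6.94, tolerance = 0.01)
  expect_gt(a$r2, 0.99)
  expect_lte(a$r2_adj, a$r2)
  expect_lt(a$model_p, 1e-4)
  expect_equal(a$lof_p, 0.1246, tolerance = 0.002)
  b <- rsm_anova(ofi_alcl3_fit)
  expect_equal(b$rmse, 1.60, tolerance = 0.01)
  expect_equal(b$r2, 0.968, tolerance = 0.001)
  expect_equal(b$r2_adj, 0.93, tolerance = 0.01)
  expect_equal(b$lof_p, 0.1826, tolerance = 0.002)
  # coefficient p-values: two-sided t tests (spot-check printed values)
  expect_lt(ofi_fcrc_fit$coef_p[["x1"]], 1e-4)
  expect_equal(ofi_fcrc_fit$coef_p[["x1*x3"]], 0.0113, tolerance = 0.02)
  expect_equal(ofi_fcrc_fit$coef_p[["x3*x4"]], 0.0844, tolerance = 0.02)
})

test_that("predictions match the printed prediction columns", {
  pr <- attr(ofi, "predictions")
  X <- coded_matrix(ofi)
  # run 22's printed FCRC prediction is a digit transposition (322.46 for
  # 325.47); every other entry agrees
  dev_f <- predict(ofi_fcrc_fit, X) - pr$FCRC
  expect_lt(max(abs(dev_f[-22])), 0.15)
  expect_equal(predict(ofi_fcrc_fit, X)[22], 325.47, tolerance = 1e-2)
  dev_a <- predict(ofi_alcl3_fit, X) - pr$AlCl3
  expect_lt(max(abs(dev_a)), 0.15)
  expect_equal(predict(ofi_fcrc_fit, c(1, 0, 1, 0)), 136.40,
               tolerance = 1e-3)
  expect_equal(predict(ofi_fcrc_fit, c(1, 0, 0, -1)), 128.23,
               tolerance = 1e-3)
  expect_equal(predict(ofi_fcrc_fit, rep(0, 4)), 362.78, tolerance = 1e-3)
})

test_that("residuals of an intercept model sum to zero", {
  expect_lt(abs(sum(ofi_fcrc_fit$residuals)), 1e-8 * ofi_fcrc_fit$n)
  expect_lt(abs(sum(ofi_alcl3_fit$residuals)), 1e-8 * ofi_alcl3_fit$n)
})

test_that("OLS equals the brute-force normal-equations solution", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 25
    X <- matrix(runif(n * 3, -1, 1), n, 3)
    y <- rnorm(n, mean = 2 + X[, 1] - 0.5 * X[, 2]^2, sd = 0.3)
    fac <- lapply(1:3, function(i) mae_factor(paste0("f", i), -1, 1))
    spec <- design_spec(fac, 0)
    runs <- data.frame(run_id = 1:n,
                       pattern = strrep("0", 3),  # placeholder labels
                       x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
    ds <- bbd_dataset(spec, runs, list(y = data.frame(run_id = 1:n, mean = y,
                                                      sd = 0)))
    fit <- fit_quadratic(ds, "y")
    Z <- cbind(1, X, X^2, X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 2] * X[, 3])
    beta_ne <- solve(t(Z) %*% Z, t(Z) %*% y)
    expect_equal(unname(fit$coef), drop(beta_ne), tolerance = 1e-8)
  }
})

test_that("inter-response correlation matches the published scatter", {
  expect_equal(response_correlation(ofi, "FCRC", "AlCl3"), 0.5493,
               tolerance = 2e-4)
  expect_equal(response_correlation(ofi, "FCRC", "FCRC"), 1)
})

test_that("cube vertices cover all factor extremes with known values", {
  cv <- cube_vertex_predictions(ofi_fcrc_fit)
  expect_identical(nrow(cv), 16L)
  low <- cv$prediction[rowSums(cv[, 1:4]) == -4]
  high <- cv$prediction[rowSums(cv[, 1:4]) == 4]
  expect_equal(low, 279.46, tolerance = 1e-3)
  expect_equal(high, 129.01, tolerance = 1e-3)
})

test_that("prediction grids have the declared shape and centre value", {
  g <- prediction_grid(ofi_fcrc_fit, 1, 2, resolution = 7)
  expect_identical(nrow(g), 49L)
  ctr <- g[g$xi == 0 & g$xj == 0, ]
  expect_equal(ctr$prediction, ofi_fcrc_fit$beta0)
  # phenolic optimum sits below the centre ethanol level (negative x1)
  prof <- prediction_grid(ofi_fcrc_fit, 1, 2, resolution = 41)
  expect_lt(prof$xi[which.max(prof$prediction)], 0)
  expect_error(prediction_grid(ofi_fcrc_fit, 2, 2), "distinct")
})

test_that("coefficient recovery stays within 3 standard errors", {
  truth <- c(ofi_fcrc_fit$beta0, ofi_fcrc_fit$beta_lin,
             ofi_fcrc_fit$beta_quad, unname(ofi_fcrc_fit$beta_int))
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    sp <- synthetic_surface_spec(4, truth[1], truth[2:5], truth[6:9],
                                 truth[10:15], noise_sd = 2, seed = 100 + s)
    fit <- fit_quadratic(simulate_bbd_dataset(sp, n_center = 3), "y")
    within <- abs(unname(fit$coef) - truth) <= 3 * unname(fit$coef_se)
    hits <- hits + sum(within); total <- total + length(within)
  }
  expect_gte(hits / total, 0.99)
})

test_that("fit serialization round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(ofi_fcrc_fit, path)
  back <- read_fit_json(path)
  expect_equal(back$coef, ofi_fcrc_fit$coef, tolerance = 1e-12)
  expect_equal(predict(back, c(0.3, -0.2, 1, -1)),
               predict(ofi_fcrc_fit, c(0.3, -0.2, 1, -1)), tolerance = 1e-10)
})
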