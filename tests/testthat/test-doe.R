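test_that("run-count formula matches the Box-Behnken combinatorics", {
  expect_identical(bbd_run_count(4, 3), 27L)
  expect_identical(bbd_run_count(3, 0), 12L)
  expect_identical(bbd_run_count(4, 5), 29L)
  expect_error(bbd_run_count(2, 3), "k >= 3")
})

test_that("generated designs have the edge-midpoint structure at every k", {
  for (k in 3:6) {
    for (c0 in c(0L, 3L, 6L)) {
      fac <- lapply(seq_len(k), function(i) mae_factor(paste0("f", i), 0, 10))
      runs <- generate_bbd(design_spec(fac, c0))
      expect_identical(nrow(runs), as.integer(bbd_run_count(k, c0)))
      X <- as.matrix(runs[, paste0("x", seq_len(k))])
      center <- rowSums(abs(X)) == 0
      expect_identical(sum(center), as.integer(c0))
      # non-centre runs: exactly two coordinates at +/-1, the rest 0
      expect_true(all(rowSums(abs(X[!center, , drop = FALSE])) == 2))
      expect_true(all(apply(abs(X[!center, , drop = FALSE]), 1, max) == 1))
      expect_identical(anyDuplicated(runs$run_id), 0L)
    }
  }
  expect_error(design_spec(list(mae_factor("a", 0, 1),
                                mae_factor("b", 0, 1)), 1), "at least 3")
})

test_that("coding is linear in the midpoint and half-range and inverts", {
  eth <- mae_factor("ethanol", 50, 100, "%")
  pow <- mae_factor("power", 400, 800, "W")
  rat <- mae_factor("ratio", 30, 50, "mL/g")
  expect_equal(code_level(75, eth), 0)
  expect_equal(code_level(800, pow), 1)
  expect_equal(code_level(48.175, rat), 0.8175)
  for (f in list(eth, pow, rat)) {
    a <- seq(f$low - f$half_range, f$high + f$half_range, length.out = 11)
    expect_equal(decode_level(code_level(a, f), f), a, tolerance = 1e-12)
    x <- seq(-1.5, 1.5, length.out = 11)
    expect_equal(code_level(decode_level(x, f), f), x, tolerance = 1e-12)
  }
  expect_error(mae_factor("bad", 5, 5), "strictly below")
})

test_that("pattern strings round-trip with coded vectors", {
  expect_identical(pattern_of(c(1, 0, 1, 0)), "+0+0")
  expect_identical(pattern_of(c(-1, 0, 1, 0)), "-0+0")
  expect_identical(pattern_of(c(0, 0, 0, 0)), "0000")
  expect_equal(coded_of("+0+0"), c(1, 0, 1, 0))
  expect_equal(coded_of("−0+0"), c(-1, 0, 1, 0))  # typographic minus
  expect_error(pattern_of(c(0.5, 0, 0)), "not representable")
  expect_error(coded_of("+x0"), "invalid pattern")
})

test_that("DPPH inhibition follows the control-normalized difference", {
  expect_equal(dpph_inhibition(1, 1), 0)
  expect_equal(dpph_inhibition(2, 1), 50)
  expect_equal(dpph_inhibition(1, 0.6043), 39.57)
  expect_error(dpph_inhibition(0, 1), "invalid control")
})

test_that("the packaged press-residue dataset matches the printed design", {
  expect_identical(nrow(ofi), 27L)
  expect_identical(sort(center_run_ids(ofi)), c(8L, 20L, 23L))
  expect_equal(observed_response(ofi, "FCRC")$mean[18], 375.26)
  expect_equal(observed_response(ofi, "FCRC")$sd[18], 1.71)
  expect_equal(observed_response(ofi, "AlCl3")$mean[12], 24.42)
  expect_identical(unique(observed_response(ofi, "FCRC")$n_reps), 3L)
  # patterns re-derived from coded levels match the printed strings
  X <- coded_matrix(ofi)
  expect_identical(unname(apply(X, 1, pattern_of)), ofi$pattern)
  # every non-centre run is an edge midpoint
  noncenter <- ofi$pattern != "0000"
  expect_true(all(rowSums(abs(X[noncenter, ])) == 2))
  # OVAT screening fixture carries all five screening blocks
  ovat <- ofi_ovat_screening()
  expect_setequal(unique(ovat$parameter),
                  c("solvent", "ethanol_pct", "power_W", "time_min",
                    "ratio_mL_g"))
  expect_equal(ovat$FCRC_mean[ovat$level == "ethanol"], 296.59)
})
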