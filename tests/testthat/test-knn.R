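test_that("normalization maps feature range onto [-1, +1] and inverts", {
  X <- cbind(a = c(2, 4, 10), b = c(-1, 0, 3))
  nz <- fit_normalizer(X)
  Xn <- normalize(nz, X)
  expect_equal(apply(Xn, 2, min), c(a = -1, b = -1))
  expect_equal(apply(Xn, 2, max), c(a = 1, b = 1))
  expect_equal(unname(drop(normalize(nz, c(6, 1)))), c(0, 0))
  expect_equal(denormalize(nz, Xn), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_normalizer(cbind(c(1, 1, 1), c(0, 1, 2))),
               "degenerate")
})

test_that("distances match hand values for the closed-form metrics", {
  hp <- function(m, p = 2) knn_hyperparams(m, "equal", 1, p)
  u <- c(0, 0); v <- c(3, 4)
  expect_equal(knn_distance(u, v, hp("euclidean")), 5)
  expect_equal(knn_distance(u, v, hp("cityblock")), 7)
  expect_equal(knn_distance(u, v, hp("chebyshev")), 4)
  expect_equal(knn_distance(c(0, 0), c(1, 1), hp("minkowski", 3)), 2^(1/3))
  expect_equal(knn_distance(c(1, 0), c(0, 1), hp("hamming")), 1)
  expect_equal(knn_distance(c(1, 2, 0), c(1, 3, 0), hp("hamming")), 1/3)
  # jaccard: unequal & not-both-zero over not-both-zero; 0/0 -> 0
  expect_equal(knn_distance(c(1, 0, 2), c(1, 0, 3), hp("jaccard")), 1/2)
  expect_equal(knn_distance(c(0, 0), c(0, 0), hp("jaccard")), 0)
  # cosine/correlation degenerate conventions
  expect_equal(knn_distance(c(0, 0), c(1, 1), hp("cosine")), 1)
  expect_equal(knn_distance(c(2, 2), c(1, 1), hp("correlation")), 1)
  st <- list(var = c(4, 9))
  expect_equal(knn_distance(c(0, 0), c(2, 3), hp("seuclidean"), st),
               sqrt(2))
  st <- list(cov_inv = diag(2))
  expect_equal(knn_distance(u, v, hp("mahalanobis"), st), 5)
})

test_that("every metric is symmetric with zero self-distance", {
  set.seed(4)
  X <- matrix(rnorm(40 * 4), 40, 4)
  state <- list(cov_inv = solve(cov(X)), var = apply(X, 2, var))
  for (m in knn_metrics()) {
    hp <- knn_hyperparams(m, "equal", 1, 2.5)
    for (i in 1:25) {
      u <- X[sample(40, 1), ]; v <- X[sample(40, 1), ]
      duv <- knn_distance(u, v, hp, state)
      expect_gte(duv, -1e-12)
      expect_equal(duv, knn_distance(v, u, hp, state), tolerance = 1e-12)
      expect_equal(knn_distance(u, u, hp, state), 0, tolerance = 1e-12)
    }
  }
})

test_that("mahalanobis distance agrees with the base-R oracle", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4)
  m <- knn_model(X, rnorm(30), knn_hyperparams("mahalanobis", "equal", 1))
  q <- rnorm(4)
  oracle <- sqrt(stats::mahalanobis(X, center = q, cov = cov(X)))
  ours <- vapply(seq_len(30), function(i)
    knn_distance(q, X[i, ], m$hyperparams, m$state), numeric(1))
  expect_equal(ours, unname(oracle), tolerance = 1e-8)
})

test_that("neighbour aggregation follows the weighting scheme", {
  X <- cbind(c(0, 1, 2, 10)); y <- c(10, 40, 7, 100)
  mk <- function(w, k) knn_model(X, y, knn_hyperparams("euclidean", w, k))
  # query at a training point, k = 1: that target (zero-distance rule)
  expect_equal(knn_predict(mk("inverse", 1), 1), 40)
  # k = 2 equal weighting from query 0.5: mean(10, 40)
  expect_equal(knn_predict(mk("equal", 2), 0.5), 25)
  # squared inverse at distances 1 and 2: (10*1 + 40*0.25)/1.25
  expect_equal(knn_predict(mk("squared_inverse", 2), -1), 16)
  # k = n with equal weights equals the global mean
  expect_equal(knn_predict(mk("equal", 4), 0.3), mean(y))
  expect_error(knn_model(X, y, knn_hyperparams("euclidean", "equal", 5)),
               "insufficient neighbors")
})

test_that("predictions are invariant to training-row order", {
  set.seed(21)
  X <- matrix(runif(20 * 3), 20, 3); y <- rnorm(20)
  q <- runif(3)
  perm <- sample(20)
  # continuous metrics only: set-style metrics tie almost surely, and the
  # documented (distance, index) tie-break is order-dependent by design
  for (m in c("euclidean", "cityblock", "minkowski")) {
    hp <- knn_hyperparams(m, "inverse", 3)
    p1 <- knn_predict(knn_model(X, y, hp), q)
    p2 <- knn_predict(knn_model(X[perm, ], y[perm], hp), q)
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("the seeded split is disjoint, exhaustive and reproducible", {
  s <- split_train_val(27, 0.7, 123)
  expect_identical(length(s$train), 19L)
  expect_identical(length(s$val), 8L)
  expect_identical(sort(c(s$train, s$val)), 1:27)
  expect_identical(s, split_train_val(27, 0.7, 123))
  expect_false(identical(s, split_train_val(27, 0.7, 124)))
})

test_that("evaluation metrics behave under exact and shifted predictions", {
  X <- matrix(seq(-1, 1, length.out = 10)); y <- 3 * drop(X) + 1
  m <- knn_model(X, y, knn_hyperparams("euclidean", "inverse", 2))
  ev <- knn_evaluate(m, X, y)  # training-set eval: zero-distance rule
  expect_equal(ev$r, 1)
  expect_equal(ev$rmse, 0)
  ev2 <- knn_evaluate(m, X, y + 2)
  expect_equal(ev2$rmse, 2)
  expect_equal(ev2$r, 1)
})

test_that("all metric/weighting/k configurations are finite on the dataset", {
  for (m in knn_metrics()) {
    for (w in knn_weightings()) {
      for (k in 1:5) {
        mod <- knn_model(ofi_norm$X, ofi_norm$fcrc,
                         knn_hyperparams(m, w, k))
        pred <- knn_predict(mod, ofi_norm$X)
        expect_true(all(is.finite(pred)),
                    info = paste(m, w, k, sep = "/"))
      }
    }
  }
})

test_that("KNN models round-trip through JSON", {
  m <- knn_model(ofi_norm$X, ofi_norm$fcrc,
                 knn_hyperparams("jaccard", "squared_inverse", 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_knn_json(m, path)
  back <- read_knn_json(path)
  q <- ofi_norm$X[5, ] + 0.01
  expect_equal(knn_predict(back, q), knn_predict(m, q), tolerance = 1e-12)
})
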