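## K-nearest-neighbour regression over normalized extraction factors.
## Brute-force neighbour search (n is tens of runs); eleven distance
## metrics, three distance-weighting schemes.

#' Supported distance metrics and weighting schemes
#' @return Character vector of admissible names.
#' @export
knn_metrics <- function() {
  c("euclidean", "chebyshev", "minkowski", "mahalanobis", "cosine",
    "correlation", "spearman", "hamming", "jaccard", "cityblock",
    "seuclidean")
}

#' @rdname knn_metrics
#' @export
knn_weightings <- function() c("equal", "inverse", "squared_inverse")

#' Range normalization to [-1, +1]
#'
#' `fit_normalizer()` records per-feature minima and maxima;
#' `normalize()` maps each feature linearly so its minimum becomes -1 and
#' its maximum +1 (`x' = 2 (x - min) / (max - min) - 1`); `denormalize()`
#' inverts the map.
#'
#' @param X Numeric matrix or data frame (rows = observations).
#' @param spec A `range_normalizer`.
#' @return `fit_normalizer()` returns a `range_normalizer`; the others a
#'   matrix with the same shape as the input.
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  if (any(mx <= mn))
    stop("degenerate normalization: constant feature ",
         paste(colnames(X)[mx <= mn], collapse = ", "))
  structure(list(min = mn, max = mx), class = "range_normalizer")
}

#' @rdname fit_normalizer
#' @export
normalize <- function(spec, X) {
  stopifnot(inherits(spec, "range_normalizer"))
  X <- rbind(X)
  sweep(sweep(X, 2, spec$min), 2, (spec$max - spec$min) / 2, "/") - 1
}

#' @rdname fit_normalizer
#' @export
denormalize <- function(spec, X) {
  stopifnot(inherits(spec, "range_normalizer"))
  X <- rbind(X)
  sweep(sweep((X + 1) / 2, 2, spec$max - spec$min, "*"), 2, spec$min, "+")
}

#' KNN hyperparameters
#'
#' @param metric One of [knn_metrics()].
#' @param weighting One of [knn_weightings()]: neighbour weights 1, 1/d or
#'   1/d^2.
#' @param k Number of neighbours.
#' @param minkowski_exponent Exponent p > 0, used only by the Minkowski
#'   metric.
#' @return An object of class `knn_hyperparams`.
#' @export
knn_hyperparams <- function(metric = "euclidean", weighting = "equal",
                            k = 3L, minkowski_exponent = 2) {
  metric <- match.arg(metric, knn_metrics())
  weighting <- match.arg(weighting, knn_weightings())
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k),
            is.numeric(minkowski_exponent), minkowski_exponent > 0)
  structure(list(metric = metric, weighting = weighting, k = as.integer(k),
                 minkowski_exponent = minkowski_exponent),
            class = "knn_hyperparams")
}

# Metric state computed from the TRAINING inputs only: covariance (inverse)
# for mahalanobis, per-feature variance for seuclidean. Covariance gets a
# 1e-8 ridge when near-singular.
metric_state <- function(X, metric) {
  if (metric == "mahalanobis") {
    S <- stats::cov(X)
    inv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(inv) || rcond_est(S) < 1e-10)
      inv <- solve(S + diag(1e-8, ncol(X)))
    list(cov_inv = inv)
  } else if (metric == "seuclidean") {
    v <- apply(X, 2, stats::var)
    v[v < 1e-12] <- 1e-12
    list(var = v)
  } else list()
}

rcond_est <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  max(min(e), 0) / max(e)
}

#' Distance between two vectors under a KNN configuration
#'
#' Standard definitions throughout. Conventions for the set-style and
#' similarity-style metrics on real vectors: Hamming is the proportion of
#' exactly unequal coordinates; Jaccard is the number of unequal,
#' not-both-zero coordinates over the number of not-both-zero coordinates
#' (0/0 -> 0); cosine/correlation/Spearman distances are one minus the
#' respective similarity, with degenerate (zero or constant) vectors giving
#' distance 1; Spearman ranks use average ties.
#'
#' @param u,v Numeric vectors of equal length.
#' @param hp A [knn_hyperparams()].
#' @param state Metric state from the training inputs (covariance inverse or
#'   per-feature variances) where the metric needs it.
#' @return Non-negative scalar distance.
#' @export
knn_distance <- function(u, v, hp, state = list()) {
  stopifnot(length(u) == length(v))
  d <- u - v
  switch(hp$metric,
    euclidean = sqrt(sum(d^2)),
    cityblock = sum(abs(d)),
    chebyshev = max(abs(d)),
    minkowski = sum(abs(d)^hp$minkowski_exponent)^(1 / hp$minkowski_exponent),
    seuclidean = sqrt(sum(d^2 / state$var)),
    mahalanobis = sqrt(max(drop(t(d) %*% state$cov_inv %*% d), 0)),
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) 1 else 1 - sum(u * v) / (nu * nv)
    },
    correlation = {
      if (length(u) < 2 || stats::sd(u) == 0 || stats::sd(v) == 0) 1
      else 1 - stats::cor(u, v)
    },
    spearman = {
      ru <- rank(u); rv <- rank(v)  # average-rank ties
      if (length(u) < 2 || stats::sd(ru) == 0 || stats::sd(rv) == 0) 1
      else 1 - stats::cor(ru, rv)
    },
    hamming = mean(u != v),
    jaccard = {
      nz <- (u != 0) | (v != 0)
      if (!any(nz)) 0 else sum(u != v & nz) / sum(nz)
    }
  )
}

#' Build a KNN regression model
#'
#' Lazy learner: stores the (normalized) training inputs and targets plus
#' any metric state; all work happens at prediction time.
#'
#' @param X Training inputs, n-by-d numeric matrix (already normalized).
#' @param y Training targets, length n.
#' @param hyperparams A [knn_hyperparams()]; `k` must not exceed n.
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(X, y, hyperparams) {
  stopifnot(inherits(hyperparams, "knn_hyperparams"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  if (hyperparams$k > nrow(X))
    stop("insufficient neighbors: k = ", hyperparams$k,
         " exceeds training size ", nrow(X))
  structure(list(hyperparams = hyperparams, X = X, y = as.numeric(y),
                 state = metric_state(X, hyperparams$metric)),
            class = "knn_model")
}

#' Predict with a KNN regression model
#'
#' Selects the k training points nearest to the query (ties broken by
#' training index, stable ascending), then returns the weighted mean of
#' their targets with weights 1, 1/d or 1/d^2 per the weighting scheme. If
#' any selected neighbour is at distance zero, the unweighted mean of the
#' zero-distance targets is returned (so inverse-weighted prediction at a
#' training point reproduces its target).
#'
#' @param model A [knn_model()].
#' @param query Numeric vector of length d, or an m-by-d matrix.
#' @return Numeric prediction(s).
#' @export
knn_predict <- function(model, query) {
  stopifnot(inherits(model, "knn_model"))
  Q <- rbind(query)
  stopifnot(ncol(Q) == ncol(model$X))
  unname(apply(Q, 1, function(q) knn_predict_one(model, q)))
}

knn_predict_one <- function(model, q) {
  hp <- model$hyperparams
  dists <- vapply(seq_len(nrow(model$X)),
                  function(i) knn_distance(q, model$X[i, ], hp, model$state),
                  numeric(1))
  ord <- order(dists, seq_along(dists))[seq_len(hp$k)]
  dsel <- dists[ord]
  ysel <- model$y[ord]
  if (any(dsel == 0)) return(mean(ysel[dsel == 0]))
  w <- switch(hp$weighting,
              equal = rep(1, length(dsel)),
              inverse = 1 / dsel,
              squared_inverse = 1 / dsel^2)
  sum(w * ysel) / sum(w)
}

#' Seeded train/validation split
#'
#' Uniform random partition without replacement: `ceiling(fraction * n)`
#' rows to training, the rest to validation; disjoint and exhaustive.
#'
#' @param n Number of rows (or a `bbd_dataset`, whose row count is used).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(n, fraction = 0.7, seed = 1L) {
  if (inherits(n, "bbd_dataset")) n <- nrow(n)
  stopifnot(is.numeric(n), n >= 2, fraction > 0, fraction < 1)
  n_train <- ceiling(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = sort(idx), val = setdiff(seq_len(n), idx))
}

#' Correlation and RMSE of model predictions
#'
#' @param model A [knn_model()].
#' @param X Evaluation inputs (normalized), m-by-d.
#' @param y Observed targets, length m (m >= 2 for R).
#' @return List with `r` (Pearson correlation of predicted vs observed; `NA`
#'   when predictions are constant) and `rmse` (divisor = set size).
#' @export
knn_evaluate <- function(model, X, y) {
  X <- rbind(X)
  stopifnot(nrow(X) == length(y), length(y) >= 2L)
  pred <- knn_predict(model, X)
  r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_
       else stats::cor(pred, y)
  list(r = r, rmse = sqrt(mean((pred - y)^2)))
}

#' Serialize / restore a KNN model as JSON
#'
#' @param model A [knn_model()].
#' @param path File path.
#' @return `read_knn_json()` returns a `knn_model`.
#' @export
write_knn_json <- function(model, path) {
  stopifnot(inherits(model, "knn_model"))
  obj <- list(hyperparams = unclass(model$hyperparams),
              X = apply(model$X, 1, as.list), y = model$y)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_knn_json
#' @export
read_knn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- knn_hyperparams(obj$hyperparams$metric, obj$hyperparams$weighting,
                        obj$hyperparams$k, obj$hyperparams$minkowski_exponent)
  X <- do.call(rbind, lapply(obj$X, unlist))
  knn_model(X, obj$y, hp)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
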