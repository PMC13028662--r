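## End-to-end composition: dragonfly-driven KNN hyperparameter tuning,
## desirability optimization of the response-surface fit, multi-objective
## dragonfly optimization over KNN surrogates, and the validation report.

# Decode a continuous dragonfly position into admissible KNN hyperparameters
# (discrete dimensions rounded to the nearest level at evaluation time).
decode_knn_position <- function(x, n_train) {
  metric <- knn_metrics()[clamp_round(x[1], 1, 11)]
  weighting <- knn_weightings()[clamp_round(x[2], 1, 3)]
  k <- clamp_round(x[3], 1, n_train)
  p <- min(max(x[4], 1), 10)
  knn_hyperparams(metric, weighting, k, p)
}

clamp_round <- function(x, lo, hi) as.integer(min(max(round(x), lo), hi))

#' Tune KNN hyperparameters with the dragonfly algorithm
#'
#' Normalizes the full dataset to [-1, +1] (normalization precedes the
#' split), partitions it with [split_train_val()], then searches the mixed
#' hyperparameter space — metric (11 levels), weighting scheme (3 levels),
#' neighbour count `k` in `[1, n_train]`, Minkowski exponent in `[1, 10]` —
#' by dragonfly minimization of the validation RMSE. Discrete dimensions are
#' continuous internally and rounded at evaluation time. The default
#' configuration (euclidean, equal weights, k = 3) is injected into the
#' initial swarm, so the tuned result never underperforms that baseline.
#'
#' @param dataset A `bbd_dataset`.
#' @param response Response name.
#' @param config A [da_config()] for the search (bounds are set
#'   internally; pass `NULL` for the default budget of 100 iterations and
#'   30 agents).
#' @param fraction Training fraction (default 0.7).
#' @param seed Seed for the train/validation split (also the default search
#'   seed when `config` is `NULL`).
#' @return An object of class `knn_tuning`: `best_hyperparams`, `metrics`
#'   (train/val/all r and rmse), `model` (refit on the training split),
#'   `normalizer`, `split`, and the evaluation `log` (one row per objective
#'   evaluation with the decoded hyperparameters and validation RMSE).
#' @export
tune_knn <- function(dataset, response, config = NULL, fraction = 0.7,
                     seed = 1L) {
  stopifnot(inherits(dataset, "bbd_dataset"))
  A <- actual_matrix(dataset)
  y <- observed_response(dataset, response)$mean
  norm <- fit_normalizer(A)
  Xn <- normalize(norm, A)
  split <- split_train_val(nrow(Xn), fraction, seed)
  if (!length(split$val)) stop("invalid split: empty validation set")
  Xtr <- Xn[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- Xn[split$val, , drop = FALSE]; yva <- y[split$val]
  n_train <- nrow(Xtr)
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  objective <- function(pos) {
    hp <- decode_knn_position(pos, n_train)
    model <- knn_model(Xtr, ytr, hp)
    rmse <- knn_evaluate(model, Xva, yva)$rmse
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(metric = hp$metric, weighting = hp$weighting, k = hp$k,
                 minkowski_exponent = hp$minkowski_exponent,
                 val_rmse = rmse)
    rmse
  }
  lower <- c(1, 1, 1, 1); upper <- c(11, 3, n_train, 10)
  if (is.null(config)) {
    config <- da_config(lower, upper, max_iterations = 100L, n_agents = 30L,
                        seed = seed)
  } else {
    config$lower <- lower; config$upper <- upper
  }
  baseline <- c(match("euclidean", knn_metrics()),
                match("equal", knn_weightings()), min(3, n_train), 2)
  config$init <- rbind(baseline)
  res <- da_minimize(objective, config)
  log <- do.call(rbind, log_env$rows)
  best_row <- log[which.min(log$val_rmse), ]
  best_hp <- knn_hyperparams(best_row$metric, best_row$weighting,
                             best_row$k, best_row$minkowski_exponent)
  model <- knn_model(Xtr, ytr, best_hp)
  metrics <- list(
    train = knn_evaluate(model, Xtr, ytr),
    val = knn_evaluate(model, Xva, yva),
    all = knn_evaluate(model, Xn, y)
  )
  structure(list(response_name = response, best_hyperparams = best_hp,
                 metrics = metrics, model = model, normalizer = norm,
                 split = split, log = log, da_result = res),
            class = "knn_tuning")
}

#' @export
print.knn_tuning <- function(x, ...) {
  hp <- x$best_hyperparams
  cat(sprintf("KNN tuning for '%s': %s / %s / k = %d (val RMSE %.4f)\n",
              x$response_name, hp$metric, hp$weighting, hp$k,
              x$metrics$val$rmse))
  m <- x$metrics
  cat(sprintf("  R: train %.4f, val %.4f, all %.4f\n",
              m$train$r, m$val$r, m$all$r))
  cat(sprintf("  RMSE: train %.4f, val %.4f, all %.4f\n",
              m$train$rmse, m$val$rmse, m$all$rmse))
  invisible(x)
}

#' Derringer maximize-type desirability
#'
#' `desirability()` maps a response value onto [0, 1]: 0 at or below the
#' lower anchor `L`, 1 at or above the target `T`, and
#' `((y - L)/(T - L))^s` between. `overall_desirability()` combines
#' per-response desirabilities by their geometric mean.
#'
#' @param value Response value(s).
#' @param L Lower anchor (d = 0).
#' @param T_ Target (d = 1); must exceed `L`.
#' @param s Shape exponent, positive (default 1, linear).
#' @param d Vector of per-response desirabilities.
#' @return Desirability in [0, 1].
#' @export
desirability <- function(value, L, T_, s = 1) {
  if (!(L < T_)) stop("invalid desirability spec: L must be below T")
  stopifnot(s > 0)
  pmin(pmax((value - L) / (T_ - L), 0), 1)^s
}

#' @rdname desirability
#' @export
overall_desirability <- function(d) {
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]")
  exp(mean(log(pmax(d, 0))))  # geometric mean; any zero gives zero
}

#' Desirability-based multi-response optimization of response-surface fits
#'
#' Maximizes the geometric mean of per-response maximize-type scores
#' `max((y - L)/(T - L), 0)^s` over the coded box [-1, +1]^k by dense grid
#' search followed by local refinement (`L-BFGS-B`). The search score is the
#' Derringer desirability WITHOUT its upper saturation: clipping every
#' response at `T` floods the top of the surface with ties (any point where
#' all responses exceed their targets scores exactly 1), leaving the argmax
#' undefined; dropping the clip keeps the score strictly discriminating
#' while preserving the ordering everywhere below the targets. By default
#' each response is anchored at its observed minimum (`L`) and the model's
#' maximum grid prediction (`T`).
#'
#' @param fits Named list of `quadratic_fit` objects (same factors).
#' @param spec Optional named list of desirability anchors per response,
#'   each `list(L=, T=, s=)`; defaults as described above.
#' @param factors Optional [design_spec()] used to express the optimum in
#'   actual units.
#' @param resolution Grid points per axis for the search stage (default 11).
#' @return List with `coded` and (when `factors` is given) `actual` optimum,
#'   `predictions` (per response at the optimum), `desirability`, and the
#'   evaluated `grid_best`.
#' @export
optimize_rsm <- function(fits, spec = NULL, factors = NULL,
                         resolution = 11L) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)),
            all(vapply(fits, inherits, logical(1), "quadratic_fit")))
  k <- fits[[1]]$k
  g <- seq(-1, 1, length.out = resolution)
  G <- as.matrix(expand.grid(rep(list(g), k)))
  preds <- vapply(fits, function(f) predict(f, G), numeric(nrow(G)))
  if (is.null(spec)) {
    spec <- lapply(names(fits), function(r)
      list(L = min(fits[[r]]$y), T = max(preds[, r]), s = 1))
    names(spec) <- names(fits)
  }
  for (r in names(fits)) {
    if (!(spec[[r]]$L < spec[[r]]$T))
      stop("invalid desirability spec for '", r, "': L must be below T")
  }
  score <- function(x) {
    d <- vapply(names(fits), function(r) {
      sp <- spec[[r]]
      pmax((predict(fits[[r]], x) - sp$L) / (sp$T - sp$L), 0)^(sp$s %||% 1)
    }, numeric(1))
    exp(mean(log(d)))
  }
  grid_scores <- apply(G, 1, score)
  i0 <- which.max(grid_scores)
  opt <- stats::optim(G[i0, ], function(x) -score(x), method = "L-BFGS-B",
                      lower = rep(-1, k), upper = rep(1, k))
  coded <- opt$par
  best_d <- -opt$value
  if (best_d < grid_scores[i0]) { coded <- G[i0, ]; best_d <- grid_scores[i0] }
  predictions <- vapply(fits, function(f) predict(f, coded), numeric(1))
  out <- list(coded = unname(coded), predictions = predictions,
              desirability = best_d, grid_best = grid_scores[i0],
              spec = spec)
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "design_spec"))
    out$actual <- stats::setNames(
      vapply(seq_len(k), function(j)
        decode_level(coded[j], factors$factors[[j]]), numeric(1)),
      names(factors$factors))
  }
  out
}

#' Multi-objective optimization over KNN surrogates
#'
#' Runs [moda_optimize()] to maximize every surrogate response at once
#' (internally negated to the minimization convention) over the normalized
#' factor box, then selects the compromise archive member maximizing the
#' sum of the predicted responses.
#'
#' @param models Named list of [knn_model()] objects trained on the full
#'   normalized dataset.
#' @param normalizer The `range_normalizer` used to build the models, for
#'   reporting the optimum in actual units.
#' @param config A [da_config()]; pass `NULL` for the default budget (100
#'   iterations, 30 agents, seed 1) over [-1, 1]^d.
#' @return List with the `pareto_archive` (objectives restored to the
#'   maximization scale), `compromise` (normalized coordinates),
#'   `compromise_actual`, and `predictions` at the compromise.
#' @export
optimize_knn_moda <- function(models, normalizer, config = NULL) {
  stopifnot(is.list(models), length(models) >= 2L, !is.null(names(models)),
            all(vapply(models, inherits, logical(1), "knn_model")))
  d <- ncol(models[[1]]$X)
  if (is.null(config))
    config <- da_config(rep(-1, d), rep(1, d), max_iterations = 100L,
                        n_agents = 30L, seed = 1L)
  objectives <- lapply(models, function(m) function(x) -knn_predict(m, x))
  archive <- moda_optimize(objectives, config)
  pred_mat <- -archive$objectives
  colnames(pred_mat) <- names(models)
  i <- which.max(rowSums(pred_mat))
  compromise <- archive$positions[i, ]
  out <- list(archive = archive, pareto_predictions = pred_mat,
              compromise = compromise,
              predictions = pred_mat[i, ])
  if (!missing(normalizer) && !is.null(normalizer))
    out$compromise_actual <- drop(denormalize(normalizer, compromise))
  out
}

#' Validation report: experimental vs predicted responses
#'
#' Tabulates, per response, the experimental mean (plus/minus sd), the model
#' prediction and the absolute error, and appends a summed-response row
#' whose entries are the componentwise sums.
#'
#' @param experimental Data frame with columns `response`, `mean`, `sd`.
#' @param predicted Named numeric vector of predictions, names matching
#'   `experimental$response`.
#' @return Data frame with columns `response`, `experimental_mean`,
#'   `experimental_sd`, `predicted`, `error`; last row is `"sum"`.
#' @examples
#' vi <- ofi_validation_inputs()
#' validation_report(vi$knn_da$experimental, vi$knn_da$predicted)
#' @export
validation_report <- function(experimental, predicted) {
  stopifnot(is.data.frame(experimental),
            all(c("response", "mean", "sd") %in% names(experimental)),
            setequal(experimental$response, names(predicted)))
  pred <- unname(predicted[experimental$response])
  out <- data.frame(response = experimental$response,
                    experimental_mean = experimental$mean,
                    experimental_sd = experimental$sd,
                    predicted = pred,
                    error = abs(experimental$mean - pred))
  rbind(out, data.frame(response = "sum",
                        experimental_mean = sum(out$experimental_mean),
                        experimental_sd = sum(out$experimental_sd),
                        predicted = sum(out$predicted),
                        error = abs(sum(out$experimental_mean) -
                                      sum(out$predicted))))
}
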