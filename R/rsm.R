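## Second-order response-surface fitting on coded Box-Behnken factors.
## The canonical model is the FULL expansion: intercept, k linear, k pure
## quadratic and k(k-1)/2 two-way interaction terms (p = 1 + 2k + k(k-1)/2).

# n x k coded matrix -> n x (p-1) term matrix in canonical order:
# x1..xk, x1^2..xk^2, then interactions i<j lexicographic.
quadratic_terms <- function(X) {
  X <- rbind(X)  # promote a bare vector to a 1-row matrix
  k <- ncol(X)
  pairs <- utils::combn(k, 2)
  M <- cbind(X, X^2,
             X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE])
  colnames(M) <- c(paste0("x", 1:k), paste0("x", 1:k, "^2"),
                   paste0("x", pairs[1, ], "*x", pairs[2, ]))
  M
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares of the observed per-run response means on the full
#' quadratic expansion of the coded factors: intercept, linear, pure
#' quadratic and all two-way interaction terms (15 parameters for k = 4).
#' Fitting is unweighted and uses run means; replicate standard deviations
#' are carried along for lack-of-fit testing only.
#'
#' @param dataset A `bbd_dataset`.
#' @param response Name of the response to fit.
#' @return An object of class `quadratic_fit`: coefficient estimates
#'   (`beta0`, `beta_lin`, `beta_quad`, `beta_int`), standard errors,
#'   t statistics and two-sided p-values, plus `sse`, `sst`, `residual_df`
#'   and the data needed for [rsm_anova()].
#' @examples
#' \donttest{
#' fit <- fit_quadratic(ofi_press_residue(), "FCRC")
#' fit$beta0          # 362.78
#' predict(fit, c(0, 0, 0, 0))
#' }
#' @export
fit_quadratic <- function(dataset, response) {
  stopifnot(inherits(dataset, "bbd_dataset"))
  ob <- observed_response(dataset, response)
  X <- coded_matrix(dataset)
  y <- ob$mean
  k <- ncol(X)
  M <- quadratic_terms(X)
  p <- ncol(M) + 1L
  n <- nrow(M)
  if (n < p) stop("unestimable model: ", n, " runs for ", p, " parameters")
  df <- as.data.frame(M)
  names(df) <- paste0("t", seq_len(ncol(M)))  # syntactic names for lm
  df$y <- y
  fit <- stats::lm(y ~ ., data = df)
  if (fit$rank < p) stop("unestimable model: design matrix is rank deficient")
  # summary.lm warns on interpolating (zero-residual) fits, a legitimate
  # case here (noise-free synthetic surfaces); the SEs are then just 0
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", colnames(M))
  se <- sm$coefficients[, "Std. Error"]
  tv <- sm$coefficients[, "t value"]
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(se) <- names(tv) <- names(pv) <- names(coefs)
  pairs <- utils::combn(k, 2)
  beta_int <- coefs[(2L + 2L * k):p]
  structure(list(
    response_name = response, k = k,
    beta0 = unname(coefs[1]),
    beta_lin = unname(coefs[2:(k + 1)]),
    beta_quad = unname(coefs[(k + 2):(2 * k + 1)]),
    beta_int = stats::setNames(unname(beta_int),
                               paste0(pairs[1, ], ":", pairs[2, ])),
    coef = coefs, coef_se = se, coef_t = tv, coef_p = pv,
    n = n, p = p, residual_df = n - p,
    sse = sum(stats::resid(fit)^2),
    sst = sum((y - mean(y))^2),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::resid(fit)),
    y = y, run_id = ob$run_id,
    center_run_ids = center_run_ids(dataset)
  ), class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Second-order fit of '%s' (k = %d, %d runs, %d parameters)\n",
              x$response_name, x$k, x$n, x$p))
  tab <- data.frame(estimate = x$coef, se = x$coef_se,
                    t = x$coef_t, p = x$coef_p)
  print(round(tab, 4))
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' Evaluates `beta0 + sum(bj xj) + sum(bjj xj^2) + sum(bij xi xj)` at coded
#' points.
#'
#' @param object A `quadratic_fit`.
#' @param newdata Coded point: numeric vector of length k or an n-by-k
#'   matrix/data frame.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.quadratic_fit <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata) else rbind(newdata)
  stopifnot(ncol(X) == object$k)
  unname(drop(cbind(1, quadratic_terms(X)) %*% object$coef))
}

#' ANOVA report for a response-surface fit
#'
#' Computes R-squared, adjusted R-squared, RMSE (root of SSE over residual
#' df), the model F test, and — when the design carries replicated centre
#' runs — the lack-of-fit F test, with pure error estimated from the centre
#' replicates only.
#'
#' @param fit A `quadratic_fit`.
#' @return An object of class `anova_report`: `r2`, `r2_adj`, `rmse`,
#'   `model_f`, `model_p`, and (if estimable) `lof_f`, `lof_p`, `ss_pure_error`,
#'   `df_pure_error`, `ss_lack_of_fit`, `df_lack_of_fit`, plus the
#'   per-coefficient p-values `coef_p`.
#' @examples
#' \donttest{
#' rep <- rsm_anova(fit_quadratic(ofi_press_residue(), "FCRC"))
#' rep$rmse   # 6.94
#' }
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  n <- fit$n; p <- fit$p
  if (fit$residual_df < 1) stop("no residual degrees of freedom (n <= p)")
  r2 <- 1 - fit$sse / fit$sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  rmse <- sqrt(fit$sse / (n - p))
  ssr <- fit$sst - fit$sse
  model_f <- (ssr / (p - 1)) / (fit$sse / (n - p))
  model_p <- stats::pf(model_f, p - 1, n - p, lower.tail = FALSE)
  out <- list(response_name = fit$response_name,
              r2 = r2, r2_adj = r2_adj, rmse = rmse,
              model_f = model_f, model_p = model_p,
              coef_p = fit$coef_p)
  ctr <- fit$run_id %in% fit$center_run_ids
  if (sum(ctr) >= 2) {
    yc <- fit$y[ctr]
    ss_pe <- sum((yc - mean(yc))^2)
    df_pe <- sum(ctr) - 1L
    df_lof <- fit$residual_df - df_pe
    ss_lof <- fit$sse - ss_pe
    if (df_lof >= 1) {
      lof_f <- (ss_lof / df_lof) / (ss_pe / df_pe)
      out$lof_f <- lof_f
      out$lof_p <- stats::pf(lof_f, df_lof, df_pe, lower.tail = FALSE)
      out$ss_pure_error <- ss_pe; out$df_pure_error <- df_pe
      out$ss_lack_of_fit <- ss_lof; out$df_lack_of_fit <- df_lof
    }
  }
  structure(out, class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("ANOVA for '%s': R2 = %.4f, adj R2 = %.4f, RMSE = %.4f\n",
              x$response_name, x$r2, x$r2_adj, x$rmse))
  cat(sprintf("  model F = %.2f (p = %.3g)\n", x$model_f, x$model_p))
  if (!is.null(x$lof_f))
    cat(sprintf("  lack of fit F = %.2f (p = %.4f)\n", x$lof_f, x$lof_p))
  invisible(x)
}

#' Pearson correlation between two observed responses
#'
#' @param dataset A `bbd_dataset`.
#' @param resp_a,resp_b Response names.
#' @return Pearson product-moment correlation of the per-run observed means.
#' @export
response_correlation <- function(dataset, resp_a, resp_b) {
  a <- observed_response(dataset, resp_a)$mean
  b <- observed_response(dataset, resp_b)$mean
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a response has zero variance")
  stats::cor(a, b)
}

#' Predictions at the factor-range extremes (cube vertices)
#'
#' Evaluates the fitted model at all 2^k coded vertices (every factor at
#' -1 or +1), the values displayed at the corners of cube plots.
#'
#' @param fit A `quadratic_fit`.
#' @return Data frame with the k coded vertex coordinates and `prediction`.
#' @export
cube_vertex_predictions <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  V <- as.matrix(expand.grid(rep(list(c(-1, 1)), fit$k)))
  colnames(V) <- paste0("x", seq_len(fit$k))
  out <- as.data.frame(V)
  out$prediction <- predict(fit, V)
  out
}

#' Prediction grid over two coded axes
#'
#' Regular `resolution` x `resolution` grid over the coded square [-1, +1]^2
#' on two chosen factors, the remaining factors held at `fixed`; the numeric
#' export behind contour and profiler displays.
#'
#' @param fit A `quadratic_fit`.
#' @param axis_i,axis_j Distinct factor indices in `1:k`.
#' @param fixed Numeric vector of length k supplying the coded coordinates of
#'   the non-axis factors (entries at `axis_i`, `axis_j` are ignored).
#' @param resolution Points per axis (default 21).
#' @return Data frame with columns `xi`, `xj`, `prediction`.
#' @export
prediction_grid <- function(fit, axis_i, axis_j, fixed = rep(0, fit$k),
                            resolution = 21L) {
  stopifnot(inherits(fit, "quadratic_fit"),
            axis_i %in% seq_len(fit$k), axis_j %in% seq_len(fit$k),
            length(fixed) == fit$k, resolution >= 2L)
  if (axis_i == axis_j) stop("grid axes must be distinct")
  g <- seq(-1, 1, length.out = resolution)
  pts <- expand.grid(xi = g, xj = g)
  X <- matrix(rep(fixed, each = nrow(pts)), ncol = fit$k)
  X[, axis_i] <- pts$xi
  X[, axis_j] <- pts$xj
  pts$prediction <- predict(fit, X)
  pts
}

#' Serialize a fitted model as JSON (lossless round trip)
#'
#' @param fit A `quadratic_fit`.
#' @param path File path.
#' @return `read_fit_json()` returns a `quadratic_fit`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "quadratic_fit"))
  obj <- unclass(fit)
  obj$beta_int <- as.list(obj$beta_int)
  for (f in c("coef", "coef_se", "coef_t", "coef_p")) obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta_int <- unlist(obj$beta_int)
  for (f in c("coef", "coef_se", "coef_t", "coef_p")) obj[[f]] <- unlist(obj[[f]])
  ints <- c("k", "n", "p", "residual_df", "run_id", "center_run_ids")
  for (f in ints) obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "quadratic_fit")
}
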