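## Synthetic Box-Behnken experiments from known second-order surfaces, and
## canonical optimizer test surfaces, so every pipeline stage is testable
## without external data.

#' Specify a ground-truth second-order surface
#'
#' The coefficient layout matches `quadratic_fit`: intercept, k linear,
#' k pure quadratic, k(k-1)/2 interaction terms (pairs i < j, lexicographic).
#' Replicate noise is homoscedastic Gaussian with standard deviation
#' `noise_sd`; the triplicate default mirrors the laboratory protocol the
#' generator emulates.
#'
#' @param k Number of factors (>= 3 for design generation).
#' @param beta0 Intercept.
#' @param beta_lin,beta_quad Numeric vectors of length k.
#' @param beta_int Numeric vector of length k(k-1)/2 (pairs in lexicographic
#'   order), or a named vector with names like `"1:2"`.
#' @param noise_sd Replicate noise standard deviation, >= 0.
#' @param n_reps Replicates per run (default 3).
#' @param seed Integer seed.
#' @return An object of class `synthetic_surface_spec`.
#' @export
synthetic_surface_spec <- function(k, beta0, beta_lin, beta_quad, beta_int,
                                   noise_sd = 0, n_reps = 3L, seed = 1L) {
  n_int <- k * (k - 1) / 2
  stopifnot(length(beta_lin) == k, length(beta_quad) == k,
            length(beta_int) == n_int, noise_sd >= 0, n_reps >= 1)
  structure(list(k = as.integer(k), beta0 = beta0, beta_lin = beta_lin,
                 beta_quad = beta_quad, beta_int = unname(beta_int),
                 noise_sd = noise_sd, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "synthetic_surface_spec")
}

# Evaluate the true polynomial at coded points (n x k matrix).
eval_surface <- function(spec, X) {
  X <- rbind(X)
  coefs <- c(spec$beta0, spec$beta_lin, spec$beta_quad, spec$beta_int)
  unname(drop(cbind(1, quadratic_terms(X)) %*% coefs))
}

#' Simulate a Box-Behnken experiment from a known surface
#'
#' Builds the k-factor Box-Behnken design, evaluates the true second-order
#' polynomial at each coded run, adds independent Gaussian replicate noise,
#' and records the per-run mean and sd over `n_reps` replicates. Seeded and
#' reproducible.
#'
#' @param spec A [synthetic_surface_spec()].
#' @param n_center Number of centre points (default 3).
#' @param factors Optional list of [mae_factor()]s; by default each factor
#'   spans [-1, 1] so actual and coded units coincide.
#' @param response Name of the simulated response column (default `"y"`).
#' @return A `bbd_dataset`. The true run-level surface values are attached
#'   as attribute `"truth"`.
#' @examples
#' sp <- synthetic_surface_spec(3, 10, c(1, 2, 3), c(-1, 0, 1),
#'                              c(0.5, 0, -0.5), noise_sd = 0)
#' d <- simulate_bbd_dataset(sp)
#' @export
simulate_bbd_dataset <- function(spec, n_center = 3L, factors = NULL,
                                 response = "y") {
  stopifnot(inherits(spec, "synthetic_surface_spec"))
  if (is.null(factors))
    factors <- lapply(seq_len(spec$k), function(j)
      mae_factor(paste0("f", j), -1, 1))
  dspec <- design_spec(factors, n_center)
  runs <- generate_bbd(dspec)
  X <- as.matrix(runs[, paste0("x", seq_len(spec$k))])
  truth <- eval_surface(spec, X)
  sims <- with_seed(spec$seed, {
    matrix(stats::rnorm(length(truth) * spec$n_reps, mean = rep(truth,
           each = spec$n_reps), sd = spec$noise_sd),
           ncol = spec$n_reps, byrow = TRUE)
  })
  observed <- list(data.frame(run_id = runs$run_id,
                              mean = rowMeans(sims),
                              sd = apply(sims, 1, stats::sd)))
  names(observed) <- response
  out <- bbd_dataset(dspec, runs, observed, n_reps = spec$n_reps)
  attr(out, "truth") <- truth
  out
}

## Coefficients of the published full second-order models (coded factors):
## the phenolic (FCRC) and flavonoid (AlCl3) response surfaces of the
## press-residue study, used as fixed test surfaces.
table_fcrc_coefs <- function() {
  list(beta0 = 362.78,
       beta_lin = c(-109.01, 7.59, 12.63, 13.56),
       beta_quad = c(-105.74, -5.19, -13.87, -15.98),
       beta_int = c(1.86, -10.39, -9.74, 1.342, -7.37, 6.53))
}

table_alcl3_coefs <- function() {
  list(beta0 = 37.24,
       beta_lin = c(-5.59, -0.23, 1.69, 1.57),
       beta_quad = c(0.07, 0.43, 0.81, -1.66),
       beta_int = c(-8.45, -0.57, -3.17, 2.19, -0.57, 4.71))
}

#' Canonical optimizer test surfaces
#'
#' Named objective functions with documented domains and known optima:
#' \describe{
#'   \item{`sphere`}{`sum(x^2)`, any dimension; minimum 0 at the origin.}
#'   \item{`neg_quadratic_known_max`}{`-(sum((x - 0.3)^2))`, maximum 0 at
#'     `x = 0.3` elementwise (a concave surface with known interior argmax).}
#'   \item{`table3_fcrc`, `table3_alcl3`}{The published full second-order
#'     models of the press-residue responses on the coded box [-1, 1]^4
#'     (e.g. `table3_fcrc(rep(0, 4))` is 362.78).}
#'   \item{`biobjective_x2`}{List of the two convex objectives `x^2` and
#'     `(x - 2)^2` on [-4, 6]; the Pareto set is exactly [0, 2].}
#' }
#'
#' @param name Surface name.
#' @return A function (or, for `biobjective_x2`, a list of two functions)
#'   with attributes `domain` and, where known, `optimum`.
#' @export
make_test_surface <- function(name) {
  switch(name,
    sphere = structure(function(x) sum(x^2),
                       domain = c(-5, 5), optimum = 0),
    neg_quadratic_known_max =
      structure(function(x) -sum((x - 0.3)^2),
                domain = c(-1, 1), optimum = 0.3),
    table3_fcrc = {
      cf <- table_fcrc_coefs()
      sp <- synthetic_surface_spec(4, cf$beta0, cf$beta_lin, cf$beta_quad,
                                   cf$beta_int)
      structure(function(x) eval_surface(sp, x), domain = c(-1, 1))
    },
    table3_alcl3 = {
      cf <- table_alcl3_coefs()
      sp <- synthetic_surface_spec(4, cf$beta0, cf$beta_lin, cf$beta_quad,
                                   cf$beta_int)
      structure(function(x) eval_surface(sp, x), domain = c(-1, 1))
    },
    biobjective_x2 = structure(
      list(function(x) sum(x^2), function(x) sum((x - 2)^2)),
      domain = c(-4, 6), pareto_set = c(0, 2)),
    stop("unavailable fixture: unknown test surface '", name, "'")
  )
}
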