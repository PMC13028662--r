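## Dragonfly swarm optimizers. Agents combine separation, alignment and
## cohesion within an adaptive neighbourhood radius, attraction to the best
## solution seen (food) and repulsion from the worst (enemy), with an
## inertia-weighted step; isolated agents take a Levy flight. The
## multi-objective variant steers food/enemy selection by the crowding of a
## bounded Pareto archive.

#' Configure a dragonfly optimization run
#'
#' The behaviour-weight schedule follows the canonical formulation:
#' separation/alignment/cohesion weights are `2 * runif() * c_t` with
#' `c_t = max(0.1 - t * 0.1 / (T/2), 0)`, food attraction `2 * runif()`,
#' enemy repulsion `c_t`, and inertia annealed linearly over `w_range`.
#' The neighbourhood radius grows from a quarter of the box to the full box
#' over the run; steps are clamped to a tenth of the box per iteration.
#'
#' @param lower,upper Finite bound vectors, `lower < upper` elementwise.
#' @param max_iterations Iteration budget (default 100).
#' @param n_agents Swarm size (default 30).
#' @param seed Integer seed; identical configurations reproduce identical runs.
#' @param archive_capacity Pareto archive bound (multi-objective only).
#' @param n_segments Hypercube segments per objective for archive crowding.
#' @param levy_exponent Levy flight stability exponent (default 1.5).
#' @param w_range Inertia weight annealed linearly from `w_range[1]` to
#'   `w_range[2]`.
#' @param init Optional matrix of initial agent positions (rows; recycled
#'   positions beyond `n_agents` ignored, remaining agents uniform in the box).
#' @return An object of class `da_config`.
#' @export
da_config <- function(lower, upper, max_iterations = 100L, n_agents = 30L,
                      seed = 1L, archive_capacity = 100L, n_segments = 10L,
                      levy_exponent = 1.5, w_range = c(0.9, 0.4),
                      init = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper),
            max_iterations >= 1, n_agents >= 2)
  if (!is.null(init)) {
    init <- rbind(init)
    stopifnot(ncol(init) == length(lower))
  }
  structure(list(lower = lower, upper = upper,
                 max_iterations = as.integer(max_iterations),
                 n_agents = as.integer(n_agents), seed = as.integer(seed),
                 archive_capacity = as.integer(archive_capacity),
                 n_segments = as.integer(n_segments),
                 levy_exponent = levy_exponent, w_range = w_range,
                 init = init),
            class = "da_config")
}

# Mantegna Levy step, length d.
levy_step <- function(d, beta) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  sigma <- (num / den)^(1 / beta)
  0.01 * stats::rnorm(d) * sigma / abs(stats::rnorm(d))^(1 / beta)
}

clip_step <- function(x, dx, lower, upper) {
  xn <- x + dx
  low <- xn < lower; high <- xn > upper
  xn[low] <- lower[low]; xn[high] <- upper[high]
  dx[low | high] <- 0  # zero the offending step component at the boundary
  list(x = xn, dx = dx)
}

#' Single-objective dragonfly minimization
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param config A [da_config()].
#' @return List with `best_position`, `best_value`, and `trace` (the
#'   best-so-far value after each iteration, non-increasing).
#' @examples
#' cfg <- da_config(rep(-5, 2), rep(5, 2), max_iterations = 50, seed = 1)
#' da_minimize(function(x) sum(x^2), cfg)$best_value
#' @export
da_minimize <- function(objective, config) {
  stopifnot(inherits(config, "da_config"))
  wrapped <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) stop("invalid objective: non-finite value")
    v
  }
  with_seed(config$seed, da_loop_single(wrapped, config))
}

da_loop_single <- function(objective, config) {
  lo <- config$lower; up <- config$upper
  d <- length(lo); n <- config$n_agents; Tmax <- config$max_iterations
  range <- up - lo
  delta_max <- range / 10
  X <- sweep(sweep(matrix(stats::runif(n * d), n, d), 2, range, "*"),
             2, lo, "+")
  if (!is.null(config$init)) {
    m <- min(nrow(config$init), n)
    X[seq_len(m), ] <- config$init[seq_len(m), , drop = FALSE]
  }
  DX <- matrix(0, n, d)
  food_pos <- X[1, ]; food_val <- Inf
  enemy_pos <- X[1, ]; enemy_val <- -Inf
  trace <- numeric(Tmax)
  for (it in seq_len(Tmax)) {
    vals <- apply(X, 1, objective)
    ibest <- which.min(vals); iworst <- which.max(vals)
    if (vals[ibest] < food_val) { food_val <- vals[ibest]; food_pos <- X[ibest, ] }
    if (vals[iworst] > enemy_val) { enemy_val <- vals[iworst]; enemy_pos <- X[iworst, ] }
    upd <- da_update_swarm(X, DX, food_pos, enemy_pos, it, config)
    X <- upd$X; DX <- upd$DX
    trace[it] <- food_val
  }
  vals <- apply(X, 1, objective)
  ibest <- which.min(vals)
  if (vals[ibest] < food_val) { food_val <- vals[ibest]; food_pos <- X[ibest, ] }
  list(best_position = food_pos, best_value = food_val, trace = trace)
}

# One swarm update shared by DA and MODA. Food/enemy positions are supplied
# per agent (matrix) or globally (vector).
da_update_swarm <- function(X, DX, food_pos, enemy_pos, it, config) {
  lo <- config$lower; up <- config$upper
  d <- length(lo); n <- nrow(X); Tmax <- config$max_iterations
  range <- up - lo
  delta_max <- range / 10
  r <- range / 4 + range * 2 * (it / Tmax)
  w <- config$w_range[1] -
    it * (config$w_range[1] - config$w_range[2]) / Tmax
  ct <- max(0.1 - it * 0.1 / (Tmax / 2), 0)
  food_m <- if (is.matrix(food_pos)) food_pos else
    matrix(food_pos, n, d, byrow = TRUE)
  enemy_m <- if (is.matrix(enemy_pos)) enemy_pos else
    matrix(enemy_pos, n, d, byrow = TRUE)
  for (i in seq_len(n)) {
    diff <- sweep(X, 2, X[i, ])
    nb <- which(apply(abs(diff), 1, function(z) all(z <= r)) &
                  seq_len(n) != i)
    S <- if (length(nb)) -colSums(sweep(X[nb, , drop = FALSE], 2, X[i, ]))
         else numeric(d)
    A <- if (length(nb)) colMeans(DX[nb, , drop = FALSE]) else DX[i, ]
    C <- if (length(nb)) colMeans(X[nb, , drop = FALSE]) - X[i, ]
         else numeric(d)
    food_near <- all(abs(food_m[i, ] - X[i, ]) <= r)
    enemy_near <- all(abs(enemy_m[i, ] - X[i, ]) <= r)
    Fv <- if (food_near) food_m[i, ] - X[i, ] else numeric(d)
    Ev <- if (enemy_near) enemy_m[i, ] + X[i, ] else numeric(d)
    if (food_near) {
      s <- 2 * stats::runif(1) * ct; a <- 2 * stats::runif(1) * ct
      cc <- 2 * stats::runif(1) * ct; f <- 2 * stats::runif(1); e <- ct
      DX[i, ] <- s * S + a * A + cc * C + f * Fv + e * Ev + w * DX[i, ]
      DX[i, ] <- pmin(pmax(DX[i, ], -delta_max), delta_max)
      res <- clip_step(X[i, ], DX[i, ], lo, up)
    } else if (length(nb)) {
      DX[i, ] <- w * DX[i, ] + stats::runif(1) * A +
        stats::runif(1) * C + stats::runif(1) * S
      DX[i, ] <- pmin(pmax(DX[i, ], -delta_max), delta_max)
      res <- clip_step(X[i, ], DX[i, ], lo, up)
    } else {
      step <- levy_step(d, config$levy_exponent) * X[i, ]
      DX[i, ] <- 0
      res <- clip_step(X[i, ], step, lo, up)
      res$dx <- DX[i, ]
    }
    X[i, ] <- res$x; DX[i, ] <- res$dx
  }
  list(X = X, DX = DX)
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` when it is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(a <= b) && any(a < b)
}

# Archive crowding: fixed hypercube segmentation of the archive's objective
# bounding box, n_segments cells per objective. Returns the per-member count
# of archive members sharing its cell.
archive_crowding <- function(obj_mat, n_segments) {
  rng <- apply(obj_mat, 2, range)
  width <- rng[2, ] - rng[1, ]
  width[width == 0] <- 1
  cell <- apply(obj_mat, 1, function(o) {
    idx <- pmin(floor((o - rng[1, ]) / width * n_segments), n_segments - 1)
    paste(idx, collapse = ",")
  })
  counts <- table(cell)
  as.integer(counts[cell])
}

# Add candidate (position, objectives) rows to the archive, keep only
# mutually non-dominated members, truncate most-crowded first at capacity.
archive_update <- function(archive, pos, obj, capacity, n_segments) {
  P <- rbind(archive$positions, pos)
  O <- rbind(archive$objectives, obj)
  dup <- duplicated(round(O, 12))
  P <- P[!dup, , drop = FALSE]; O <- O[!dup, , drop = FALSE]
  n <- nrow(O)
  dominated <- vapply(seq_len(n), function(i)
    any(vapply(seq_len(n), function(j)
      j != i && dominates(O[j, ], O[i, ]), logical(1))), logical(1))
  P <- P[!dominated, , drop = FALSE]; O <- O[!dominated, , drop = FALSE]
  while (nrow(O) > capacity) {
    crowd <- archive_crowding(O, n_segments)
    cand <- which(crowd == max(crowd))
    drop_i <- cand[sample.int(length(cand), 1)]
    P <- P[-drop_i, , drop = FALSE]; O <- O[-drop_i, , drop = FALSE]
  }
  list(positions = P, objectives = O)
}

# Roulette draw of one archive index: food from sparse cells (weight
# 1/count), enemy from crowded cells (weight count).
archive_select <- function(archive, n_segments, mode = c("food", "enemy")) {
  mode <- match.arg(mode)
  n <- nrow(archive$objectives)
  if (n == 1L) return(1L)
  crowd <- archive_crowding(archive$objectives, n_segments)
  w <- if (mode == "food") 1 / crowd else crowd
  sample.int(n, 1, prob = w / sum(w))
}

#' Multi-objective dragonfly optimization
#'
#' Runs the dragonfly dynamics with per-agent food drawn from a sparse
#' (least-crowded) region of a bounded Pareto archive and enemy from a
#' crowded one, via roulette selection; the archive is refreshed every
#' iteration with dominance filtering and crowding-based truncation.
#' All objectives are minimized.
#'
#' @param objectives List of at least two objective functions.
#' @param config A [da_config()]; `archive_capacity` and `n_segments`
#'   control the archive.
#' @return An object of class `pareto_archive`: list with `positions` and
#'   `objectives` matrices (rows are mutually non-dominated solutions).
#' @export
moda_optimize <- function(objectives, config) {
  stopifnot(is.list(objectives), length(objectives) >= 2L,
            inherits(config, "da_config"))
  wrapped <- function(x) {
    v <- vapply(objectives, function(f) f(x), numeric(1))
    if (any(!is.finite(v))) stop("invalid objective: non-finite value")
    v
  }
  with_seed(config$seed, moda_loop(wrapped, config))
}

moda_loop <- function(objective_vec, config) {
  lo <- config$lower; up <- config$upper
  d <- length(lo); n <- config$n_agents; Tmax <- config$max_iterations
  X <- sweep(sweep(matrix(stats::runif(n * d), n, d), 2, up - lo, "*"),
             2, lo, "+")
  if (!is.null(config$init)) {
    m <- min(nrow(config$init), n)
    X[seq_len(m), ] <- config$init[seq_len(m), , drop = FALSE]
  }
  DX <- matrix(0, n, d)
  archive <- list(positions = NULL, objectives = NULL)
  for (it in seq_len(Tmax)) {
    O <- matrix(t(apply(X, 1, objective_vec)), nrow = n)
    archive <- archive_update(archive, X, O, config$archive_capacity,
                              config$n_segments)
    food_idx <- vapply(seq_len(n), function(i)
      archive_select(archive, config$n_segments, "food"), integer(1))
    enemy_idx <- vapply(seq_len(n), function(i)
      archive_select(archive, config$n_segments, "enemy"), integer(1))
    food_rows <- archive$positions[food_idx, , drop = FALSE]
    enemy_rows <- archive$positions[enemy_idx, , drop = FALSE]
    upd <- da_update_swarm(X, DX, food_rows, enemy_rows, it, config)
    X <- upd$X; DX <- upd$DX
  }
  O <- matrix(t(apply(X, 1, objective_vec)), nrow = n)
  archive <- archive_update(archive, X, O, config$archive_capacity,
                            config$n_segments)
  structure(archive, class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("Pareto archive: %d non-dominated solutions, %d objectives\n",
              nrow(x$objectives), ncol(x$objectives)))
  invisible(x)
}
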