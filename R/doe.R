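#' Define an extraction factor
#'
#' A factor is described by its actual low and high levels; the centre level
#' and the half-range follow from them. Coded levels -1/0/+1 map linearly to
#' low/centre/high.
#'
#' @param name Factor name (e.g. `"ethanol"`).
#' @param low,high Actual low (-1) and high (+1) levels; `low < high`.
#' @param units Unit string, for printing only.
#' @return An object of class `mae_factor` with fields `name`, `low`, `high`,
#'   `center`, `half_range`, `units`.
#' @examples
#' eth <- mae_factor("ethanol", 50, 100, "%")
#' code_level(75, eth)    # 0
#' decode_level(1, eth)   # 100
#' @export
mae_factor <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (!(low < high)) stop("factor '", name, "': low must be strictly below high")
  structure(list(name = name, low = low, high = high,
                 center = (low + high) / 2, half_range = (high - low) / 2,
                 units = units),
            class = "mae_factor")
}

#' @export
print.mae_factor <- function(x, ...) {
  cat(sprintf("Factor %s: %g / %g / %g %s (coded -1/0/+1)\n",
              x$name, x$low, x$center, x$high, x$units))
  invisible(x)
}

#' Specify a Box-Behnken design
#'
#' @param factors List of [mae_factor()] objects, length `k >= 3`.
#' @param n_center Number of centre-point replicate runs, `C0 >= 0`.
#' @return An object of class `design_spec`.
#' @seealso [generate_bbd()], [bbd_run_count()]
#' @export
design_spec <- function(factors, n_center = 3L) {
  if (inherits(factors, "mae_factor")) factors <- list(factors)
  stopifnot(is.list(factors), length(factors) >= 1L,
            all(vapply(factors, inherits, logical(1), "mae_factor")),
            is.numeric(n_center), length(n_center) == 1L, n_center >= 0)
  if (length(factors) < 3L)
    stop("Box-Behnken designs require at least 3 factors (k >= 3)")
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  structure(list(factors = factors, n_center = as.integer(n_center)),
            class = "design_spec")
}

#' Number of runs in a Box-Behnken design
#'
#' A k-factor Box-Behnken design with `C0` centre points has
#' `N = 2 k (k - 1) + C0` runs: four edge-midpoint runs for each of the
#' `k(k-1)/2` factor pairs plus the centre replicates.
#'
#' @param k Number of factors, at least 3.
#' @param n_center Number of centre points.
#' @return Integer run count.
#' @examples
#' bbd_run_count(4, 3)  # 27
#' @export
bbd_run_count <- function(k, n_center) {
  stopifnot(is.numeric(k), length(k) == 1L, k == round(k),
            is.numeric(n_center), length(n_center) == 1L,
            n_center == round(n_center), n_center >= 0)
  if (k < 3) stop("Box-Behnken designs require k >= 3 factors")
  as.integer(2 * k * (k - 1) + n_center)
}

#' Convert between actual and coded factor levels
#'
#' Coding is linear: `coded = (actual - center) / half_range`, so the low,
#' centre and high levels map to -1, 0 and +1. Values outside `[low, high]`
#' are permitted and code beyond the unit interval.
#'
#' @param actual,coded Numeric value(s) in actual or coded units.
#' @param factor An [mae_factor()].
#' @return Numeric value(s) on the other scale.
#' @export
code_level <- function(actual, factor) {
  stopifnot(inherits(factor, "mae_factor"))
  (actual - factor$center) / factor$half_range
}

#' @rdname code_level
#' @export
decode_level <- function(coded, factor) {
  stopifnot(inherits(factor, "mae_factor"))
  factor$center + coded * factor$half_range
}

#' Render a coded run as a pattern string, and back
#'
#' `pattern_of()` maps a coded vector with entries in \{-1, 0, +1\} to a
#' string of "-", "0", "+" symbols; `coded_of()` inverts it. Typographic
#' minus signs in patterns are normalized to ASCII on input.
#'
#' @param coded Numeric vector with entries in \{-1, 0, +1\}.
#' @param pattern Character scalar of "+", "-", "0" symbols.
#' @return A character scalar, or a numeric vector.
#' @examples
#' pattern_of(c(1, 0, 1, 0))   # "+0+0"
#' coded_of("-0+0")            # c(-1, 0, 1, 0)
#' @export
pattern_of <- function(coded) {
  stopifnot(is.numeric(coded))
  if (!all(coded %in% c(-1, 0, 1)))
    stop("pattern not representable: coded entries must be -1, 0 or +1")
  paste(c("-", "0", "+")[coded + 2L], collapse = "")
}

#' @rdname pattern_of
#' @export
coded_of <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- normalize_pattern(pattern)
  sym <- strsplit(pattern, "")[[1]]
  if (!all(sym %in% c("+", "-", "0")))
    stop("invalid pattern symbol(s) in '", pattern, "'")
  unname(c("-" = -1, "0" = 0, "+" = 1)[sym])
}

# Unicode minus / en-dash variants seen in typeset tables -> ASCII hyphen.
normalize_pattern <- function(pattern) {
  gsub("[−–—]", "-", pattern)
}

#' Generate a Box-Behnken design
#'
#' Emits, for every unordered factor pair in lexicographic order, the four
#' runs with that pair at (-1,-1), (-1,+1), (+1,-1), (+1,+1) and all other
#' factors at 0, followed by the centre-point replicates. The ordering is
#' canonical and deterministic; randomized run order is out of scope.
#'
#' @param spec A [design_spec()].
#' @return A data frame with columns `run_id`, `pattern` and one coded-level
#'   column `x1 ... xk`, one row per run.
#' @examples
#' fac <- lapply(1:3, function(i) mae_factor(paste0("f", i), 0, 1))
#' nrow(generate_bbd(design_spec(fac, 0)))  # 12
#' @export
generate_bbd <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  k <- length(spec$factors)
  pairs <- utils::combn(k, 2)
  # per pair: (-1,-1), (-1,+1), (+1,-1), (+1,+1), other factors at centre
  signs <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), ncol = 2, byrow = TRUE)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    ij <- pairs[, p]
    t(apply(signs, 1, function(s) {
      x <- numeric(k); x[ij] <- s; x
    }))
  })
  coded <- do.call(rbind, rows)
  if (spec$n_center > 0)
    coded <- rbind(coded, matrix(0, nrow = spec$n_center, ncol = k))
  colnames(coded) <- paste0("x", seq_len(k))
  out <- data.frame(run_id = seq_len(nrow(coded)),
                    pattern = apply(coded, 1, pattern_of))
  cbind(out, as.data.frame(coded))
}

#' DPPH radical-scavenging inhibition
#'
#' Percent inhibition from control and sample absorbances:
#' `(A_control - A_sample) / A_control * 100`.
#'
#' @param a_control Absorbance of the control reaction; must be positive.
#' @param a_sample Absorbance in the presence of the extract.
#' @return Percent inhibition.
#' @examples
#' dpph_inhibition(2, 1)  # 50
#' @export
dpph_inhibition <- function(a_control, a_sample) {
  stopifnot(is.numeric(a_control), is.numeric(a_sample),
            all(a_sample >= 0))
  if (any(a_control <= 0)) stop("invalid control: a_control must be > 0")
  (a_control - a_sample) / a_control * 100
}
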