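#' Assemble a Box-Behnken dataset
#'
#' Binds a design to per-run observed response summaries (mean, sd over
#' `n_reps` replicates). The container is a data frame with one row per run:
#' `run_id`, `pattern`, coded columns `x1...xk`, actual-level columns named
#' after the factors, then `<response>_mean` and `<response>_sd` columns.
#'
#' @param spec A [design_spec()].
#' @param runs Data frame as returned by [generate_bbd()] (columns `run_id`,
#'   `pattern`, `x1...xk`).
#' @param observed Named list, one element per response, each a data frame
#'   with columns `run_id`, `mean`, `sd` (sd may be `NA`).
#' @param n_reps Replicates per run behind each mean/sd (default 3).
#' @return An object of class `bbd_dataset` (a data frame with attributes
#'   `spec`, `response_names`, `n_reps`).
#' @export
bbd_dataset <- function(spec, runs, observed, n_reps = 3L) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(runs),
            is.list(observed), length(observed) >= 1L,
            !is.null(names(observed)))
  k <- length(spec$factors)
  xcols <- paste0("x", seq_len(k))
  stopifnot(all(c("run_id", "pattern", xcols) %in% names(runs)))
  if (anyDuplicated(runs$run_id)) stop("duplicate run_id in design runs")
  df <- runs[, c("run_id", "pattern", xcols)]
  for (j in seq_len(k)) {
    f <- spec$factors[[j]]
    df[[f$name]] <- decode_level(df[[xcols[j]]], f)
  }
  for (resp in names(observed)) {
    ob <- observed[[resp]]
    stopifnot(all(c("run_id", "mean") %in% names(ob)))
    if (is.null(ob$sd)) ob$sd <- NA_real_
    if (!setequal(ob$run_id, df$run_id))
      stop("response '", resp, "': observed run_ids do not match the design")
    if (any(!is.na(ob$sd) & ob$sd < 0)) stop("negative sd for '", resp, "'")
    idx <- match(df$run_id, ob$run_id)
    df[[paste0(resp, "_mean")]] <- ob$mean[idx]
    df[[paste0(resp, "_sd")]] <- ob$sd[idx]
  }
  structure(df, spec = spec, response_names = names(observed),
            n_reps = as.integer(n_reps),
            class = c("bbd_dataset", "data.frame"))
}

#' @export
print.bbd_dataset <- function(x, ...) {
  cat(sprintf("Box-Behnken dataset: %d runs, %d factors, responses: %s\n",
              nrow(x), length(attr(x, "spec")$factors),
              paste(attr(x, "response_names"), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Accessors for a `bbd_dataset`
#'
#' `coded_matrix()` returns the n-by-k coded design matrix, `actual_matrix()`
#' the same runs in actual units, `observed_response()` the per-run summary
#' for one response, and `center_run_ids()` the run ids of the centre
#' replicates.
#'
#' @param dataset A `bbd_dataset`.
#' @param response Response name.
#' @return A matrix, data frame or integer vector as described.
#' @export
coded_matrix <- function(dataset) {
  k <- length(attr(dataset, "spec")$factors)
  as.matrix(as.data.frame(dataset)[, paste0("x", seq_len(k))])
}

#' @rdname coded_matrix
#' @export
actual_matrix <- function(dataset) {
  fac <- attr(dataset, "spec")$factors
  m <- as.matrix(as.data.frame(dataset)[, names(fac)])
  m
}

#' @rdname coded_matrix
#' @export
observed_response <- function(dataset, response) {
  if (!response %in% attr(dataset, "response_names"))
    stop("unknown response '", response, "'")
  data.frame(run_id = dataset$run_id,
             mean = dataset[[paste0(response, "_mean")]],
             sd = dataset[[paste0(response, "_sd")]],
             n_reps = attr(dataset, "n_reps"))
}

#' @rdname coded_matrix
#' @export
center_run_ids <- function(dataset) {
  k <- length(attr(dataset, "spec")$factors)
  dataset$run_id[dataset$pattern == strrep("0", k)]
}

#' The four extraction factors of the press-residue study
#'
#' Ethanol concentration 50-100 % (v/v), microwave power 400-800 W,
#' irradiation time 2-4 min, liquid-to-solid ratio 30-50 mL/g; coded
#' -1/0/+1 at low/centre/high.
#'
#' @return A [design_spec()] with `k = 4` factors and 3 centre points.
#' @export
ofi_design_spec <- function() {
  design_spec(list(
    mae_factor("ethanol", 50, 100, "%"),
    mae_factor("power", 400, 800, "W"),
    mae_factor("time", 2, 4, "min"),
    mae_factor("ratio", 30, 50, "mL/g")
  ), n_center = 3L)
}

#' Load the packaged press-residue Box-Behnken dataset
#'
#' The 27-run, 4-factor Box-Behnken experiment on *Opuntia ficus-indica*
#' seed press residue: observed means and standard deviations (triplicate
#' measurements) of the Folin-Ciocalteu reducing capacity (`FCRC`, mg
#' GAE/100 g DW) and the AlCl3 complexation response (`AlCl3`, mg QE/100 g
#' DW) at each run. The published model predictions at the design points are
#' attached as attribute `"predictions"` (a data frame `run_id`, `FCRC`,
#' `AlCl3`) for regression testing of the response-surface fit.
#'
#' One quirk of the published prediction column is preserved as printed:
#' the FCRC prediction of run 22 (322.46) is a digit transposition of the
#' model value 325.47; every other entry agrees with the refitted model to
#' within 0.01.
#'
#' @return A `bbd_dataset` with 27 runs and responses `FCRC`, `AlCl3`.
#' @examples
#' d <- ofi_press_residue()
#' observed_response(d, "FCRC")[18, ]
#' @export
ofi_press_residue <- function() {
  path <- system.file("extdata", "ofi_press_residue_bbd.csv",
                      package = "maeopt", mustWork = TRUE)
  expected <- "3aaec0e5ce51a3b3995a8e1bbd8f5a91"
  if (!identical(unname(tools::md5sum(path)), expected))
    stop("corrupted package data: checksum mismatch for ", basename(path))
  ds <- read_bbd_csv(path, spec = ofi_design_spec(), n_reps = 3L)
  pred_path <- system.file("extdata", "ofi_press_residue_predictions.csv",
                           package = "maeopt", mustWork = TRUE)
  pred <- utils::read.csv(pred_path)
  attr(ds, "predictions") <- pred[match(ds$run_id, pred$run_id), ]
  ds
}

#' One-variable-at-a-time screening results
#'
#' Preliminary single-factor screening of solvent type, ethanol
#' concentration, microwave power, extraction time and liquid-to-solid
#' ratio, as means plus/minus sd (n = 3) of both colorimetric responses.
#'
#' @return A data frame with columns `parameter`, `level`, `FCRC_mean`,
#'   `FCRC_sd`, `AlCl3_mean`, `AlCl3_sd`.
#' @export
ofi_ovat_screening <- function() {
  path <- system.file("extdata", "ofi_ovat_screening.csv",
                      package = "maeopt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published optimum conditions and validation measurements
#'
#' The two optimum operating points of the study — the response-surface
#' (desirability) optimum and the tuned-KNN/multi-objective optimum — with
#' the laboratory validation means (plus/minus sd) and the model predictions
#' at those points. The tuned-KNN condition uses ethanol 50 %, power 800 W,
#' time 4 min, ratio 47.2802 mL/g (the prose values; one typeset row of the
#' source omits the time and prints 804 W).
#'
#' @return A named list with elements `bbd` and `knn_da`, each containing
#'   `conditions` (named vector in actual units), `experimental` (data frame
#'   `response`, `mean`, `sd`) and `predicted` (named vector).
#' @export
ofi_validation_inputs <- function() {
  list(
    bbd = list(
      conditions = c(ethanol = 51.98, power = 800, time = 4, ratio = 48.175),
      experimental = data.frame(
        response = c("FCRC", "AlCl3"),
        mean = c(375.8514, 49.1563),
        sd = c(0.46, 0.37)),
      predicted = c(FCRC = 407.2125, AlCl3 = 57.5826)
    ),
    knn_da = list(
      conditions = c(ethanol = 50, power = 800, time = 4, ratio = 47.2802),
      experimental = data.frame(
        response = c("FCRC", "AlCl3"),
        mean = c(376.8514, 49.1614),
        sd = c(0.23, 0.33)),
      predicted = c(FCRC = 379.6535, AlCl3 = 48.3414)
    )
  )
}
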