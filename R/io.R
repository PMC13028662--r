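#' Read and write Box-Behnken datasets as CSV
#'
#' The design-file dialect is one header row with columns `run_id`,
#' `pattern`, one actual-level column per factor (named after the factor),
#' then `<response>_mean` and `<response>_sd` per response; UTF-8 with "."
#' as decimal separator. Numeric fields round-trip to 1e-12.
#'
#' @param path File path.
#' @param spec A [design_spec()] naming the factors and their levels; coded
#'   levels are recomputed from the actual columns on read.
#' @param n_reps Replicates behind each mean/sd (not stored in the file).
#' @param dataset A `bbd_dataset` to write.
#' @return `read_bbd_csv()` returns a `bbd_dataset`; `write_bbd_csv()`
#'   returns `path` invisibly.
#' @export
read_bbd_csv <- function(path, spec, n_reps = 3L) {
  stopifnot(inherits(spec, "design_spec"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("no runs: '", basename(path), "' is header-only")
  fac_names <- names(spec$factors)
  needed <- c("run_id", "pattern", fac_names)
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  mean_cols <- grep("_mean$", names(raw), value = TRUE)
  if (!length(mean_cols)) stop("missing column(s): no *_mean response column")
  responses <- sub("_mean$", "", mean_cols)
  for (col in c("run_id", fac_names, mean_cols,
                intersect(paste0(responses, "_sd"), names(raw)))) {
    if (!is.numeric(raw[[col]])) {
      vals <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))[1]
      stop("non-numeric cell in column '", col, "' at line ", bad + 1L)
    }
  }
  if (anyDuplicated(raw$run_id)) {
    dup <- raw$run_id[duplicated(raw$run_id)][1]
    stop("duplicate run_id ", dup, " (line ",
         which(raw$run_id == dup)[2] + 1L, ")")
  }
  raw$pattern <- vapply(raw$pattern, normalize_pattern, character(1))
  coded <- vapply(seq_along(fac_names),
                  function(j) code_level(raw[[fac_names[j]]], spec$factors[[j]]),
                  numeric(nrow(raw)))
  coded <- matrix(coded, nrow = nrow(raw))
  colnames(coded) <- paste0("x", seq_along(fac_names))
  runs <- cbind(raw[, c("run_id", "pattern")], as.data.frame(coded))
  observed <- lapply(responses, function(r) {
    sd_col <- paste0(r, "_sd")
    data.frame(run_id = raw$run_id, mean = raw[[paste0(r, "_mean")]],
               sd = if (sd_col %in% names(raw)) raw[[sd_col]] else NA_real_)
  })
  names(observed) <- responses
  bbd_dataset(spec, runs, observed, n_reps = n_reps)
}

#' @rdname read_bbd_csv
#' @export
write_bbd_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "bbd_dataset"))
  spec <- attr(dataset, "spec")
  resp <- attr(dataset, "response_names")
  cols <- c("run_id", "pattern", names(spec$factors),
            as.vector(rbind(paste0(resp, "_mean"), paste0(resp, "_sd"))))
  out <- as.data.frame(dataset)[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a design specification as JSON
#'
#' @param spec A [design_spec()].
#' @param path File path.
#' @return `read_design_spec_json()` returns a [design_spec()].
#' @export
write_design_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "design_spec"))
  obj <- list(
    factors = lapply(unname(spec$factors), function(f)
      list(name = f$name, low = f$low, high = f$high, units = f$units)),
    n_center = spec$n_center
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_spec_json
#' @export
read_design_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  design_spec(lapply(obj$factors, function(f)
    mae_factor(f$name, f$low, f$high, f$units %||% "")),
    n_center = obj$n_center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
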