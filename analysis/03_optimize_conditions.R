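#!/usr/bin/env Rscript
# Locate optimum extraction conditions two ways:
#  (1) desirability-based multi-response optimization of the fitted
#      response surfaces over the coded box, and
#  (2) multi-objective dragonfly optimization (Pareto archive) over KNN
#      surrogates trained on all 27 runs, with the compromise point chosen
#      to maximize the summed predicted responses.

suppressPackageStartupMessages(library(maeopt))
dir.create("results", showWarnings = FALSE)
seed <- 1L

dataset <- ofi_press_residue()
spec <- ofi_design_spec()

## (1) response-surface desirability optimum
fits <- lapply(c(FCRC = "FCRC", AlCl3 = "AlCl3"),
               function(r) fit_quadratic(dataset, r))
opt_rsm <- optimize_rsm(fits, factors = spec, resolution = 11)
message(sprintf(
  "RSM desirability optimum: ethanol %.2f %%, power %.0f W, time %.2f min, ratio %.2f mL/g",
  opt_rsm$actual["ethanol"], opt_rsm$actual["power"],
  opt_rsm$actual["time"], opt_rsm$actual["ratio"]))
message(sprintf("  predicted FCRC %.2f, AlCl3 %.2f (power and time at their upper bounds)",
                opt_rsm$predictions["FCRC"], opt_rsm$predictions["AlCl3"]))

## (2) MODA over KNN surrogates (tuned hyperparameters, full-data models)
A <- actual_matrix(dataset)
nz <- fit_normalizer(A)
Xn <- normalize(nz, A)
models <- list()
for (resp in c("FCRC", "AlCl3")) {
  tuned <- tune_knn(dataset, resp, fraction = 0.7, seed = seed)
  models[[resp]] <- knn_model(Xn, observed_response(dataset, resp)$mean,
                              tuned$best_hyperparams)
}
cfg <- da_config(rep(-1, 4), rep(1, 4), max_iterations = 100L,
                 n_agents = 30L, seed = seed)
opt_knn <- optimize_knn_moda(models, nz, cfg)
message(sprintf(
  "KNN/MODA compromise: ethanol %.2f %%, power %.0f W, time %.2f min, ratio %.2f mL/g",
  opt_knn$compromise_actual[1], opt_knn$compromise_actual[2],
  opt_knn$compromise_actual[3], opt_knn$compromise_actual[4]))
message(sprintf("  predicted FCRC %.2f, AlCl3 %.2f, sum %.2f (archive size %d)",
                opt_knn$predictions["FCRC"], opt_knn$predictions["AlCl3"],
                sum(opt_knn$predictions), nrow(opt_knn$archive$positions)))

out <- list(
  seed = seed,
  rsm = list(actual = as.list(opt_rsm$actual),
             predictions = as.list(opt_rsm$predictions),
             desirability = opt_rsm$desirability),
  knn_moda = list(actual = as.list(setNames(drop(opt_knn$compromise_actual),
                                            names(spec$factors))),
                  predictions = as.list(opt_knn$predictions),
                  archive_size = nrow(opt_knn$archive$positions))
)
jsonlite::write_json(out, "results/optima.json", auto_unbox = TRUE,
                     digits = NA)
arch <- cbind(as.data.frame(opt_knn$archive$positions),
              as.data.frame(opt_knn$pareto_predictions))
names(arch)[1:4] <- paste0("x", 1:4)
write.csv(arch, "results/moda_archive.csv", row.names = FALSE)
message("wrote results/optima.json and results/moda_archive.csv")
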