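# Shared fixtures, built in code.

ofi <- ofi_press_residue()
ofi_fcrc_fit <- fit_quadratic(ofi, "FCRC")
ofi_alcl3_fit <- fit_quadratic(ofi, "AlCl3")

# Small 3-factor synthetic dataset with a known surface.
toy_surface <- function(noise_sd = 0, seed = 1L) {
  synthetic_surface_spec(
    k = 3, beta0 = 100, beta_lin = c(-20, 5, 8),
    beta_quad = c(-15, -2, 3), beta_int = c(4, -6, 2),
    noise_sd = noise_sd, n_reps = 3L, seed = seed)
}

# Normalized inputs + targets for the packaged dataset.
ofi_norm <- local({
  A <- actual_matrix(ofi)
  nz <- fit_normalizer(A)
  list(normalizer = nz, X = normalize(nz, A),
       fcrc = ofi$FCRC_mean, alcl3 = ofi$AlCl3_mean)
})
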