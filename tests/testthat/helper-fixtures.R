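# Shared fixtures, built once per test run.

stem_params <- cell_type_params("stem")
hep_params <- cell_type_params("hepatocyte")
ladder_um <- size_ladder()

# One oxygen lookup table per cell type covering the full ladder (+ head
# room for radius and sOCR fluctuations).
.lk_cache <- new.env(parent = emptyenv())
get_lookup <- function(params) {
  key <- sprintf("%.6g_%.6g_%.6g", params$socr_mean, params$k_M, params$c0)
  if (is.null(.lk_cache[[key]])) {
    hi <- params$socr_mean * (1 + 6 * max(params$socr_sd_frac, 0.2)) *
      params$rho_c * (max(ladder_um) * 1e-6 * 1.8)^2 /
      (params$D * params$c0)
    .lk_cache[[key]] <- build_oxygen_lookup(params,
                                            phi2_range = c(1e-6, hi))
  }
  .lk_cache[[key]]
}

# Three consecutive synthetic distributions satisfying the scaling ansatz
# exactly, with the reference variability (mass CV ~30%, noise CV 20%).
scaling_triplet <- function(delta0, n, seed, q2 = 0.01, noise_cv = 0.2,
                            ratio = 2.595) {
  mms <- 4.2e-9 * ratio^(0:2)
  lapply(1:3, function(i)
    make_scaling_population(mms[i], n, delta0, q2 = q2,
                            noise_cv = noise_cv,
                            seed = child_seed(seed, 60, i)))
}
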