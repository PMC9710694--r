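# shared simulation runs for the calibration/power tests; memoised so
# several test blocks can reuse one run
.sim_cache <- new.env(parent = emptyenv())

cached_oc <- function(n_codons, omega_true, n_pairs, expected_ds = 0.3,
                      alpha = 0.05, seed = 20260101) {
  key <- paste(n_codons, omega_true, n_pairs, expected_ds, alpha, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    grid <- tibble::tibble(
      n_codons = n_codons, omega_true = omega_true,
      expected_ds = expected_ds, n_pairs = n_pairs
    )
    .sim_cache[[key]] <- operating_characteristics(
      grid, alpha = alpha, policy = "none", seed = seed
    )
  }
  .sim_cache[[key]]
}
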