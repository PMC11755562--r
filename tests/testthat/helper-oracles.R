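# shared fixtures and independent oracles used across test files

# two peptides from the N-terminal window set with a 4-residue overlap
tiny_stitch_input <- function() {
  data.frame(id = c("BP1", "BP2"),
             start = c(2L, 12L), end = c(15L, 23L),
             sequence = c("SNKKQSNRLTEQHK", "EQHKLSQGVIGI"))
}

# exhaustive two-sample permutation test (two-sided, |mean diff| statistic)
perm_test_p <- function(x, y) {
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  obs <- abs(mean(x) - mean(y))
  stats <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(stats >= obs - 1e-12)
}

# closed-form Pearson r from raw sums
pearson_r_closed <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# noise-free measurement set: control plus peptides with known k_eff ratios
noise_free_panel <- function(d50s = c(A = 500, B = 100), dose = 500) {
  cfg <- assay_config(noise_cv = 0, seed = 42L)
  eff <- do.call(rbind, lapply(names(d50s), function(id)
    peptide_effect(id, d50s[[id]])))
  list(config = cfg, effects = eff,
       measurements = simulate_panel(eff, cfg, dose = dose))
}
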