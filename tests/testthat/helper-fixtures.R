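# Small deterministic fixtures shared across test files.

# Two-population block-LD dataset at test scale.
small_dataset <- function(seed = 42L, n_indiv = c(150L, 100L), n_snps = 240L,
                          ld = 0.7, corr = 0.5) {
  sc <- sim_scenario(n_pops = 2L, n_indiv = n_indiv, n_snps = n_snps,
                     n_chrom = 2L, block_len = 40L, within_block_ld = ld,
                     effect_corr = corr, seed = seed)
  simulate_dataset(sc)
}

# One-population dataset for imputation / rescaling tests.
one_pop_dataset <- function(seed = 43L, n = 240L, m = 200L, ld = 0.85) {
  sc <- sim_scenario(n_pops = 1L, n_indiv = n, n_snps = m, n_chrom = 2L,
                     block_len = 50L, within_block_ld = ld, seed = seed)
  simulate_dataset(sc)
}

# Hand-sized panel with explicit dosages (no simulation).
tiny_panel <- function() {
  dos <- rbind(c(2, 1, 0, 1),
               c(1, 0, 1, 2),
               c(0, 1, 2, 1),
               c(1, 2, 1, 0),
               c(2, 2, 0, 1))
  genotype_panel(dos, snp_ids = paste0("s", 1:4),
                 chrom = c("1", "1", "2", "2"),
                 indiv_ids = paste0("b", 1:5))
}

summaries_of <- function(ds) {
  sc <- ds$scenario
  lapply(seq_along(ds$panels), function(i)
    summarize_population(ds$panels[[i]], ds$truth[[i]]$records,
                         err_var = sc$err_var[i], dgv_var = sc$dgv_var[i],
                         population = names(ds$panels)[i]))
}

spec_of <- function(ds, summaries) {
  theta <- vapply(summaries, function(s) compute_theta(s$allele_freq), 0)
  covariance_spec(ds$scenario$dgv_var, ds$scenario$effect_corr, theta)
}
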