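#!/usr/bin/env Rscript
# Build the synthetic study panel: a structured selfing population with two
# correlated methylation-like traits (three planted QTLs: one shared, two
# trait-2-specific), an ancestry cline in longitude with an extra loading on
# the trait-2 QTLs, and negative-binomial transposon insertion counts with a
# planted genotype x genotype interaction. Writes the full plain-text bundle
# (VCF, genotype matrix, phenotypes, BED, allc, a priori list, truth file)
# under results/fixture/.

library(condgwas)

seed <- 1L
out <- "results/fixture"

cfg <- sim_config(
  n_lines = 300, n_snps = 4000, n_chromosomes = 5, n_clusters = 5,
  fst = 0.3,
  qtl_spec = data.frame(
    snp_index = c(400L, 706L, 1500L, 2200L, 2600L, 3400L),
    effect1 = c(0.4, 0, 0, 0, 0, 0),
    effect2 = c(0.35, 0.3, 0.45, 0.3, 0.4, 0.35)),
  shared_factor_sd = 0.9, h2_background_1 = 0.05, h2_background_2 = 0.05,
  noise_sd_1 = 0.3, noise_sd_2 = 0.5,
  cline_strength = 0.3,
  cline_snp_indices = c(800L, 1500L, 2200L, 2600L, 3400L),
  cline_snp_effect = -0.45,
  insertion_baseline = 0.1, insertion_interaction_log_ratio = log(30),
  snp_spacing = 2000,
  seed = seed)

paths <- write_fixture_bundle(cfg, out, n_te = 60, n_genes = 250,
                              n_apriori = 25)
cat("Panel:", cfg$n_lines, "lines x", cfg$n_snps, "SNPs;",
    "expected trait correlation", round(expected_trait_correlation(cfg), 3),
    "\n")
cat("Bundle written:\n")
print(paths)
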