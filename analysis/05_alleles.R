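#!/usr/bin/env Rscript
# Allele-level analyses of the conditional hits: orientation of the
# trait-decreasing alleles, per-line cumulative counts and the additive fit,
# variance jointly explained (r^2), the longitude cline tested against
# frequency-matched SNP sets, and the epistatic effect of the cumulative
# count on transposon insertion counts at the true partner locus. Writes
# results/alleles.tsv and results/epistasis.tsv.

library(condgwas)

snp_meta <- read.delim("results/fixture/snp_meta.tsv")
geno <- read_genotype_matrix("results/fixture/genotypes.tsv",
                             snp_meta[, c("id", "chrom", "pos")])
phen <- read.delim("results/fixture/phenotypes.tsv")
truth <- yaml::read_yaml("results/fixture/truth.yaml")
cond <- read.delim("results/scan_conditional.tsv")
class(cond) <- c("assoc_result", "data.frame")

top <- cond[order(cond$p_value), ]
focal <- orient_alleles(cond, head(top$snp_id, 5))
cat("Focal loci and decreasing alleles:\n")
print(focal[, c("snp_id", "maf", "beta", "decreasing_code")])

counts <- cumulative_counts(geno, focal)
fit <- additive_fit(phen$trait2, counts)
cat(sprintf("Additive fit: slope %.3f (se %.3f) per decreasing allele\n",
            fit$slope, fit$slope_se))
print(fit$class_means)
r2 <- variance_explained_r2(phen$trait2, geno, focal$snp_index)
cat(sprintf("Variance jointly explained by focal loci: r2 = %.3f\n", r2))

spec <- perm_spec(n_perm = 3000, seed = 11)
cline <- clinal_test(geno, focal, phen$longitude, spec)
cat(sprintf("Cline: observed r = %.3f, permutation p = %.4f (%d matched sets)\n",
            cline$observed_r, cline$p_value, spec$n_perm))

write.table(
  data.frame(fit$class_means, slope = fit$slope, r2 = r2,
             cline_r = cline$observed_r, cline_p = cline$p_value),
  "results/alleles.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

partner <- truth$insertion$focal_snp
mods_id <- geno$snps$id[unlist(truth$insertion$modifier_snps)]
focal_i <- orient_alleles(
  transform(cond, beta = ifelse(snp_id %in% mods_id, -abs(beta), beta)),
  mods_id)
epi <- epistasis_insertion_test(phen$insertion_count, geno, partner, focal_i,
                                spec, k_grid = 0:5)
print(epi)
write.table(epi, "results/epistasis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- epi$k >= truth$insertion$k & !epi$empty & epi$p_value < 0.05
cat(sprintf("Classes with elevated mobilization (p < 0.05): %s\n",
            paste(epi$k[which(sig)], collapse = ", ")))
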