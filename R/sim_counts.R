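#' Simulate recent transposon insertion counts with a planted epistatic
#' interaction
#'
#' Per-line counts are negative binomial with
#' `log(mean) = log(insertion_baseline) + insertion_interaction_log_ratio * I`,
#' where the indicator `I` is 1 for lines that carry the alternative allele
#' at the focal SNP and at least `insertion_k` alternative alleles across the
#' modifier SNPs. This emulates transposon mobilization that is elevated only
#' in a particular multi-locus genotype class.
#'
#' @param geno a `geno_matrix`.
#' @param focal_snp index of the focal (partner) SNP.
#' @param modifier_snps indices of the modifier SNPs.
#' @param config a [sim_config()]; uses `insertion_baseline`,
#'   `insertion_interaction_log_ratio`, `insertion_k`,
#'   `insertion_dispersion`, `seed`.
#' @return integer vector of counts, one per line, with the interaction
#'   indicator as attribute `"interacting"`.
#' @export
simulate_insertion_counts <- function(geno, focal_snp, modifier_snps, config) {
  validate_sim_config(config)
  m <- ncol(geno$X)
  idx <- c(focal_snp, modifier_snps)
  if (any(idx < 1L | idx > m)) stop("SNP index out of range")
  set.seed(derive_seed(config$seed, 3L))
  focal <- geno$X[, focal_snp]
  mods <- geno$X[, modifier_snps, drop = FALSE]
  nmod <- rowSums(mods == 1L, na.rm = TRUE)
  interacting <- !is.na(focal) & focal == 1L & nmod >= config$insertion_k
  mu <- exp(log(config$insertion_baseline) +
              config$insertion_interaction_log_ratio * interacting)
  counts <- stats::rnbinom(length(mu), size = config$insertion_dispersion,
                           mu = mu)
  names(counts) <- geno$line_ids
  attr(counts, "interacting") <- interacting
  counts
}
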