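#' Simulation configuration for the synthetic inbred panel
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' population structure, the planted genetic architecture of two correlated
#' methylation-like traits, the geographic cline, and the transposon
#' insertion-count model. The generator emulates a selfing panel, so
#' genotypes are haploid-equivalent 0/1 with no heterozygotes.
#'
#' @param n_lines number of inbred lines.
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes number of chromosomes over which SNPs are laid out
#'   contiguously.
#' @param n_clusters number of ancestry clusters (Balding--Nichols demes).
#' @param fst divergence parameter in `[0, 1)` controlling between-cluster
#'   allele-frequency variance.
#' @param structure `"island"` (independent Balding--Nichols demes; default)
#'   or `"stepping-stone"` (demes drift sequentially along a chain, giving
#'   the smoothly decaying kinship spectrum of a geographically continuous
#'   panel; total end-to-end divergence ~ `fst`).
#' @param maf_floor lower bound of the ancestral allele-frequency draw;
#'   frequencies are uniform on `[maf_floor, 1 - maf_floor]`.
#' @param qtl_spec data frame with columns `snp_index`, `effect1`, `effect2`:
#'   planted QTLs with per-trait effects in standardized units (applied to the
#'   z-scored genotype column, so `effect^2` is the variance contributed).
#' @param shared_factor_sd scaling of the shared factor in trait 2; trait 1
#'   receives the unit-variance shared factor unscaled.
#' @param shared_structured logical; if `TRUE` (default) the shared factor is
#'   drawn with covariance equal to the kinship matrix, i.e. it is a shared
#'   polygenic factor, which is what makes the univariate scan of trait 2
#'   structure-confounded the way highly heritable correlated traits are.
#' @param h2_background_1,h2_background_2 variance of the trait-specific
#'   polygenic background (covariance `h2 * K`), each in `[0, 1)`.
#' @param noise_sd_1,noise_sd_2 residual noise standard deviations.
#' @param cline_strength correlation-scale loading of the ancestry cluster
#'   score on longitude, in `[-1, 1]`.
#' @param cline_snp_indices optional SNP indices whose cumulative alternative
#'   allele count loads directly on longitude (a planted cline at focal loci
#'   over and above the ancestry-wide cline).
#' @param cline_snp_effect loading of the z-scored cumulative count of
#'   `cline_snp_indices` alleles on longitude.
#' @param insertion_baseline negative-binomial mean insertion count for the
#'   non-interacting genotype classes.
#' @param insertion_interaction_log_ratio log fold-change of the insertion
#'   mean in lines carrying the focal alternative allele together with at
#'   least `insertion_k` modifier alternative alleles.
#' @param insertion_k number of modifier alternative alleles required to
#'   trigger the interaction (default 2).
#' @param insertion_dispersion negative-binomial size parameter.
#' @param ld_block_len if `> 1`, SNPs are generated in blocks of this length
#'   by copying the block seed column with independent Bernoulli flips, giving
#'   locally correlated SNPs (block-copy LD).
#' @param ld_flip_rate per-entry flip rate within an LD block.
#' @param mask_rate fraction of genotype entries set missing at random.
#' @param snp_spacing base-pair spacing between consecutive SNP positions.
#' @param seed integer seed; an identical seed yields a bit-identical bundle.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 200L,
                       n_snps = 2000L,
                       n_chromosomes = 5L,
                       n_clusters = 5L,
                       fst = 0.3,
                       structure = c("island", "stepping-stone"),
                       maf_floor = 0.05,
                       qtl_spec = NULL,
                       shared_factor_sd = 1,
                       shared_structured = TRUE,
                       h2_background_1 = 0.2,
                       h2_background_2 = 0.2,
                       noise_sd_1 = 0.5,
                       noise_sd_2 = 0.5,
                       cline_strength = 0.6,
                       cline_snp_indices = NULL,
                       cline_snp_effect = 0,
                       insertion_baseline = 0.1,
                       insertion_interaction_log_ratio = log(30),
                       insertion_k = 2L,
                       insertion_dispersion = 1,
                       ld_block_len = 1L,
                       ld_flip_rate = 0.05,
                       mask_rate = 0,
                       snp_spacing = 200L,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    n_clusters = as.integer(n_clusters),
    fst = fst, structure = match.arg(structure),
    maf_floor = maf_floor,
    qtl_spec = qtl_spec,
    shared_factor_sd = shared_factor_sd,
    shared_structured = isTRUE(shared_structured),
    h2_background_1 = h2_background_1, h2_background_2 = h2_background_2,
    noise_sd_1 = noise_sd_1, noise_sd_2 = noise_sd_2,
    cline_strength = cline_strength,
    cline_snp_indices = if (is.null(cline_snp_indices)) integer(0) else
      as.integer(cline_snp_indices),
    cline_snp_effect = cline_snp_effect,
    insertion_baseline = insertion_baseline,
    insertion_interaction_log_ratio = insertion_interaction_log_ratio,
    insertion_k = as.integer(insertion_k),
    insertion_dispersion = insertion_dispersion,
    ld_block_len = as.integer(ld_block_len),
    ld_flip_rate = ld_flip_rate,
    mask_rate = mask_rate,
    snp_spacing = as.integer(snp_spacing),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lines >= 2L, cfg$n_snps >= 1L, cfg$n_chromosomes >= 1L)
  if (cfg$n_clusters > cfg$n_lines) {
    stop("invalid configuration: n_clusters > n_lines")
  }
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must be in [0, 1)")
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5) {
    stop("maf_floor must be in [0, 0.5)")
  }
  for (h in c(cfg$h2_background_1, cfg$h2_background_2)) {
    if (h < 0 || h >= 1) stop("variance fractions must be in [0, 1)")
  }
  if (!is.null(cfg$qtl_spec)) {
    qs <- cfg$qtl_spec
    stopifnot(is.data.frame(qs),
              all(c("snp_index", "effect1", "effect2") %in% names(qs)))
    if (anyDuplicated(qs$snp_index)) stop("qtl_spec indices must be unique")
    if (any(qs$snp_index < 1L | qs$snp_index > cfg$n_snps)) {
      stop("qtl_spec indices out of range")
    }
  }
  if (any(cfg$cline_snp_indices < 1L | cfg$cline_snp_indices > cfg$n_snps)) {
    stop("cline_snp_indices out of range")
  }
  if (abs(cfg$cline_strength) > 1) stop("cline_strength must be in [-1, 1]")
  if (cfg$mask_rate < 0 || cfg$mask_rate >= 1) stop("mask_rate must be in [0, 1)")
  if (cfg$insertion_baseline <= 0) stop("insertion_baseline must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  %d lines x %d SNPs on %d chromosomes; %d ancestry clusters (Fst = %g)\n",
              x$n_lines, x$n_snps, x$n_chromosomes, x$n_clusters, x$fst))
  nq <- if (is.null(x$qtl_spec)) 0L else nrow(x$qtl_spec)
  cat(sprintf("  %d planted QTLs; shared factor sd %g; backgrounds (%g, %g); seed %d\n",
              nq, x$shared_factor_sd, x$h2_background_1, x$h2_background_2,
              x$seed))
  invisible(x)
}
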