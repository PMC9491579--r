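#' Simulate structured inbred genotypes
#'
#' Balding--Nichols-style generator for a selfing panel: for each SNP an
#' ancestral frequency p0 is drawn uniform on `[maf_floor, 1 - maf_floor]`,
#' each ancestry cluster draws its own frequency from
#' `Beta(p0 (1 - Fst) / Fst, (1 - p0)(1 - Fst) / Fst)`, and each line draws a
#' haploid-equivalent 0/1 genotype from its cluster frequency. Lines are
#' assigned to clusters cyclically so cluster sizes differ by at most one.
#' SNPs get contiguous 1-based positions, `snp_spacing` apart, split evenly
#' across chromosomes.
#'
#' With `ld_block_len > 1` SNPs are generated in blocks: the first SNP of a
#' block is drawn as above and the remaining block members are copies of it
#' with independent Bernoulli(`ld_flip_rate`) flips, giving locally correlated
#' markers. With `mask_rate > 0` entries are set missing completely at random.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `geno_matrix`: a list with `X` (n_lines x
#'   n_snps integer 0/1 matrix, possibly with NA), `snps` (data frame with
#'   `id`, `chrom`, `pos`, `mac`, `maf`), `line_ids`, and `cluster` (ancestry
#'   label per line).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_lines
  m <- config$n_snps
  k <- config$n_clusters
  cluster <- rep_len(seq_len(k), n)

  blk <- max(1L, config$ld_block_len)
  n_seed <- ceiling(m / blk)

  p0 <- stats::runif(n_seed, config$maf_floor, 1 - config$maf_floor)
  # cluster frequencies: n_seed x k
  if (config$fst < 1e-12) {
    pc <- matrix(p0, n_seed, k)
  } else if (config$structure == "island") {
    a <- p0 * (1 - config$fst) / config$fst
    b <- (1 - p0) * (1 - config$fst) / config$fst
    pc <- matrix(stats::rbeta(n_seed * k, rep(a, k), rep(b, k)), n_seed, k)
  } else {
    # stepping-stone: demes drift sequentially with per-step divergence
    # fst / (k - 1), so end-to-end divergence is about fst
    f <- config$fst / max(1L, k - 1L)
    pc <- matrix(0, n_seed, k)
    pc[, 1L] <- p0
    for (c0 in seq_len(k)[-1L]) {
      pprev <- pmin(pmax(pc[, c0 - 1L], 1e-3), 1 - 1e-3)
      pc[, c0] <- stats::rbeta(n_seed, pprev * (1 - f) / f,
                               (1 - pprev) * (1 - f) / f)
    }
  }

  # seed genotypes: n x n_seed, line i draws from its cluster's frequency
  P <- t(pc)[cluster, , drop = FALSE]            # n x n_seed
  Xseed <- matrix(stats::rbinom(n * n_seed, 1L, P), n, n_seed)

  if (blk == 1L) {
    X <- Xseed[, seq_len(m), drop = FALSE]
  } else {
    block_of <- rep(seq_len(n_seed), each = blk)[seq_len(m)]
    X <- Xseed[, block_of, drop = FALSE]
    first_of_block <- !duplicated(block_of)
    flip_cols <- which(!first_of_block)
    if (length(flip_cols)) {
      flips <- matrix(stats::rbinom(n * length(flip_cols), 1L,
                                    config$ld_flip_rate),
                      n, length(flip_cols))
      X[, flip_cols] <- abs(X[, flip_cols, drop = FALSE] - flips)
    }
  }
  storage.mode(X) <- "integer"

  if (config$mask_rate > 0) {
    nmiss <- stats::rbinom(1L, n * m, config$mask_rate)
    if (nmiss > 0) {
      X[sample.int(n * m, nmiss)] <- NA_integer_
    }
  }

  per_chrom <- ceiling(m / config$n_chromosomes)
  chrom_idx <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(m)]
  pos <- (ave(seq_len(m), chrom_idx, FUN = seq_along)) * config$snp_spacing
  snps <- data.frame(
    id = sprintf("snp%06d", seq_len(m)),
    chrom = paste0("chr", chrom_idx),
    pos = as.integer(pos),
    mac = apply(X, 2L, snp_mac),
    maf = apply(X, 2L, snp_maf),
    stringsAsFactors = FALSE
  )
  line_ids <- sprintf("line%04d", seq_len(n))
  rownames(X) <- line_ids
  colnames(X) <- snps$id

  structure(list(X = X, snps = snps, line_ids = line_ids, cluster = cluster),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d SNPs (%s), %d clusters, %.2f%% missing\n",
              nrow(x$X), ncol(x$X), paste(unique(x$snps$chrom), collapse = ","),
              length(unique(x$cluster)), 100 * mean(is.na(x$X))))
  invisible(x)
}
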