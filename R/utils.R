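#' Z-score a numeric vector
#'
#' Centers and scales to unit sample standard deviation. Used for phenotypes,
#' covariates and tested SNP columns before association so that effect sizes
#' are comparable across loci.
#'
#' @param x numeric vector (no NA).
#' @return numeric vector with mean 0 and sd 1.
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant vector")
  }
  (x - mean(x)) / s
}

#' Derive a stage seed from a global seed
#'
#' Deterministic arithmetic derivation so that one global seed reproduces an
#' entire multi-stage run while stages remain decoupled.
#'
#' @param seed global integer seed.
#' @param stage small integer stage offset.
#' @return integer seed < 2^31.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647L)
}

# Minor allele count / frequency over the non-missing entries of a 0/1 column.
snp_mac <- function(x) {
  x <- x[!is.na(x)]
  min(sum(x == 1L), sum(x == 0L))
}

snp_maf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  min(sum(x == 1L), sum(x == 0L)) / length(x)
}

# Column-wise mean imputation of a 0/1 matrix (returns numeric matrix).
impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- cm[idx[, 2L]]
  X
}
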