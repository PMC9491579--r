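#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the fraction of SNPs, non-missing in both lines, at which the
#' two lines carry the same genotype. Computed on all SNPs (no MAF filter by
#' default: the MAF filter belongs to the association scan, not to the
#' relatedness estimate), which can be changed via `maf_min`.
#'
#' @param geno a `geno_matrix` or a plain 0/1 matrix (lines x SNPs, NA
#'   allowed).
#' @param maf_min optional MAF filter applied before computing IBS.
#' @return symmetric n x n matrix with unit diagonal.
#' @export
compute_kinship <- function(geno, maf_min = NULL) {
  X <- if (inherits(geno, "geno_matrix")) geno$X else geno
  if (nrow(X) < 2L) stop("need at least 2 lines")
  if (!is.null(maf_min)) {
    keep <- apply(X, 2L, snp_maf) > maf_min
    X <- X[, keep, drop = FALSE]
  }
  A <- (X == 1L); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- (X == 0L); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  M <- !is.na(X); storage.mode(M) <- "double"
  matches <- tcrossprod(A) + tcrossprod(B)
  denom <- tcrossprod(M)
  if (any(denom == 0)) {
    stop("a pair of lines has no jointly non-missing SNPs")
  }
  K <- matches / denom
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}
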