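# Shared fixture builders and independent oracles for the test suite.

# Wrap a raw 0/1 matrix as a geno_matrix, with evenly spaced positions.
make_geno <- function(X, chrom = NULL, pos = NULL, cluster = NULL,
                      spacing = 1000L) {
  n <- nrow(X); m <- ncol(X)
  storage.mode(X) <- "integer"
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * spacing
  line_ids <- sprintf("l%03d", seq_len(n))
  ids <- sprintf("s%03d", seq_len(m))
  rownames(X) <- line_ids; colnames(X) <- ids
  structure(list(
    X = X,
    snps = data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
                      mac = apply(X, 2, condgwas:::snp_mac),
                      maf = apply(X, 2, condgwas:::snp_maf),
                      stringsAsFactors = FALSE),
    line_ids = line_ids,
    cluster = if (is.null(cluster)) rep(1L, n) else cluster),
    class = "geno_matrix")
}

# Brute-force GLS oracle: forms V = sigma_g2 K + sigma_e2 I explicitly,
# inverts it, and computes the Wald t test for each SNP. Independent of the
# eigen-rotation code path it checks.
oracle_scan <- function(y, geno, K, covariate = NULL, maf_min = 0.05,
                        null_fit) {
  n <- length(y)
  yz <- (y - mean(y)) / sd(y)
  V <- null_fit$sigma_g2 * K + null_fit$sigma_e2 * diag(n)
  Vi <- solve(V)
  X0 <- cbind(rep(1, n))
  if (!is.null(covariate)) {
    X0 <- cbind(X0, (covariate - mean(covariate)) / sd(covariate))
  }
  maf <- apply(geno$X, 2, condgwas:::snp_maf)
  keep <- which(!is.na(maf) & maf > maf_min)
  out <- lapply(keep, function(j) {
    x <- geno$X[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x <- (x - mean(x)) / sd(x)
    X <- cbind(X0, x)
    p <- ncol(X)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% yz)
    r <- yz - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    se <- sqrt(s2 * solve(XtViX)[p, p])
    tt <- b[p] / se
    data.frame(snp_index = j, beta = b[p], se = se,
               p_value = 2 * pt(-abs(tt), n - p))
  })
  do.call(rbind, out)
}

# Dense-matrix restricted log-likelihood for the bivariate trait model,
# used as the oracle for the block-diagonalized MTMM implementation.
dense_bivariate_rll <- function(z1, z2, K, Vg, Ve) {
  n <- length(z1)
  V <- kronecker(Vg, K) + kronecker(Ve, diag(n))
  X <- kronecker(diag(2), rep(1, n))
  y <- c(z1, z2)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(
    -0.5 * (determinant(V)$modulus + drop(t(r) %*% Vi %*% r) +
              determinant(XtViX)$modulus - determinant(t(X) %*% X)$modulus +
              (2 * n - 2) * log(2 * pi)))
}

# Structured polygenic draw with covariance h2 * K (for REML recovery tests:
# drawn from the same K that is fitted).
draw_polygenic <- function(K, h2) {
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(eK$values, 0)
  as.numeric(eK$vectors %*% (sqrt(lam * h2) * rnorm(nrow(K))))
}
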