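#' Bivariate multi-trait mixed-model scan (common / specific / any effects)
#'
#' Stacks two z-scored traits and models their joint covariance as
#' `Vg %x% K + Ve %x% I` with 2x2 genetic and residual covariance matrices
#' estimated once under the no-SNP null by REML. The eigendecomposition of K
#' block-diagonalizes the problem into n independent 2x2 blocks, so the
#' restricted likelihood is evaluated in O(n); it is maximized over a
#' Cholesky parameterization of `Vg` and `Ve` (6 parameters, Nelder--Mead,
#' 5 deterministic multi-starts), which keeps both matrices positive
#' semi-definite by construction.
#'
#' Per SNP, trait-specific effects `(beta1, beta2)` are fitted by GLS in the
#' null-rotated space and three Wald tests are reported:
#' \itemize{
#'   \item `any`: 2-df test of `(beta1, beta2) = (0, 0)`;
#'   \item `common`: 1-df test of a shared effect under the constraint
#'     `beta1 = beta2`;
#'   \item `specific`: 1-df test of `beta1 - beta2 = 0`.
#' }
#'
#' If the two traits are numerically identical after z-scoring, the
#' trait-difference contrast carries no information (its variance is zero):
#' the specific statistic is identically 0 (`p = 1`) and the common test
#' reduces to, and is reported as, the univariate scan of the trait.
#'
#' @param y1,y2 numeric trait vectors aligned with `geno` rows (NA allowed;
#'   lines missing either trait are dropped).
#' @param geno a `geno_matrix`.
#' @param K kinship matrix; computed if `NULL`.
#' @param maf_min strict MAF filter.
#' @param n_starts number of multi-starts for the null REML optimization.
#' @return object of class `mtmm_result`: a list with data frames `any`,
#'   `common`, `specific` (each `snp_id`, `chrom`, `pos`, `maf`, statistic,
#'   `p_value`, `neg_log10_p`, plus `beta1`/`beta2`), the fitted `Vg`, `Ve`,
#'   the genetic correlation `rg`, and the REML log-likelihood.
#' @export
mtmm_scan <- function(y1, y2, geno, K = NULL, maf_min = 0.05, n_starts = 5L) {
  stopifnot(inherits(geno, "geno_matrix"))
  n_all <- nrow(geno$X)
  if (length(y1) != n_all || length(y2) != n_all) {
    stop("trait / genotype dimension mismatch")
  }
  if (is.null(K)) K <- compute_kinship(geno)
  include <- !is.na(y1) & !is.na(y2)
  n <- sum(include)
  if (n < 10L) stop("too few lines with both traits")
  z1 <- zscore(y1[include]); z2 <- zscore(y2[include])

  Xg <- geno$X[include, , drop = FALSE]
  maf <- apply(Xg, 2L, snp_maf)
  keep <- which(!is.na(maf) & maf > maf_min)
  if (!length(keep)) stop("no SNPs pass the MAF filter")
  meta <- data.frame(snp_id = geno$snps$id[keep], chrom = geno$snps$chrom[keep],
                     pos = geno$snps$pos[keep], maf = maf[keep],
                     stringsAsFactors = FALSE)

  if (isTRUE(all.equal(z1, z2, tolerance = 1e-12))) {
    uni <- association_scan(y1, geno, K, maf_min = maf_min)
    base <- data.frame(meta, beta1 = uni$beta, beta2 = uni$beta,
                       stringsAsFactors = FALSE)
    mk <- function(stat, p) {
      d <- base; d$statistic <- stat; d$p_value <- p
      d$neg_log10_p <- -log10(p); d
    }
    tuni <- (uni$beta / uni$se)^2
    out <- list(any = mk(tuni, uni$p_value),
                common = mk(tuni, uni$p_value),
                specific = mk(rep(0, nrow(base)), rep(1, nrow(base))),
                Vg = NULL, Ve = NULL, rg = 1,
                reml_loglik = NA_real_, degenerate = TRUE)
    class(out) <- "mtmm_result"
    return(out)
  }

  Ki <- K[include, include]
  eK <- eigen((Ki + t(Ki)) / 2, symmetric = TRUE)
  lam <- pmax(eK$values, 0)
  U <- eK$vectors
  u0 <- as.numeric(crossprod(U, rep(1, n)))
  ys1 <- as.numeric(crossprod(U, z1))
  ys2 <- as.numeric(crossprod(U, z2))

  null <- mtmm_reml(ys1, ys2, u0, lam, n_starts = n_starts)
  iC <- mtmm_block_inverses(null$Vg, null$Ve, lam)

  Gz <- impute_mean(Xg[, keep, drop = FALSE])
  sds <- apply(Gz, 2L, stats::sd)
  Gz <- sweep(sweep(Gz, 2L, colMeans(Gz)), 2L, pmax(sds, 1e-12), "/")
  Gs <- crossprod(U, Gz)

  m <- length(keep)
  # per-SNP cross sums, vectorized over SNPs
  xu11 <- as.numeric(crossprod(Gs, iC$i11 * u0))
  xu12 <- as.numeric(crossprod(Gs, iC$i12 * u0))
  xu22 <- as.numeric(crossprod(Gs, iC$i22 * u0))
  xx11 <- colSums(Gs^2 * iC$i11)
  xx12 <- colSums(Gs^2 * iC$i12)
  xx22 <- colSums(Gs^2 * iC$i22)
  xy1 <- as.numeric(crossprod(Gs, iC$i11 * ys1 + iC$i12 * ys2))
  xy2 <- as.numeric(crossprod(Gs, iC$i12 * ys1 + iC$i22 * ys2))
  # intercept-only sums
  a11 <- sum(u0^2 * iC$i11); a12 <- sum(u0^2 * iC$i12)
  a22 <- sum(u0^2 * iC$i22)
  b1 <- sum(u0 * (iC$i11 * ys1 + iC$i12 * ys2))
  b2 <- sum(u0 * (iC$i12 * ys1 + iC$i22 * ys2))

  beta1 <- beta2 <- w_any <- w_spec <- bet_c <- w_com <- numeric(m)
  for (j in seq_len(m)) {
    A4 <- matrix(c(a11, a12, xu11[j], xu12[j],
                   a12, a22, xu12[j], xu22[j],
                   xu11[j], xu12[j], xx11[j], xx12[j],
                   xu12[j], xu22[j], xx12[j], xx22[j]), 4L, 4L)
    rhs <- c(b1, b2, xy1[j], xy2[j])
    Ainv <- tryCatch(solve(A4), error = function(e) NULL)
    if (is.null(Ainv)) {
      beta1[j] <- beta2[j] <- NA_real_
      w_any[j] <- w_spec[j] <- w_com[j] <- 0
      next
    }
    bt <- Ainv %*% rhs
    beta1[j] <- bt[3L]; beta2[j] <- bt[4L]
    Vsnp <- Ainv[3:4, 3:4]
    w_any[j] <- tryCatch(
      drop(t(bt[3:4]) %*% solve(Vsnp, bt[3:4])), error = function(e) 0)
    cvec <- c(0, 0, 1, -1)
    denom <- drop(t(cvec) %*% Ainv %*% cvec)
    w_spec[j] <- if (denom > 0) (bt[3L] - bt[4L])^2 / denom else 0
    # constrained common-effect fit: single column (x, x)
    A3 <- matrix(c(a11, a12, xu11[j] + xu12[j],
                   a12, a22, xu12[j] + xu22[j],
                   xu11[j] + xu12[j], xu12[j] + xu22[j],
                   xx11[j] + 2 * xx12[j] + xx22[j]), 3L, 3L)
    r3 <- c(b1, b2, xy1[j] + xy2[j])
    A3inv <- tryCatch(solve(A3), error = function(e) NULL)
    if (is.null(A3inv)) { w_com[j] <- 0; next }
    b3 <- A3inv %*% r3
    bet_c[j] <- b3[3L]
    w_com[j] <- if (A3inv[3L, 3L] > 0) b3[3L]^2 / A3inv[3L, 3L] else 0
  }

  mk <- function(stat, df, b1v, b2v) {
    p <- pmax(stats::pchisq(stat, df, lower.tail = FALSE), 1e-300)
    d <- data.frame(meta, beta1 = b1v, beta2 = b2v, statistic = stat,
                    p_value = p, neg_log10_p = -log10(p),
                    stringsAsFactors = FALSE)
    d
  }
  out <- list(
    any = mk(w_any, 2L, beta1, beta2),
    common = mk(w_com, 1L, bet_c, bet_c),
    specific = mk(w_spec, 1L, beta1, beta2),
    Vg = null$Vg, Ve = null$Ve,
    rg = null$Vg[1L, 2L] / sqrt(null$Vg[1L, 1L] * null$Vg[2L, 2L]),
    reml_loglik = null$loglik, degenerate = FALSE)
  class(out) <- "mtmm_result"
  out
}

# 2x2 block inverses of C_i = Vg * lambda_i + Ve, vectorized over blocks.
mtmm_block_inverses <- function(Vg, Ve, lam) {
  c11 <- Vg[1, 1] * lam + Ve[1, 1]
  c22 <- Vg[2, 2] * lam + Ve[2, 2]
  c12 <- Vg[1, 2] * lam + Ve[1, 2]
  det <- c11 * c22 - c12^2
  list(i11 = c22 / det, i22 = c11 / det, i12 = -c12 / det,
       logdet = sum(log(det)))
}

# REML over the Cholesky parameterization of (Vg, Ve) for the bivariate
# null model with per-trait intercepts. theta = (log lg11, lg21, log lg22,
# log le11, le21, log le22).
mtmm_reml <- function(ys1, ys2, u0, lam, n_starts = 5L,
                      reltol = 1e-8, maxit = 2000L) {
  n <- length(lam)

  unpack <- function(th) {
    Lg <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2L, 2L)
    Le <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2L, 2L)
    list(Vg = tcrossprod(Lg), Ve = tcrossprod(Le))
  }

  negll <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 20)) return(1e10)
    V <- unpack(th)
    iC <- mtmm_block_inverses(V$Vg, V$Ve, lam)
    if (!all(is.finite(iC$i11))) return(1e10)
    a11 <- sum(u0^2 * iC$i11); a12 <- sum(u0^2 * iC$i12)
    a22 <- sum(u0^2 * iC$i22)
    detA <- a11 * a22 - a12^2
    if (!is.finite(detA) || detA <= 0) return(1e10)
    bb1 <- sum(u0 * (iC$i11 * ys1 + iC$i12 * ys2))
    bb2 <- sum(u0 * (iC$i12 * ys1 + iC$i22 * ys2))
    yVy <- sum(iC$i11 * ys1^2 + 2 * iC$i12 * ys1 * ys2 + iC$i22 * ys2^2)
    beta1 <- (a22 * bb1 - a12 * bb2) / detA
    beta2 <- (a11 * bb2 - a12 * bb1) / detA
    quad <- yVy - (beta1 * bb1 + beta2 * bb2)
    ll <- -0.5 * (iC$logdet + quad + log(detA) - 2 * log(n) +
                    (2 * n - 2) * log(2 * pi))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  cv <- stats::cor(ys1, ys2)
  h2s <- c(0.5, 0.2, 0.8, 0.35, 0.65)[seq_len(n_starts)]
  best <- NULL
  for (s in seq_along(h2s)) {
    h <- h2s[s]
    th0 <- c(0.5 * log(h), cv * sqrt(h), 0.5 * log(h / 2),
             0.5 * log(1 - h), cv * sqrt(1 - h), 0.5 * log((1 - h) / 2))
    opt <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("multi-trait REML failed to converge; diagnostics: best objective ",
         best$value)
  }
  V <- unpack(best$par)
  list(Vg = V$Vg, Ve = V$Ve, loglik = -best$value, par = best$par,
       convergence = best$convergence)
}

#' @export
print.mtmm_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("MTMM scan (degenerate: identical traits; common == univariate)\n")
  } else {
    cat(sprintf("MTMM scan: %d SNPs; genetic correlation rg = %.3f\n",
                nrow(x$any), x$rg))
  }
  invisible(x)
}
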