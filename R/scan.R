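#' Mixed-model association scan (univariate or conditional)
#'
#' Scans every SNP with MAF strictly above `maf_min` under the model
#' `y = alpha * L + beta * x + g + e`, `var(y) = sigma_g2 K + sigma_e2 I`,
#' where `L` is an optional correlated-trait covariate (the conditional
#' model; the univariate model takes `alpha = 0`). The phenotype, the
#' covariate, and each tested SNP column are z-scored over the included
#' lines. The null model (without any SNP) is fitted once by [reml_fit()];
#' per-SNP effects are then tested by generalized least squares in the
#' eigen-rotated space with the variance ratio `delta` held at the null
#' estimate (the EMMAX approximation), giving a two-sided Wald t test with
#' `n - p` degrees of freedom. `exact = TRUE` refits `delta` per SNP by REML
#' instead (slow; for validation).
#'
#' Lines with a missing phenotype (or covariate) are dropped before
#' z-scoring. Missing genotypes are mean-imputed per SNP before z-scoring.
#' A SNP collinear with the fixed effects gets `p = 1` and a `collinear`
#' flag.
#'
#' @param y numeric phenotype vector aligned with the rows of `geno` (NA
#'   allowed; those lines are dropped).
#' @param geno a `geno_matrix`.
#' @param K kinship matrix for all lines of `geno`; computed if `NULL`.
#' @param covariate optional numeric covariate vector (same alignment).
#' @param maf_min strict MAF threshold (SNPs with `MAF > maf_min` are tested).
#' @param exact refit `delta` per SNP by REML (exact mixed model) instead of
#'   holding it at the null estimate.
#' @param refit_top two-stage scan: after the EMMAX pass, refit this many of
#'   the strongest associations exactly (per-SNP REML) and replace their
#'   statistics. A strongly structured causal SNP inflates the null model's
#'   genetic variance and partially absorbs itself under the EMMAX
#'   approximation; the exact refit removes that bias exactly where it
#'   matters while keeping the genome pass fast. 0 disables.
#' @return data frame of class `assoc_result` with one row per tested SNP:
#'   `snp_id`, `chrom`, `pos`, `mac`, `maf`, `beta`, `se`, `p_value`,
#'   `neg_log10_p`, `collinear`, and `alpha` for conditional scans.
#'   Attributes: `model` ("univariate"/"conditional"), `null_fit`, `n_lines`.
#' @export
association_scan <- function(y, geno, K = NULL, covariate = NULL,
                             maf_min = 0.05, exact = FALSE,
                             refit_top = 0L) {
  stopifnot(inherits(geno, "geno_matrix"))
  n_all <- nrow(geno$X)
  if (length(y) != n_all) stop("phenotype / genotype dimension mismatch")
  if (!is.null(covariate) && length(covariate) != n_all) {
    stop("covariate / genotype dimension mismatch")
  }
  if (is.null(K)) K <- compute_kinship(geno)
  include <- !is.na(y)
  if (!is.null(covariate)) include <- include & !is.na(covariate)
  n <- sum(include)
  if (n < 4L) stop("too few lines with complete phenotype data")

  yz <- zscore(y[include])
  cz <- if (is.null(covariate)) NULL else zscore(covariate[include])
  Ki <- K[include, include]

  Xg <- geno$X[include, , drop = FALSE]
  maf <- apply(Xg, 2L, snp_maf)
  mac <- apply(Xg, 2L, snp_mac)
  keep <- which(!is.na(maf) & maf > maf_min)
  if (!length(keep)) stop("no SNPs pass the MAF filter")

  null <- reml_fit(yz, covariates = cz, K = Ki)
  p0 <- null$p
  df <- n - (p0 + 1L)

  Gz <- impute_mean(Xg[, keep, drop = FALSE])
  sds <- apply(Gz, 2L, stats::sd)
  Gz <- sweep(sweep(Gz, 2L, colMeans(Gz)), 2L, pmax(sds, 1e-12), "/")

  if (exact) {
    res <- exact_scan(yz, cz, Gz, Ki)
    beta <- res$beta; se <- res$se; alpha <- res$alpha
    collinear <- res$collinear
  } else {
    sw <- sqrt(1 / (null$eigenvalues + null$delta))
    X0w <- null$Xs * sw
    yw <- null$ys * sw
    qr0 <- qr(X0w)
    Q <- qr.Q(qr0)
    ey <- yw - Q %*% crossprod(Q, yw)
    if (sum(ey^2) < 1e-12 * sum(yw^2)) {
      # fixed effects explain the phenotype completely (e.g. the covariate
      # is a copy of it): no residual information, every SNP gets p = 1
      out <- data.frame(
        snp_id = geno$snps$id[keep], chrom = geno$snps$chrom[keep],
        pos = geno$snps$pos[keep], mac = mac[keep], maf = maf[keep],
        beta = 0, se = NA_real_, p_value = 1, neg_log10_p = 0,
        collinear = FALSE, stringsAsFactors = FALSE)
      if (!is.null(cz)) out$alpha <- NA_real_
      out$snp_index <- keep
      class(out) <- c("assoc_result", "data.frame")
      attr(out, "model") <- if (is.null(covariate)) "univariate" else "conditional"
      attr(out, "null_fit") <- null
      attr(out, "n_lines") <- n
      return(out)
    }
    Gw <- crossprod(null$U, Gz) * sw
    EG <- Gw - Q %*% crossprod(Q, Gw)
    exx <- colSums(EG^2)
    exy <- colSums(EG * as.numeric(ey))
    collinear <- exx < n * 1e-10
    beta <- exy / exx
    rss <- pmax(sum(ey^2) - beta * exy, 0)
    se <- sqrt(rss / df / exx)
    alpha <- NULL
    if (!is.null(cz)) {
      A <- qr.coef(qr0, Gw)        # (p0 x m) projections of SNPs on X0
      c0 <- qr.coef(qr0, yw)
      alpha <- as.numeric(c0[2L] - A[2L, ] * beta)
    }
  }

  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  bad <- collinear | !is.finite(p)
  p[bad] <- 1
  beta[collinear] <- NA_real_
  se[collinear] <- NA_real_
  p <- pmax(p, 1e-300)

  out <- data.frame(
    snp_id = geno$snps$id[keep], chrom = geno$snps$chrom[keep],
    pos = geno$snps$pos[keep], mac = mac[keep], maf = maf[keep],
    beta = beta, se = se, p_value = p, neg_log10_p = -log10(p),
    collinear = collinear, stringsAsFactors = FALSE)
  if (!is.null(cz) && !is.null(alpha)) out$alpha <- alpha
  out$snp_index <- keep
  out$exact_refit <- FALSE

  if (refit_top > 0L && !exact) {
    top <- utils::head(order(out$p_value), min(refit_top, nrow(out)))
    eK <- list(values = null$eigenvalues, vectors = null$U)
    for (i in top) {
      if (out$collinear[i]) next
      Xj <- cbind(cz, Gz[, match(out$snp_index[i], keep)])
      fit <- tryCatch(reml_fit(yz, covariates = Xj, K = NULL, eigen_K = eK),
                      error = function(e) NULL)
      if (is.null(fit)) next
      w <- 1 / (fit$eigenvalues + fit$delta)
      XtWX <- crossprod(fit$Xs, fit$Xs * w)
      Vb <- fit$sigma_g2 * solve(XtWX)
      k <- fit$p
      out$beta[i] <- fit$beta[k]
      out$se[i] <- sqrt(Vb[k, k])
      tt <- out$beta[i] / out$se[i]
      out$p_value[i] <- max(2 * stats::pt(-abs(tt), n - k), 1e-300)
      out$neg_log10_p[i] <- -log10(out$p_value[i])
      if (!is.null(cz)) out$alpha[i] <- fit$beta[2L]
      out$exact_refit[i] <- TRUE
    }
  }

  class(out) <- c("assoc_result", "data.frame")
  attr(out, "model") <- if (is.null(covariate)) "univariate" else "conditional"
  attr(out, "null_fit") <- null
  attr(out, "n_lines") <- n
  out
}

# Per-SNP exact mixed model: REML refit of delta with the SNP in the fixed
# effects, Wald t at the per-SNP optimum. Used to validate the EMMAX
# approximation on small problems.
exact_scan <- function(yz, cz, Gz, Ki) {
  m <- ncol(Gz)
  beta <- se <- alpha <- rep(NA_real_, m)
  collinear <- logical(m)
  for (j in seq_len(m)) {
    Xj <- cbind(cz, Gz[, j])
    fit <- tryCatch(reml_fit(yz, covariates = Xj, K = Ki),
                    error = function(e) NULL)
    if (is.null(fit)) { collinear[j] <- TRUE; next }
    w <- 1 / (fit$eigenvalues + fit$delta)
    XtWX <- crossprod(fit$Xs, fit$Xs * w)
    Vb <- fit$sigma_g2 * solve(XtWX)
    k <- fit$p
    beta[j] <- fit$beta[k]
    se[j] <- sqrt(Vb[k, k])
    if (!is.null(cz)) alpha[j] <- fit$beta[2L]
  }
  list(beta = beta, se = se, alpha = if (is.null(cz)) NULL else alpha,
       collinear = collinear)
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' `alpha` divided by the number of tested SNPs, i.e. the SNPs that survived
#' the MAF filter of the scan.
#'
#' @param result an `assoc_result`.
#' @param alpha family-wise error rate (default 0.05).
#' @return p-value threshold.
#' @export
bonferroni_threshold <- function(result, alpha = 0.05) {
  if (!nrow(result)) stop("empty association result")
  alpha / nrow(result)
}
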