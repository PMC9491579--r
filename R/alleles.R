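#' Permutation specification for frequency-matched SNP nulls
#'
#' @param n_perm number of permutation replicates (default 3000).
#' @param mode `"exact-mac"` (candidates share the focal SNP's minor allele
#'   count exactly) or `"frequency-bin"` (candidates within
#'   `bin_halfwidth` of the focal MAF).
#' @param bin_halfwidth half-width of the MAF bin (default 0.01).
#' @param seed integer seed.
#' @return list of class `perm_spec`.
#' @export
perm_spec <- function(n_perm = 3000L, mode = c("exact-mac", "frequency-bin"),
                      bin_halfwidth = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L)
  structure(list(n_perm = as.integer(n_perm), mode = mode,
                 bin_halfwidth = bin_halfwidth, seed = as.integer(seed)),
            class = "perm_spec")
}

#' Orient the trait-decreasing allele at focal loci
#'
#' The decreasing allele at a focal SNP is the genotype code whose carriers
#' have the lower fitted (conditional) phenotype: code 1 (alternative) when
#' the fitted effect `beta` is negative, code 0 (reference) when positive.
#' An exactly zero effect cannot be oriented and is an error.
#'
#' @param scan an `assoc_result` containing the focal SNPs.
#' @param snps SNP ids or indices (matched against `snp_id` / `snp_index`).
#' @return data frame of class `focal_allele_set`: `snp_id`, `snp_index`,
#'   `mac`, `maf`, `beta`, `decreasing_code`, `decreasing_is_minor`.
#' @export
orient_alleles <- function(scan, snps) {
  if (is.numeric(snps)) {
    rows <- match(snps, scan$snp_index)
  } else {
    rows <- match(snps, scan$snp_id)
  }
  if (anyNA(rows)) stop("focal SNP(s) not present in the scan: ",
                        paste(snps[is.na(rows)], collapse = ", "))
  b <- scan$beta[rows]
  if (any(!is.finite(b))) stop("focal SNP has no finite effect estimate")
  if (any(b == 0)) stop("cannot orient an allele with effect exactly 0")
  code <- ifelse(b < 0, 1L, 0L)
  out <- data.frame(snp_id = scan$snp_id[rows], snp_index = scan$snp_index[rows],
                    mac = scan$mac[rows], maf = scan$maf[rows], beta = b,
                    decreasing_code = code, stringsAsFactors = FALSE)
  class(out) <- c("focal_allele_set", "data.frame")
  out
}

#' Per-line cumulative count of decreasing alleles
#'
#' @param geno a `geno_matrix`.
#' @param alleles a `focal_allele_set`.
#' @return integer vector (0..k) named by line; lines missing any focal
#'   genotype are dropped with a warning.
#' @export
cumulative_counts <- function(geno, alleles) {
  Xf <- geno$X[, alleles$snp_index, drop = FALSE]
  miss <- rowSums(is.na(Xf)) > 0
  if (any(miss)) {
    warning(sum(miss), " line(s) dropped: missing focal genotype")
    Xf <- Xf[!miss, , drop = FALSE]
  }
  cnt <- as.integer(
    rowSums(Xf == matrix(alleles$decreasing_code, nrow(Xf),
                         ncol(Xf), byrow = TRUE)))
  names(cnt) <- rownames(Xf)
  cnt
}

#' Additive fit of a phenotype on the cumulative allele count
#'
#' OLS slope of the phenotype on the 0..k count, plus per-class means, to
#' check that multi-locus effects combine additively (class means falling on
#' a line).
#'
#' @param y phenotype vector aligned with `counts`.
#' @param counts integer cumulative counts.
#' @return list: `slope`, `slope_se`, `intercept`, `class_means` (data frame
#'   `count`, `mean`, `n`).
#' @export
additive_fit <- function(y, counts) {
  ok <- is.finite(y) & !is.na(counts)
  y <- y[ok]; counts <- counts[ok]
  if (length(unique(counts)) < 2L) stop("need at least 2 distinct count classes")
  fit <- stats::lm(y ~ counts)
  cm <- stats::aggregate(y, list(count = counts),
                         function(v) c(mean = mean(v), n = length(v)))
  class_means <- data.frame(count = cm$count, mean = cm$x[, "mean"],
                            n = as.integer(cm$x[, "n"]))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["counts", "Estimate"]),
       slope_se = unname(sm["counts", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       class_means = class_means)
}

#' Variance jointly explained by a set of focal SNPs
#'
#' Coefficient of determination (r^2) of the OLS fit of the phenotype on the
#' focal SNP genotypes jointly, with intercept. Duplicated genotype columns
#' are dropped first.
#'
#' @param y phenotype vector aligned with `geno` rows.
#' @param geno a `geno_matrix`.
#' @param snps focal SNP indices.
#' @return fraction in `[0, 1]`.
#' @export
variance_explained_r2 <- function(y, geno, snps) {
  X <- impute_mean(geno$X[, snps, drop = FALSE])
  X <- X[, !duplicated(t(X)), drop = FALSE]
  ok <- is.finite(y)
  if (sum(ok) <= ncol(X) + 1L) stop("too few lines for the number of SNPs")
  summary(stats::lm(y[ok] ~ X[ok, , drop = FALSE]))$r.squared
}

#' Draw allele-frequency-matched null SNP sets
#'
#' For each focal SNP, candidate SNPs are those with the identical minor
#' allele count (`exact-mac` mode) or with MAF within `bin_halfwidth`
#' (`frequency-bin` mode), excluding the focal SNP itself. Each replicate set
#' takes one uniform draw per focal SNP; draws are with replacement across
#' replicates and deterministic under the spec seed.
#'
#' @param geno a `geno_matrix`.
#' @param focal a `focal_allele_set`.
#' @param spec a [perm_spec()].
#' @return integer matrix `n_perm` x `n_focal` of SNP indices.
#' @export
matched_snp_sample <- function(geno, focal, spec) {
  mac_all <- geno$snps$mac
  maf_all <- geno$snps$maf
  cand <- lapply(seq_len(nrow(focal)), function(i) {
    if (spec$mode == "exact-mac") {
      idx <- which(mac_all == focal$mac[i])
    } else {
      idx <- which(abs(maf_all - focal$maf[i]) <= spec$bin_halfwidth)
    }
    idx <- setdiff(idx, focal$snp_index[i])
    if (!length(idx)) {
      stop("no frequency-matched candidate for focal SNP ", focal$snp_id[i],
           if (spec$mode == "exact-mac") " (try frequency-bin mode)" else "")
    }
    idx
  })
  set.seed(spec$seed)
  sets <- vapply(cand, function(idx) {
    idx[sample.int(length(idx), spec$n_perm, replace = TRUE)]
  }, integer(spec$n_perm))
  matrix(sets, nrow = spec$n_perm)
}

# counts of the frequency-matched allele for a replicate SNP set: for each
# focal SNP the matched SNP contributes its minor allele when the focal
# decreasing allele is the minor one, else its major allele
null_counts <- function(geno, focal, set_idx) {
  Xs <- impute_mean(geno$X[, set_idx, drop = FALSE])
  n <- nrow(Xs)
  dec_minor <- focal_decreasing_is_minor(geno, focal)
  cnt <- numeric(n)
  for (j in seq_along(set_idx)) {
    x <- Xs[, j]
    alt_is_minor <- mean(x) <= 0.5
    code <- if (dec_minor[j] == alt_is_minor) 1 else 0
    cnt <- cnt + (x == code)
  }
  cnt
}

focal_decreasing_is_minor <- function(geno, focal) {
  vapply(seq_len(nrow(focal)), function(i) {
    x <- geno$X[, focal$snp_index[i]]
    f_alt <- mean(x == 1L, na.rm = TRUE)
    alt_is_minor <- f_alt <= 0.5
    if (focal$decreasing_code[i] == 1L) alt_is_minor else !alt_is_minor
  }, logical(1))
}

#' Permutation test of a geographic cline in cumulative allele counts
#'
#' Observed statistic: Pearson correlation between the per-line cumulative
#' decreasing-allele count and longitude. Null distribution: the same
#' statistic recomputed with each frequency-matched replicate SNP set (which
#' preserves the allele-frequency spectrum, so population-structure-driven
#' clines are part of the null). Two-sided p-value
#' `(1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @param geno a `geno_matrix`.
#' @param focal a `focal_allele_set`.
#' @param longitude per-line longitude aligned with `geno` rows (NA dropped
#'   listwise).
#' @param spec a [perm_spec()].
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list of class `perm_test`: `observed_r`, `p_value`, `null_r`,
#'   `n_perm`, `n_lines`.
#' @export
clinal_test <- function(geno, focal, longitude, spec,
                        alternative = "two.sided") {
  perm_correlation_test(geno, focal, longitude, spec, alternative,
                        label = "clinal")
}

#' Permutation test of LD between cumulative counts and a partner locus
#'
#' As [clinal_test()], with the partner locus genotype in place of
#' longitude: tests whether the focal decreasing alleles co-occur with the
#' partner allele more than frequency-matched random SNP sets do.
#'
#' @inheritParams clinal_test
#' @param partner_genotype 0/1 genotype vector of the partner locus.
#' @return list of class `perm_test`.
#' @export
ld_with_focal_test <- function(geno, focal, partner_genotype, spec,
                               alternative = "two.sided") {
  perm_correlation_test(geno, focal, as.numeric(partner_genotype), spec,
                        alternative, label = "ld")
}

perm_correlation_test <- function(geno, focal, covar, spec, alternative,
                                  label) {
  if (length(covar) != nrow(geno$X)) stop("covariate length mismatch")
  if (stats::sd(covar, na.rm = TRUE) == 0 || all(is.na(covar))) {
    stop("constant covariate: correlation undefined")
  }
  ok <- !is.na(covar)
  Xf <- geno$X[, focal$snp_index, drop = FALSE]
  ok <- ok & rowSums(is.na(Xf)) == 0
  gsub_ <- geno
  gsub_$X <- geno$X[ok, , drop = FALSE]
  gsub_$line_ids <- geno$line_ids[ok]
  covar <- covar[ok]

  obs_cnt <- as.numeric(cumulative_counts(gsub_, focal))
  r_obs <- stats::cor(obs_cnt, covar)
  sets <- matched_snp_sample(gsub_, focal, spec)
  r_null <- vapply(seq_len(nrow(sets)), function(b) {
    cnt <- null_counts(gsub_, focal, sets[b, ])
    if (stats::sd(cnt) == 0) return(0)
    stats::cor(cnt, covar)
  }, numeric(1))
  p <- perm_pvalue(r_obs, r_null, alternative)
  structure(list(observed_r = r_obs, p_value = p, null_r = r_null,
                 n_perm = spec$n_perm, n_lines = sum(ok), test = label),
            class = "perm_test")
}

perm_pvalue <- function(obs, null, alternative) {
  switch(alternative,
         two.sided = (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1),
         greater = (1 + sum(null >= obs)) / (length(null) + 1),
         less = (1 + sum(null <= obs)) / (length(null) + 1),
         stop("unknown alternative"))
}

#' Epistasis test on transposon insertion counts
#'
#' For each class k of the cumulative decreasing-allele count, the observed
#' statistic is the mean insertion count among lines that carry the partner
#' locus non-reference allele and have count k (or `>= k` with
#' `class_mode = "geq"`). The null replaces the partner locus with each of
#' `n_perm` frequency-matched SNPs (matched on the partner's minor allele
#' count, orientation preserved) and recomputes the class means. One-sided
#' (greater) p-value per class by default; empty classes are flagged with NA
#' rather than zero-filled.
#'
#' @param insertions per-line insertion counts aligned with `geno` rows.
#' @param geno a `geno_matrix`.
#' @param partner_index SNP index of the partner locus.
#' @param focal a `focal_allele_set` defining the cumulative count.
#' @param spec a [perm_spec()].
#' @param k_grid count classes to test (default 0:5).
#' @param class_mode `"exact"` (count == k) or `"geq"` (count >= k).
#' @param alternative p-value sidedness per class (default `"greater"`).
#' @return data frame of class `epistasis_result`: `k`, `n_lines`,
#'   `observed_mean`, `p_value`, `empty`.
#' @export
epistasis_insertion_test <- function(insertions, geno, partner_index, focal,
                                     spec, k_grid = 0:5,
                                     class_mode = c("exact", "geq"),
                                     alternative = "greater") {
  class_mode <- match.arg(class_mode)
  n <- nrow(geno$X)
  if (length(insertions) != n) stop("insertion counts length mismatch")
  partner <- geno$X[, partner_index]
  if (length(unique(stats::na.omit(partner))) < 2L) {
    stop("partner locus is monomorphic")
  }
  ok <- !is.na(insertions) & !is.na(partner)
  Xf <- geno$X[, focal$snp_index, drop = FALSE]
  ok <- ok & rowSums(is.na(Xf)) == 0

  gsub_ <- geno
  gsub_$X <- geno$X[ok, , drop = FALSE]
  gsub_$line_ids <- geno$line_ids[ok]
  ins <- insertions[ok]
  cnt <- as.integer(cumulative_counts(gsub_, focal))

  class_sel <- function(k) {
    if (class_mode == "exact") cnt == k else cnt >= k
  }
  stat <- function(part_vec, k) {
    sel <- part_vec == 1L & class_sel(k)
    if (!any(sel)) return(NA_real_)
    mean(ins[sel])
  }
  partner_ok <- gsub_$X[, partner_index]
  obs <- vapply(k_grid, function(k) stat(partner_ok, k), numeric(1))

  # frequency-matched null for the partner locus, orientation preserved
  pseudo_focal <- data.frame(
    snp_id = geno$snps$id[partner_index], snp_index = partner_index,
    mac = geno$snps$mac[partner_index], maf = geno$snps$maf[partner_index],
    beta = -1, decreasing_code = 1L, stringsAsFactors = FALSE)
  class(pseudo_focal) <- c("focal_allele_set", "data.frame")
  sets <- matched_snp_sample(gsub_, pseudo_focal, spec)
  part_is_minor <- focal_decreasing_is_minor(gsub_, pseudo_focal)

  null_mat <- matrix(NA_real_, spec$n_perm, length(k_grid))
  for (b in seq_len(spec$n_perm)) {
    x <- gsub_$X[, sets[b, 1L]]
    x[is.na(x)] <- 0L
    alt_is_minor <- mean(x) <= 0.5
    code <- if (part_is_minor[1L] == alt_is_minor) 1L else 0L
    pv <- as.integer(x == code)
    null_mat[b, ] <- vapply(k_grid, function(k) stat(pv, k), numeric(1))
  }

  p <- vapply(seq_along(k_grid), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    nv <- null_mat[, i]
    nv <- nv[!is.na(nv)]
    perm_pvalue(obs[i], nv, alternative)
  }, numeric(1))

  nl <- vapply(k_grid, function(k) sum(partner_ok == 1L & class_sel(k)),
               integer(1))
  out <- data.frame(k = k_grid, n_lines = nl, observed_mean = obs,
                    p_value = p, empty = is.na(obs))
  class(out) <- c("epistasis_result", "data.frame")
  attr(out, "null_means") <- null_mat
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s permutation test: r = %.3f, p = %.4g (%d permutations, %d lines)\n",
              x$test, x$observed_r, x$p_value, x$n_perm, x$n_lines))
  invisible(x)
}
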