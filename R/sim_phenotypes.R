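#' Simulate two correlated methylation-like traits
#'
#' Builds trait 1 (mCHH-like) and trait 2 (mCHG-like) from four independent
#' components each:
#' \itemize{
#'   \item planted QTL effects: for each row of `qtl_spec`, the z-scored
#'     genotype column times `effect1` / `effect2` (so `effect^2` is the
#'     variance contributed);
#'   \item a unit-variance shared factor, added unscaled to trait 1 and
#'     scaled by `shared_factor_sd` in trait 2; with `shared_structured` it is
#'     drawn with covariance K (a shared polygenic factor), otherwise i.i.d.;
#'   \item a trait-specific polygenic background with covariance
#'     `h2_background * K`;
#'   \item i.i.d. Gaussian noise with sd `noise_sd`.
#' }
#' Longitude is a unit-variance mixture of the z-scored ancestry-cluster
#' score (loading `cline_strength`), optionally the z-scored cumulative
#' alternative-allele count at `cline_snp_indices` (loading
#' `cline_snp_effect`), and Gaussian noise; it is then mapped linearly onto
#' the interval `[-20, 100]` degrees. Latitude is uniform on `[30, 65]`.
#'
#' Traits are returned unstandardized; all generating components are kept in
#' the `"truth"` attribute so recovery tests never reach into generator
#' internals beyond this record.
#'
#' @param geno a `geno_matrix` from [simulate_genotypes()].
#' @param kinship optional kinship matrix; computed from `geno` when `NULL`.
#' @param config the [sim_config()] used (its `seed` drives this stage via a
#'   derived stream, so phenotypes are reproducible given the genotypes).
#' @return a data frame of class `phenotype_table` with columns `line_id`,
#'   `trait1`, `trait2`, `longitude`, `latitude`, plus a `"truth"` attribute.
#' @export
simulate_phenotypes <- function(geno, kinship = NULL, config) {
  validate_sim_config(config)
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$X)
  if (n != config$n_lines) stop("geno and config dimensions disagree")
  if (is.null(kinship)) kinship <- compute_kinship(geno)
  if (!all(dim(kinship) == c(n, n))) stop("kinship dimension mismatch")
  set.seed(derive_seed(config$seed, 2L))

  # structured draws use the centered kinship rescaled to unit mean diagonal:
  # the IBS baseline (a common shift across all lines) carries no
  # cross-sectional variance, so without this rescaling a "unit-variance"
  # structured factor would have far less than unit variance across lines
  Ksym <- (kinship + t(kinship)) / 2
  Kc <- sweep(sweep(Ksym, 1L, rowMeans(Ksym)), 2L, colMeans(Ksym)) +
    mean(Ksym)
  Kc <- Kc / mean(diag(Kc))
  eK <- eigen(Kc, symmetric = TRUE)
  lam <- pmax(eK$values, 0)
  draw_structured <- function(var) {
    if (var <= 0) return(numeric(n))
    as.numeric(eK$vectors %*% (sqrt(lam * var) * stats::rnorm(n)))
  }

  # planted QTL contributions on z-scored genotype columns
  q1 <- q2 <- numeric(n)
  qs <- config$qtl_spec
  if (!is.null(qs) && nrow(qs)) {
    for (r in seq_len(nrow(qs))) {
      xz <- zscore(impute_mean(geno$X[, qs$snp_index[r], drop = FALSE])[, 1L])
      q1 <- q1 + qs$effect1[r] * xz
      q2 <- q2 + qs$effect2[r] * xz
    }
  }

  if (config$shared_structured) {
    shared <- draw_structured(1)
  } else {
    shared <- stats::rnorm(n)
  }
  g1 <- draw_structured(config$h2_background_1)
  g2 <- draw_structured(config$h2_background_2)
  e1 <- stats::rnorm(n, sd = config$noise_sd_1)
  e2 <- stats::rnorm(n, sd = config$noise_sd_2)

  trait1 <- q1 + shared + g1 + e1
  trait2 <- q2 + config$shared_factor_sd * shared + g2 + e2

  cl_score <- zscore(as.numeric(geno$cluster))
  a <- config$cline_strength
  b <- config$cline_snp_effect
  lon_raw <- a * cl_score
  if (b != 0 && length(config$cline_snp_indices)) {
    cnt <- rowSums(impute_mean(
      geno$X[, config$cline_snp_indices, drop = FALSE]))
    lon_raw <- lon_raw + b * zscore(cnt)
  }
  resid_var <- max(0, 1 - a^2 - b^2)
  lon_raw <- lon_raw + stats::rnorm(n, sd = sqrt(resid_var))
  longitude <- -20 + (lon_raw - min(lon_raw)) /
    max(1e-12, diff(range(lon_raw))) * 120
  latitude <- stats::runif(n, 30, 65)

  out <- data.frame(line_id = geno$line_ids,
                    trait1 = trait1, trait2 = trait2,
                    longitude = longitude, latitude = latitude,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "truth") <- list(
    qtl_spec = qs, shared = shared, polygenic1 = g1, polygenic2 = g2,
    noise_sd = c(config$noise_sd_1, config$noise_sd_2),
    shared_factor_sd = config$shared_factor_sd,
    cline_strength = a, cline_snp_indices = config$cline_snp_indices,
    cline_snp_effect = b)
  out
}

#' Analytic correlation of the two simulated traits
#'
#' Closed-form expectation of `cor(trait1, trait2)` under the generating
#' model, treating QTL genotype columns as uncorrelated with each other and
#' with the structured components (exact in the unstructured limit, accurate
#' to Monte-Carlo order under moderate structure).
#'
#' @param config a [sim_config()] object.
#' @return expected Pearson correlation.
#' @export
expected_trait_correlation <- function(config) {
  qs <- config$qtl_spec
  v_q1 <- v_q2 <- cov_q <- 0
  if (!is.null(qs) && nrow(qs)) {
    v_q1 <- sum(qs$effect1^2)
    v_q2 <- sum(qs$effect2^2)
    cov_q <- sum(qs$effect1 * qs$effect2)
  }
  s <- config$shared_factor_sd
  v1 <- v_q1 + 1 + config$h2_background_1 + config$noise_sd_1^2
  v2 <- v_q2 + s^2 + config$h2_background_2 + config$noise_sd_2^2
  (cov_q + s) / sqrt(v1 * v2)
}
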