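test_that("IBS kinship counts matching genotypes, pairwise over non-missing", {
  X <- rbind(a = c(0L, 1L, 0L, 1L),
             b = c(0L, 1L, 0L, 1L),
             c = c(1L, 0L, 1L, 0L),
             d = c(0L, 1L, 0L, 0L))
  K <- compute_kinship(X)
  expect_equal(unname(diag(K)), rep(1, 4))
  expect_equal(K["a", "b"], 1)        # identical
  expect_equal(K["a", "c"], 0)        # complementary
  expect_equal(K["a", "d"], 0.75)     # agree at 3 of 4
  expect_true(isSymmetric(K))

  Xm <- X; Xm["a", 1:2] <- NA
  Km <- compute_kinship(Xm)
  expect_equal(Km["a", "d"], 0.5)     # agree at 1 of 2 jointly observed
  Xbad <- rbind(a = c(NA, NA), b = c(0L, 1L))
  expect_error(compute_kinship(Xbad), "jointly non-missing")
})

test_that("REML fit maximizes the restricted likelihood and caches rotation", {
  set.seed(101)
  cfg <- sim_config(n_lines = 120, n_snps = 600, n_clusters = 4, fst = 0.3,
                    seed = 51)
  g <- simulate_genotypes(cfg)
  K <- compute_kinship(g)
  y <- draw_polygenic(K, 0.6) + rnorm(120, sd = sqrt(0.4))
  fit <- reml_fit(y, K = K)
  expect_s3_class(fit, "null_model_fit")
  expect_gte(fit$sigma_g2, 0)
  expect_gte(fit$sigma_e2, 0)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)

  # dense-matrix oracle: restricted log-likelihood at the returned optimum
  # beats a coarse grid of alternatives
  dense_rll <- function(delta) {
    n <- 120
    V <- K + delta * diag(n)
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rwr <- drop(t(r) %*% Vi %*% r)
    sg2 <- rwr / (n - 1)
    as.numeric(-0.5 * ((n - 1) * log(2 * pi * sg2) + (n - 1) +
                         determinant(V)$modulus + log(det(XtViX)) -
                         log(n)))
  }
  # same objective evaluated on the z-scored-free raw y used by the fit
  grid <- 10^seq(-4, 4, length.out = 30)
  lls <- vapply(grid, dense_rll, numeric(1))
  expect_gte(fit$reml_loglik + 1e-6, max(lls))
  expect_equal(fit$reml_loglik, dense_rll(fit$delta), tolerance = 1e-6)
})

test_that("heritability is scale invariant and near zero for pure noise", {
  cfg <- sim_config(n_lines = 200, n_snps = 800, n_clusters = 5, fst = 0.3,
                    seed = 61)
  g <- simulate_genotypes(cfg)
  K <- compute_kinship(g)
  set.seed(1)
  y <- draw_polygenic(K, 0.5) + rnorm(200, sd = sqrt(0.5))
  expect_equal(snp_heritability(y, K), snp_heritability(5 * y, K),
               tolerance = 1e-6)
  set.seed(2)
  h0 <- replicate(10, snp_heritability(rnorm(200), K))
  expect_lt(mean(h0), 0.1)
})

test_that("the scan collapses to OLS when K = I and matches the toy example", {
  cfg <- sim_config(n_lines = 80, n_snps = 100, n_clusters = 2, fst = 0.2,
                    seed = 71)
  g <- simulate_genotypes(cfg)
  set.seed(3)
  y <- rnorm(80)
  sc <- association_scan(y, g, diag(80), maf_min = 0.05)
  yz <- scale(y)[, 1]
  p_ols <- vapply(sc$snp_index, function(j) {
    summary(lm(yz ~ scale(g$X[, j])))$coefficients[2, 4]
  }, numeric(1))
  expect_lt(max(abs(sc$p_value - p_ols)), 1e-10)

  # n = 6 toy: group-mean difference 3.0; z-scored beta equals cor(y, x)
  y6 <- as.numeric(1:6)
  X6 <- cbind(rep(c(0L, 1L), each = 3), c(0L, 1L, 0L, 1L, 0L, 1L))
  g6 <- make_geno(X6)
  sc6 <- association_scan(y6, g6, diag(6), maf_min = 0.05)
  i <- which(sc6$snp_index == 1L)
  expect_equal(sc6$beta[i], cor(y6, X6[, 1]), tolerance = 1e-10)
  # on the original scale the group-mean difference is 3.0
  expect_equal(sc6$beta[i] * sd(y6) / sd(X6[, 1]), 3.0, tolerance = 1e-10)
})

test_that("degenerate covariates are rejected or neutralized", {
  cfg <- sim_config(n_lines = 60, n_snps = 80, n_clusters = 2, fst = 0.2,
                    seed = 81)
  g <- simulate_genotypes(cfg)
  K <- compute_kinship(g)
  set.seed(4)
  y <- rnorm(60)
  expect_error(association_scan(y, g, K, covariate = rep(0, 60)),
               "constant")
  # covariate identical to y: nothing left to explain, p ~ 1
  sc <- association_scan(y, g, K, covariate = y)
  expect_true(all(sc$p_value > 0.99))
  # SNP collinear with the covariate gets p = 1 and a flag
  xcov <- as.numeric(g$X[, 3])
  sc2 <- association_scan(y, g, K, covariate = xcov)
  j <- which(sc2$snp_index == 3L)
  dup <- which(apply(g$X, 2, function(col) all(col == g$X[, 3])))
  expect_true(all(sc2$collinear[sc2$snp_index %in% dup]))
  expect_true(all(sc2$p_value[sc2$snp_index %in% dup] == 1))
})

test_that("exact per-SNP REML agrees with the EMMAX approximation closely", {
  cfg <- sim_config(n_lines = 60, n_snps = 40, n_clusters = 3, fst = 0.3,
                    seed = 91)
  g <- simulate_genotypes(cfg)
  K <- compute_kinship(g)
  set.seed(5)
  y <- draw_polygenic(K, 0.4) + rnorm(60, sd = sqrt(0.6))
  fast <- association_scan(y, g, K)
  slow <- association_scan(y, g, K, exact = TRUE)
  expect_equal(slow$beta, fast$beta, tolerance = 0.05)
  expect_gt(cor(-log10(slow$p_value), -log10(fast$p_value)), 0.99)
})

test_that("p-values are invariant under joint relabeling of lines", {
  cfg <- sim_config(n_lines = 70, n_snps = 120, n_clusters = 3, fst = 0.3,
                    seed = 95)
  g <- simulate_genotypes(cfg)
  K <- compute_kinship(g)
  set.seed(6)
  y <- draw_polygenic(K, 0.5) + rnorm(70, sd = sqrt(0.5))
  sc1 <- association_scan(y, g, K)
  perm <- sample(70)
  g2 <- g
  g2$X <- g$X[perm, , drop = FALSE]
  g2$line_ids <- g$line_ids[perm]
  g2$cluster <- g$cluster[perm]
  sc2 <- association_scan(y[perm], g2, K[perm, perm])
  expect_equal(sc2$p_value, sc1$p_value, tolerance = 1e-8)
})

test_that("Bonferroni threshold divides alpha by the tested SNP count", {
  cfg <- sim_config(n_lines = 50, n_snps = 200, n_clusters = 2, fst = 0.2,
                    maf_floor = 0.02, seed = 97)
  g <- simulate_genotypes(cfg)
  set.seed(7)
  sc <- association_scan(rnorm(50), g, diag(50), maf_min = 0.05)
  # the scan's row count equals the number of SNPs with MAF > 0.05
  maf <- apply(g$X, 2, condgwas:::snp_maf)
  expect_equal(nrow(sc), sum(maf > 0.05))
  expect_equal(bonferroni_threshold(sc), 0.05 / nrow(sc))
  expect_equal(bonferroni_threshold(sc[1, , drop = FALSE]), 0.05)
  expect_error(bonferroni_threshold(sc[0, ]), "empty")
})
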