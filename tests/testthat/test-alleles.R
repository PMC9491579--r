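make_scan_for <- function(geno, beta) {
  d <- data.frame(snp_id = geno$snps$id, chrom = geno$snps$chrom,
                  pos = geno$snps$pos, mac = geno$snps$mac,
                  maf = geno$snps$maf, beta = beta, se = 0.05,
                  p_value = 0.5, neg_log10_p = log10(2),
                  collinear = FALSE, snp_index = seq_along(beta))
  class(d) <- c("assoc_result", "data.frame")
  d
}

test_that("allele orientation follows the sign of the fitted effect", {
  g <- make_geno(cbind(c(0L, 0L, 1L, 1L), c(1L, 0L, 1L, 0L)))
  sc <- make_scan_for(g, beta = c(-0.3, 0.3))
  fo <- orient_alleles(sc, c("s001", "s002"))
  expect_equal(fo$decreasing_code, c(1L, 0L))
  # negating the phenotype flips every orientation
  sc2 <- make_scan_for(g, beta = c(0.3, -0.3))
  fo2 <- orient_alleles(sc2, c("s001", "s002"))
  expect_equal(fo2$decreasing_code, c(0L, 1L))
  sc3 <- make_scan_for(g, beta = c(0, 0.2))
  expect_error(orient_alleles(sc3, "s001"), "exactly 0")
})

test_that("cumulative counts tally decreasing alleles per line", {
  X <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  g <- make_geno(X)
  sc <- make_scan_for(g, beta = c(-0.2, 0.4, -0.1))
  fo <- orient_alleles(sc, c("s001", "s002", "s003"))
  # decreasing codes: 1, 0, 1 -> per-line tallies by hand
  cnt <- cumulative_counts(g, fo)
  expect_equal(unname(cnt), c(3L, 0L, 2L, 1L))
  # a line with all decreasing alleles scores k, none scores 0
  X2 <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L))
  g2 <- make_geno(X2)
  cnt2 <- cumulative_counts(g2, fo)
  expect_equal(unname(cnt2), c(3L, 0L))
  # missing focal genotypes drop the line with a warning
  X3 <- X; X3[2, 1] <- NA
  g3 <- make_geno(X3)
  expect_warning(cnt3 <- cumulative_counts(g3, fo), "dropped")
  expect_length(cnt3, 3)
})

test_that("the additive fit recovers a linear allele dose effect", {
  set.seed(121)
  counts <- sample(0:5, 600, replace = TRUE)
  y <- -0.2 * counts + rnorm(600, sd = 0.3)
  fit <- additive_fit(y, counts)
  expect_lt(abs(fit$slope - (-0.2)), 2 * fit$slope_se)
  expect_equal(nrow(fit$class_means), 6)
  # class means are monotone for an additive generator at this n
  expect_true(all(diff(fit$class_means$mean) < 0))
  # slope times count variance reproduces cov(y, count)
  expect_equal(fit$slope * var(counts), cov(y, counts), tolerance = 1e-8)
  expect_equal(additive_fit(rep(1, 10), rep(c(0, 1), 5))$slope, 0)
  expect_error(additive_fit(y, rep(2, 600)), "distinct")
})

test_that("r^2 equals its closed forms in the degenerate cases", {
  set.seed(13)
  cfg <- sim_config(n_lines = 400, n_snps = 100, n_clusters = 2, fst = 0.1,
                    seed = 33)
  g <- simulate_genotypes(cfg)
  snps <- which(g$snps$maf > 0.2)[1:5]
  X <- condgwas:::impute_mean(g$X[, snps, drop = FALSE])
  y_lin <- X %*% c(1, -2, 0.5, 1, 3)
  expect_equal(variance_explained_r2(as.numeric(y_lin), g, snps), 1)
  y1 <- rnorm(400)
  expect_equal(variance_explained_r2(y1, g, snps[1]),
               cor(y1, X[, 1])^2, tolerance = 1e-10)
  # null expectation of R^2 is p/(n-1)
  r2s <- replicate(20, variance_explained_r2(rnorm(400), g, snps))
  expect_lt(abs(mean(r2s) - 5 / 399), 3 * sd(r2s) / sqrt(20) + 1e-4)
  Xdist <- sapply(1:6, function(j) c(rep(1L, j), rep(0L, 6 - j)))
  expect_error(variance_explained_r2(rnorm(6), make_geno(Xdist), 1:6),
               "too few")
})

test_that("matched sampling preserves allele frequencies by construction", {
  set.seed(14)
  cfg <- sim_config(n_lines = 100, n_snps = 400, n_clusters = 2, fst = 0.2,
                    seed = 44)
  g <- simulate_genotypes(cfg)
  sc <- make_scan_for(g, beta = rep(-0.2, 400))
  focal <- orient_alleles(sc, g$snps$id[c(10, 20, 30)])
  spec <- perm_spec(n_perm = 50, seed = 5)
  sets <- matched_snp_sample(g, focal, spec)
  expect_equal(dim(sets), c(50L, 3L))
  for (j in 1:3) {
    expect_true(all(g$snps$mac[sets[, j]] == focal$mac[j]))
    expect_true(all(sets[, j] != focal$snp_index[j]))
  }
  # deterministic under the spec seed
  expect_identical(matched_snp_sample(g, focal, spec),
                   matched_snp_sample(g, focal, spec))
  # bin mode keeps MAFs inside the bin
  specb <- perm_spec(n_perm = 50, mode = "frequency-bin",
                     bin_halfwidth = 0.02, seed = 5)
  setsb <- matched_snp_sample(g, focal, specb)
  for (j in 1:3) {
    expect_true(all(abs(g$snps$maf[setsb[, j]] - focal$maf[j]) <= 0.02))
  }
  # a focal SNP with a unique MAC has no candidate in exact mode
  gu <- make_geno(cbind(c(1L, 0L, 0L, 0L, 0L, 0L),
                        rep(c(0L, 1L), 3), rep(c(1L, 0L), 3)))
  scu <- make_scan_for(gu, beta = rep(-1, 3))
  fu <- orient_alleles(scu, "s001")
  expect_error(matched_snp_sample(gu, fu, perm_spec(10, seed = 1)),
               "no frequency-matched candidate")
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  # a panel engineered so each of the 2 focal SNPs has exactly 4 exact-MAC
  # candidates: the null has 16 equally likely sets
  set.seed(15)
  n <- 60
  mk_col <- function(k) sample(rep(c(1L, 0L), c(k, n - k)))
  X <- cbind(mk_col(12), mk_col(18),                    # focal SNPs
             sapply(rep(c(12, 18), each = 4), mk_col),  # matched candidates
             sapply(c(5, 7, 9, 25, 27, 29), mk_col))    # non-matching
  g <- make_geno(X)
  sc <- make_scan_for(g, beta = rep(-0.5, ncol(X)))
  focal <- orient_alleles(sc, c("s001", "s002"))
  longitude <- rnorm(n) + 0.3 * (X[, 1] + X[, 2])

  # exhaustive oracle over all 16 candidate combinations
  cand1 <- 3:6; cand2 <- 7:10
  r_obs <- cor(X[, 1] + X[, 2], longitude)
  r_all <- as.vector(outer(cand1, cand2, Vectorize(function(a, b) {
    cor(X[, a] + X[, b], longitude)
  })))
  exact_tail <- mean(abs(r_all) >= abs(r_obs))

  res <- clinal_test(g, focal, longitude, perm_spec(n_perm = 20000, seed = 6))
  mc_tail <- mean(abs(res$null_r) >= abs(res$observed_r))
  expect_lt(abs(mc_tail - exact_tail),
            3 * sqrt(exact_tail * (1 - exact_tail) / 20000) + 1e-6)
})

test_that("permutation p-values are bounded, deterministic and calibrated", {
  set.seed(16)
  cfg <- sim_config(n_lines = 120, n_snps = 500, n_clusters = 3, fst = 0.2,
                    cline_strength = 0.5, seed = 55)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, config = cfg)
  sc <- make_scan_for(g, beta = runif(500, -1, -0.1))
  focal <- orient_alleles(sc, g$snps$id[c(50, 150, 250)])
  spec <- perm_spec(n_perm = 199, seed = 9)
  r1 <- clinal_test(g, focal, ph$longitude, spec)
  r2 <- clinal_test(g, focal, ph$longitude, spec)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)

  # longitude independent of everything: p roughly uniform over replicates
  set.seed(17)
  ps <- replicate(30, {
    lon <- rnorm(120)
    clinal_test(g, focal, lon, perm_spec(n_perm = 99, seed = sample.int(1e6, 1)))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # the partner locus itself is in the extreme tail of its own LD test
  res_ld <- ld_with_focal_test(g, focal, g$X[, 50], spec)
  expect_lt(res_ld$p_value, 0.05)
})

test_that("the epistasis test flags only the interacting genotype class", {
  set.seed(18)
  cfg <- sim_config(n_lines = 500, n_snps = 600, n_clusters = 2, fst = 0.15,
                    insertion_baseline = 0.1,
                    insertion_interaction_log_ratio = log(30),
                    insertion_k = 2, seed = 66)
  g <- simulate_genotypes(cfg)
  common <- which(g$snps$maf > 0.25)
  partner <- common[1]
  mods <- common[2:6]
  ins <- simulate_insertion_counts(g, partner, mods, cfg)
  sc <- make_scan_for(g, beta = rep(-0.5, 600))
  focal <- orient_alleles(sc, g$snps$id[mods])
  spec <- perm_spec(n_perm = 300, seed = 10)
  res <- epistasis_insertion_test(as.numeric(ins), g, partner, focal, spec,
                                  k_grid = 0:5)
  hit <- res$k >= 2 & !res$empty & res$n_lines >= 5
  expect_true(any(res$p_value[hit] < 0.05))
  # non-interacting classes are quiet
  expect_true(all(res$p_value[res$k < 2 & !res$empty] > 0.05))

  # all-zero insertions: every defined class has p = 1
  res0 <- epistasis_insertion_test(rep(0, 500), g, partner, focal, spec)
  expect_true(all(res0$p_value[!res0$empty] == 1))
  gmono <- g
  gmono$X[, 7] <- 0L
  expect_error(epistasis_insertion_test(as.numeric(ins), gmono, 7L,
                                        focal, spec),
               "monomorphic")
})
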