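test_that("genotype generator is deterministic and respects its limits", {
  cfg <- sim_config(n_lines = 60, n_snps = 300, n_clusters = 3, fst = 0.3,
                    seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$X, g2$X)
  expect_identical(g1$snps, g2$snps)
  expect_equal(dim(g1$X), c(60L, 300L))
  expect_true(all(g1$X %in% c(0L, 1L)))
  expect_length(unique(g1$cluster), 3L)

  # divergence-free limit: cluster allele frequencies coincide
  cfg0 <- sim_config(n_lines = 300, n_snps = 200, n_clusters = 3, fst = 1e-6,
                     seed = 7)
  g0 <- simulate_genotypes(cfg0)
  fr <- rowsum(g0$X + 0, g0$cluster) / as.numeric(table(g0$cluster))
  bc_var <- apply(fr, 2, var)
  # at fst = 1e-6 the Beta spread is ~p(1-p)*1e-6; what remains is binomial
  # sampling noise of the cluster means, ~p(1-p)/100
  expect_lt(mean(bc_var), 0.006)

  expect_error(sim_config(n_lines = 5, n_clusters = 10),
               "n_clusters > n_lines")
})

test_that("between-cluster frequency variance matches the Beta-model moment", {
  # E[var(p_c)] = p0(1-p0) * Fst; p0 ~ U(0.05, 0.95) so
  # E[p0(1-p0)] = 1/4 - Var(p0) - 0 = 0.25 - 0.9^2/12 = 0.1825; cluster
  # means estimated from n_c lines add E[p_c(1-p_c)]/n_c of sampling noise
  fst <- 0.3
  n_lines <- 400L
  cfg <- sim_config(n_lines = n_lines, n_snps = 2000, n_clusters = 2,
                    fst = fst, maf_floor = 0.05, seed = 1)
  g <- simulate_genotypes(cfg)
  fr <- rowsum(g$X + 0, g$cluster) / as.numeric(table(g$cluster))
  bc_var <- mean(apply(fr, 2, var))
  e_pq <- 0.25 - 0.9^2 / 12
  expected <- e_pq * fst + e_pq * (1 - fst) / (n_lines / 2)
  expect_equal(bc_var, expected, tolerance = 0.1)
})

test_that("stepping-stone demes decay in similarity with chain distance", {
  cfg <- sim_config(n_lines = 250, n_snps = 1200, n_clusters = 5, fst = 0.5,
                    structure = "stepping-stone", seed = 29)
  g <- simulate_genotypes(cfg)
  fr <- rowsum(g$X + 0, g$cluster) / as.numeric(table(g$cluster))
  adj <- mean(sapply(1:4, function(c0) cor(fr[c0, ], fr[c0 + 1, ])))
  far <- cor(fr[1, ], fr[5, ])
  expect_gt(adj, far)
  expect_gt(adj, 0.7)
})

test_that("LD blocks and masking behave as configured", {
  cfg <- sim_config(n_lines = 200, n_snps = 400, n_clusters = 2, fst = 0.2,
                    ld_block_len = 10, ld_flip_rate = 0.05, seed = 3)
  g <- simulate_genotypes(cfg)
  # within a block, adjacent SNPs agree at ~95% of lines; across blocks
  # there is no copy relation
  agree_within <- mean(g$X[, 2] == g$X[, 1])
  expect_gt(agree_within, 0.85)
  r_within <- abs(cor(g$X[, 1], g$X[, 5]))
  expect_gt(r_within, 0.5)

  cfgm <- sim_config(n_lines = 100, n_snps = 500, mask_rate = 0.1, seed = 5)
  gm <- simulate_genotypes(cfgm)
  expect_equal(mean(is.na(gm$X)), 0.1, tolerance = 0.02)
})

test_that("trait correlation follows the analytic expectation", {
  # no shared factor, no QTLs, no background: traits are independent noise
  cfg0 <- sim_config(n_lines = 400, n_snps = 300, shared_factor_sd = 0,
                     shared_structured = FALSE, h2_background_1 = 0,
                     h2_background_2 = 0, noise_sd_1 = 1, noise_sd_2 = 1,
                     seed = 11)
  g0 <- simulate_genotypes(cfg0)
  ph0 <- simulate_phenotypes(g0, config = cfg0)
  expect_lt(abs(cor(ph0$trait1, ph0$trait2)), 3 / sqrt(400))

  # architecture tuned for cor = 0.8: loading 0.9, noise sds 0.2 / 0.6026,
  # trait-2 QTL 0.2093
  cfg <- sim_config(n_lines = 800, n_snps = 1500, n_clusters = 10, fst = 0.3,
                    shared_factor_sd = 0.9, h2_background_1 = 0,
                    h2_background_2 = 0, noise_sd_1 = 0.2,
                    noise_sd_2 = 0.6026,
                    qtl_spec = data.frame(snp_index = 10L, effect1 = 0,
                                          effect2 = 0.2093),
                    seed = 21)
  expect_equal(expected_trait_correlation(cfg), 0.8, tolerance = 0.01)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, config = cfg)
  expect_equal(cor(ph$trait1, ph$trait2), 0.8, tolerance = 0.05)
})

test_that("a planted QTL effect is recovered by regression on the SNP", {
  cfg <- sim_config(n_lines = 500, n_snps = 400, n_clusters = 2, fst = 0.1,
                    qtl_spec = data.frame(snp_index = 17L, effect1 = 0,
                                          effect2 = 0.5),
                    shared_factor_sd = 0, shared_structured = FALSE,
                    h2_background_1 = 0, h2_background_2 = 0,
                    noise_sd_1 = 1, noise_sd_2 = 1, seed = 13)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, config = cfg)
  xz <- scale(g$X[, 17])[, 1]
  fit <- summary(lm(ph$trait2 ~ xz))$coefficients
  expect_lt(abs(fit["xz", "Estimate"] - 0.5), 2 * fit["xz", "Std. Error"])
  # trait1 got no effect
  fit1 <- summary(lm(ph$trait1 ~ xz))$coefficients
  expect_gt(fit1["xz", "Pr(>|t|)"], 0.001)
})

test_that("insertion counts carry the planted interaction ratio", {
  # genotypes engineered so the interaction indicator is the focal allele
  n <- 2000L
  X <- cbind(rep(c(0L, 1L), each = n / 2),
             matrix(1L, n, 2))
  g <- make_geno(X)
  cfg <- sim_config(n_lines = n, n_snps = 3, n_clusters = 1, fst = 0.1,
                    insertion_baseline = 0.1,
                    insertion_interaction_log_ratio = log(30),
                    insertion_k = 2, seed = 19)
  cnt <- simulate_insertion_counts(g, focal_snp = 1L,
                                   modifier_snps = c(2L, 3L), cfg)
  m0 <- mean(cnt[1:(n / 2)]); m1 <- mean(cnt[(n / 2 + 1):n])
  ratio <- m1 / m0
  # delta-method se of the ratio from negative-binomial class variances
  v0 <- var(cnt[1:(n / 2)]) / (n / 2); v1 <- var(cnt[(n / 2 + 1):n]) / (n / 2)
  se <- ratio * sqrt(v1 / m1^2 + v0 / m0^2)
  expect_lt(abs(ratio - 30), 3 * se)

  # no interaction: class means agree
  cfg0 <- sim_config(n_lines = n, n_snps = 3, n_clusters = 1,
                     insertion_baseline = 0.5,
                     insertion_interaction_log_ratio = 0, seed = 23)
  cnt0 <- simulate_insertion_counts(g, 1L, c(2L, 3L), cfg0)
  expect_gt(t.test(cnt0 ~ rep(c(0, 1), each = n / 2))$p.value, 0.001)

  # determinism
  expect_identical(simulate_insertion_counts(g, 1L, c(2L, 3L), cfg),
                   simulate_insertion_counts(g, 1L, c(2L, 3L), cfg))
})

test_that("methylation call simulator recovers true levels", {
  feats <- data.frame(id = c("te1", "te2"), chrom = "chr1",
                      start = c(0L, 10000L), end = c(4000L, 14000L))
  calls <- simulate_methylation_calls(feats, c(0.375, 0), depth = 50,
                                      seed = 3, site_spacing = 20L)
  expect_true(all(calls$mc <= calls$total))
  expect_true(all(calls$mc[calls$feature_id == "te2"] == 0))
  w1 <- weighted_methylation(calls, feats[1, ], context = c("CG", "CHG", "CHH"))
  expect_lt(abs(w1 - 0.375), 0.02)
  expect_error(simulate_methylation_calls(feats, c(0.5, 1.5), 10, 1),
               "true levels")
  expect_error(simulate_methylation_calls(feats, c(0.5, 0.5), -1, 1),
               "depth")
})

test_that("fixture bundle round-trips and is byte-identical under one seed", {
  cfg <- sim_config(n_lines = 40, n_snps = 120, n_clusters = 2, fst = 0.2,
                    qtl_spec = data.frame(snp_index = c(5L, 50L),
                                          effect1 = c(0.4, 0),
                                          effect2 = c(0.4, 0.5)),
                    seed = 77)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  p1 <- write_fixture_bundle(cfg, d1)
  p2 <- write_fixture_bundle(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), info = nm)
  }
  # truth records every planted QTL
  truth <- yaml::read_yaml(p1[["truth"]])
  expect_equal(sort(vapply(truth$qtls, `[[`, integer(1), "snp_index")),
               c(5L, 50L))
  # matrix round trip
  g0 <- simulate_genotypes(cfg)
  snp_meta <- utils::read.delim(p1[["snps"]])
  g1 <- read_genotype_matrix(p1[["matrix"]], snp_meta[, c("id", "chrom", "pos")])
  expect_identical(unname(g1$X), unname(g0$X))
  expect_equal(g1$snps$mac, g0$snps$mac)
  # VCF round trip
  g2 <- read_genotype_vcf(p1[["vcf"]])
  expect_identical(unname(g2$X), unname(g0$X))
  expect_equal(g2$snps$pos, g0$snps$pos)
})
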