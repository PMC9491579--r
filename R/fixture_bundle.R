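#' Write a complete synthetic fixture bundle to disk
#'
#' Generates the full synthetic study from one [sim_config()] and writes it
#' as plain-text files: haploid VCF + 0/1 genotype matrix (TSV), phenotype
#' and metadata table (TSV), TE/gene annotations (BED), allc-style
#' methylation calls (TSV), an a priori gene list (text), and a YAML truth
#' file recording every planted value (QTLs, cline, interaction) so that
#' downstream recovery tests read planted truth only from this file.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_te,n_genes number of TE and gene annotations to emit.
#' @param n_apriori size of the a priori candidate gene list.
#' @param methylation_depth mean read depth of the simulated calls.
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture_bundle <- function(config, out_dir, n_te = 50L, n_genes = 200L,
                                 n_apriori = 20L, methylation_depth = 30) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  geno <- simulate_genotypes(config)
  K <- compute_kinship(geno)
  phen <- simulate_phenotypes(geno, K, config)

  # deterministic focal/modifier choice for the insertion-count fixture
  set.seed(derive_seed(config$seed, 4L))
  common <- which(geno$snps$maf > 0.2)
  focal <- common[1L]
  modifiers <- common[seq(2L, min(6L, length(common)))]
  ins <- simulate_insertion_counts(geno, focal, modifiers, config)
  phen$insertion_count <- as.integer(ins)

  # annotations: genes sit inside the SNP-covered region (their p-values
  # come from nearby SNPs); TEs are tiled disjointly beyond it, because
  # methylation phenotyping is position-based and overlapping TEs would mix
  # each other's cytosines
  set.seed(derive_seed(config$seed, 5L))
  chroms <- unique(geno$snps$chrom)
  te_width <- 2000L
  te_start0 <- max(geno$snps$pos) + 10000L
  tes <- data.frame(
    id = sprintf("AT_TE%04d", seq_len(n_te)),
    chrom = rep_len(chroms, n_te),
    start = as.integer(te_start0 +
                         ((seq_len(n_te) - 1L) %/% length(chroms)) *
                         (te_width + 500L)),
    kind = "TE", stringsAsFactors = FALSE)
  tes$end <- tes$start + te_width
  tes <- tes[, c("id", "chrom", "start", "end", "kind")]
  gch <- sample(chroms, n_genes, replace = TRUE)
  gmax <- vapply(gch, function(c0) max(geno$snps$pos[geno$snps$chrom == c0]),
                 numeric(1))
  gstart <- vapply(gmax, function(mp) sample.int(max(1, mp), 1L), numeric(1))
  genes <- data.frame(id = sprintf("AT_G%04d", seq_len(n_genes)),
                      chrom = gch, start = as.integer(gstart),
                      end = as.integer(gstart + 3000L), kind = "gene",
                      stringsAsFactors = FALSE)
  feats <- rbind(tes, genes)
  true_levels <- stats::runif(nrow(tes), 0.05, 0.8)
  calls <- simulate_methylation_calls(tes, true_levels, methylation_depth,
                                      seed = derive_seed(config$seed, 6L))
  # a priori candidates: the genes nearest each planted QTL (the true
  # regulators) padded with random genes, mirroring a curated candidate list
  qs0 <- config$qtl_spec
  near <- character(0)
  if (!is.null(qs0) && nrow(qs0)) {
    for (si in qs0$snp_index) {
      ch <- geno$snps$chrom[si]; po <- geno$snps$pos[si]
      cand <- genes[genes$chrom == ch, ]
      if (nrow(cand)) {
        d <- pmax(cand$start - po, po - cand$end, 0)
        near <- c(near, cand$id[which.min(d)])
      }
    }
  }
  near <- unique(near)
  fill <- setdiff(genes$id, near)
  apriori <- sort(c(near, sample(fill, max(0, min(n_apriori, nrow(genes)) -
                                             length(near)))))

  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    matrix = file.path(out_dir, "genotypes.tsv"),
    snps = file.path(out_dir, "snp_meta.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    bed = file.path(out_dir, "annotations.bed"),
    allc = file.path(out_dir, "allc.tsv"),
    apriori = file.path(out_dir, "apriori_genes.txt"),
    truth = file.path(out_dir, "truth.yaml"))

  write_genotype_vcf(geno, paths["vcf"])
  gm <- data.frame(line_id = geno$line_ids, cluster = geno$cluster, geno$X,
                   check.names = FALSE)
  data.table::fwrite(gm, paths["matrix"], sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(geno$snps, paths["snps"], sep = "\t", quote = FALSE)
  data.table::fwrite(as.data.frame(phen), paths["phenotypes"], sep = "\t",
                     na = "NA", quote = FALSE)
  bed <- data.frame(feats$chrom, feats$start, feats$end, feats$id, 0L, "+",
                    feats$kind)
  data.table::fwrite(bed, paths["bed"], sep = "\t", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(as.data.frame(calls), paths["allc"], sep = "\t",
                     quote = FALSE)
  writeLines(apriori, paths["apriori"])

  qs <- config$qtl_spec
  truth <- list(
    seed = config$seed,
    qtls = if (is.null(qs)) list() else lapply(seq_len(nrow(qs)), function(i) {
      list(snp_index = qs$snp_index[i], snp_id = geno$snps$id[qs$snp_index[i]],
           effect1 = qs$effect1[i], effect2 = qs$effect2[i])
    }),
    insertion = list(focal_snp = focal, modifier_snps = modifiers,
                     baseline = config$insertion_baseline,
                     log_ratio = config$insertion_interaction_log_ratio,
                     k = config$insertion_k),
    cline = list(strength = config$cline_strength,
                 snp_indices = config$cline_snp_indices,
                 snp_effect = config$cline_snp_effect),
    te_true_levels = as.list(stats::setNames(round(true_levels, 6), tes$id)),
    expected_trait_correlation = expected_trait_correlation(config))
  yaml::write_yaml(truth, paths["truth"])
  invisible(paths)
}

#' Write a haploid VCF for an inbred panel
#'
#' VCFv4.2 with one haploid GT field per line; missing genotypes as `.`.
#' REF/ALT are placeholders (`A`/`T`): only the 0/1 dosage is meaningful for
#' a simulated panel.
#'
#' @param geno a `geno_matrix`.
#' @param path output path.
#' @export
write_genotype_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=condgwas-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$line_ids), collapse = "\t")),
             con)
  gt <- t(geno$X)
  gt_chr <- matrix(as.character(gt), nrow(gt), ncol(gt))
  gt_chr[is.na(gt_chr)] <- "."
  body <- paste(geno$snps$chrom, geno$snps$pos, geno$snps$id, "A", "T", ".",
                "PASS", ".", "GT",
                apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
}

#' Read a haploid VCF into a genotype matrix
#'
#' Parses GT fields with vcfR; haploid calls (`0`/`1`) and homozygous diploid
#' calls (`0/0`, `1|1`) collapse to 0/1, anything else (including
#' heterozygotes and `.`) becomes missing.
#'
#' @param path VCF path.
#' @return a `geno_matrix` (cluster labels unknown: NA).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    ifelse(g %in% c("0", "0/0", "0|0"), 0L,
           ifelse(g %in% c("1", "1/1", "1|1"), 1L, NA_integer_))
  }
  X <- t(apply(gt, 2L, code))
  if (is.null(dim(X))) X <- matrix(X, nrow = ncol(gt))
  colnames(X) <- rownames(gt)
  rownames(X) <- colnames(gt)
  fix <- vcfR::getFIX(v)
  snps <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     mac = apply(X, 2L, snp_mac),
                     maf = apply(X, 2L, snp_maf), stringsAsFactors = FALSE)
  structure(list(X = X, snps = snps, line_ids = rownames(X),
                 cluster = rep(NA_integer_, nrow(X))),
            class = "geno_matrix")
}

#' Read a 0/1 genotype matrix TSV (as written by [write_fixture_bundle()])
#'
#' @param path TSV path with `line_id`, `cluster`, then one column per SNP.
#' @param snp_meta optional SNP metadata to attach (id, chrom, pos).
#' @return a `geno_matrix`.
#' @export
read_genotype_matrix <- function(path, snp_meta = NULL) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  line_ids <- d$line_id
  cluster <- d$cluster
  X <- as.matrix(d[, setdiff(names(d), c("line_id", "cluster")), drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- line_ids
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(id = colnames(X),
                           chrom = "chr1", pos = seq_len(ncol(X)),
                           stringsAsFactors = FALSE)
  }
  snp_meta$mac <- apply(X, 2L, snp_mac)
  snp_meta$maf <- apply(X, 2L, snp_maf)
  structure(list(X = X, snps = snp_meta, line_ids = line_ids,
                 cluster = cluster),
            class = "geno_matrix")
}
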