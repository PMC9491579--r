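#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list. Checks the schema (unknown keys are
#' rejected), fills documented defaults, and verifies that every referenced
#' input path exists. Validation problems are aggregated and reported
#' together, not one at a time. Normalization is idempotent.
#'
#' Recognized keys: `seed` (global seed; every stage seed is derived from
#' it), `out_dir`, `simulate` (sim_config overrides; mutually exclusive with
#' `inputs`), `inputs` (paths: `genotypes`, `phenotypes`, `annotations`,
#' `allc`, `apriori`), `stages` (logical toggles `phenotype`, `scan`,
#' `enrich`, `alleles`), `params` (`maf_min`, `window`, `grid_min`,
#' `grid_max`, `grid_step`, `n_perm`, `n_rotations`, `n_focal`, `refit_top`,
#' `partner_snp`).
#'
#' @param config path to a YAML file, or a list.
#' @return normalized configuration of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errors <- character(0)

  known_top <- c("seed", "out_dir", "simulate", "inputs", "stages", "params")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$out_dir)) errors <- c(errors, "missing required key: out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)

  merge_keep_null <- function(defaults, given) {
    given <- as.list(given)
    defaults[names(given)] <- given
    defaults
  }
  stages_default <- list(phenotype = TRUE, scan = TRUE, enrich = TRUE,
                         alleles = TRUE)
  st <- merge_keep_null(stages_default, config$stages)
  bad_st <- setdiff(names(st), names(stages_default))
  if (length(bad_st)) {
    errors <- c(errors, paste0("unknown stage(s): ", paste(bad_st, collapse = ", ")))
  }
  config$stages <- st

  params_default <- list(maf_min = 0.05, window = 15000L, grid_min = 1,
                         grid_max = 12, grid_step = 0.25, n_perm = 3000L,
                         n_rotations = 3000L, n_focal = 5L,
                         refit_top = 10L, partner_snp = NULL)
  pr <- merge_keep_null(params_default, config$params)
  bad_pr <- setdiff(names(pr), names(params_default))
  if (length(bad_pr)) {
    errors <- c(errors, paste0("unknown param(s): ", paste(bad_pr, collapse = ", ")))
  }
  config$params <- pr

  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim && has_inp) {
    errors <- c(errors, "provide either 'simulate' or 'inputs', not both")
  }
  if (!has_sim && !has_inp) {
    errors <- c(errors, "missing required key: one of 'simulate' or 'inputs'")
  }
  if (has_inp) {
    need <- c("genotypes", "phenotypes", "annotations", "allc", "apriori")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) {
      errors <- c(errors, paste0("inputs missing: ", paste(miss, collapse = ", ")))
    }
    for (nm in intersect(need, names(config$inputs))) {
      if (!file.exists(config$inputs[[nm]])) {
        errors <- c(errors, paste0("input path does not exist: ", nm, " = ",
                                   config$inputs[[nm]]))
      }
    }
  }
  if (has_sim) {
    ok_sim <- names(formals(sim_config))
    bad_sim <- setdiff(names(config$simulate), ok_sim)
    if (length(bad_sim)) {
      errors <- c(errors, paste0("unknown simulate key(s): ",
                                 paste(bad_sim, collapse = ", ")))
    }
  }
  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  config <- config[known_top[known_top %in% names(config)]]
  class(config) <- "pipeline_config"
  config
}

#' Run the full conditional-GWAS pipeline
#'
#' Executes, in order and subject to the stage toggles:
#' simulation/loading of the input bundle, methylation phenotyping,
#' kinship + REML, univariate and conditional association scans, candidate
#' enrichment with the genome-rotation null, and the allele analyses
#' (cumulative counts, additive fit, r^2, clinal and epistasis permutation
#' tests where the needed inputs exist). Writes per-stage TSV outputs and a
#' YAML manifest with the config hash, derived seeds, package version and
#' md5 checksums of every output, sufficient to re-run bit-identically.
#' Downstream stages fail fast with a clear error if a stage they depend on
#' is toggled off.
#'
#' @param config a `pipeline_config` (or path / list accepted by
#'   [validate_config()]).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  st <- config$stages
  if (st$enrich && !st$scan) stop("stage 'enrich' requires stage 'scan'")
  if (st$alleles && !st$scan) stop("stage 'alleles' requires stage 'scan'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t0 <- proc.time()[["elapsed"]]
  times <- c()
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    times[[nm]] <<- round(t1 - t0, 2)
    t0 <<- t1
    message(sprintf("[%s] done (%.1fs)", nm, times[[nm]]))
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- utils::modifyList(list(seed = config$seed),
                                  as.list(config$simulate))
    scfg <- do.call(sim_config, sim_args)
    fix_dir <- file.path(out_dir, "fixture")
    paths <- write_fixture_bundle(scfg, fix_dir)
    inputs <- list(genotypes = unname(paths["matrix"]),
                   snps = unname(paths["snps"]),
                   phenotypes = unname(paths["phenotypes"]),
                   annotations = unname(paths["bed"]),
                   allc = unname(paths["allc"]),
                   apriori = unname(paths["apriori"]),
                   truth = unname(paths["truth"]))
    res$sim_config <- scfg
  } else {
    inputs <- config$inputs
  }
  snp_meta <- if (!is.null(inputs$snps)) {
    data.table::fread(inputs$snps, data.table = FALSE)
  } else NULL
  geno <- read_genotype_matrix(inputs$genotypes, snp_meta = snp_meta)
  phen <- data.table::fread(inputs$phenotypes, data.table = FALSE)
  feats <- read_bed(inputs$annotations)
  calls <- read_allc(inputs$allc)
  apriori <- readLines(inputs$apriori)
  tick("load")

  # --- phenotyping ----------------------------------------------------
  if (st$phenotype) {
    tes <- feats[feats$kind == "TE", , drop = FALSE]
    lev_chg <- weighted_methylation_all(calls, tes, context = "CHG")
    lev_chh <- weighted_methylation_all(calls, tes, context = "CHH")
    pheno_tab <- data.frame(feature_id = tes$id, mCHG = lev_chg,
                            mCHH = lev_chh, row.names = NULL)
    data.table::fwrite(pheno_tab, file.path(out_dir, "te_methylation.tsv"),
                       sep = "\t")
    res$te_methylation <- pheno_tab
    res$panel_mean <- c(mCHG = line_average(lev_chg),
                        mCHH = line_average(lev_chh))
    tick("phenotype")
  }

  # --- scans ----------------------------------------------------------
  if (st$scan) {
    K <- compute_kinship(geno)
    uni <- association_scan(phen$trait2, geno, K,
                            maf_min = config$params$maf_min,
                            refit_top = config$params$refit_top)
    cond <- association_scan(phen$trait2, geno, K, covariate = phen$trait1,
                             maf_min = config$params$maf_min,
                             refit_top = config$params$refit_top)
    res$h2 <- c(trait1 = snp_heritability(zscore(phen$trait1), K),
                trait2 = snp_heritability(zscore(phen$trait2), K))
    res$scan_univariate <- uni
    res$scan_conditional <- cond
    res$bonferroni <- bonferroni_threshold(cond)
    data.table::fwrite(as.data.frame(uni),
                       file.path(out_dir, "scan_univariate.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(cond),
                       file.path(out_dir, "scan_conditional.tsv"), sep = "\t")
    tick("scan")
  }

  # --- enrichment -----------------------------------------------------
  if (st$enrich) {
    genes <- feats[feats$kind == "gene", , drop = FALSE]
    gp <- assign_gene_pvalues(res$scan_conditional, genes, apriori,
                              window = config$params$window)
    grid <- seq(config$params$grid_min, config$params$grid_max,
                by = config$params$grid_step)
    enr <- enrichment_curve(gp, grid)
    rot <- rotation_significance(gp, grid,
                                 n_rotations = config$params$n_rotations,
                                 seed = derive_seed(config$seed, 7L))
    res$gene_pvalues <- gp
    res$enrichment <- enr
    res$rotation <- rot
    data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
    data.table::fwrite(rot, file.path(out_dir, "rotation.tsv"), sep = "\t")
    tick("enrich")
  }

  # --- allele analysis ------------------------------------------------
  if (st$alleles) {
    cond <- res$scan_conditional
    top <- cond[order(cond$p_value), ]
    focal_ids <- utils::head(top$snp_id, config$params$n_focal)
    focal <- orient_alleles(cond, focal_ids)
    counts <- cumulative_counts(geno, focal)
    fit <- additive_fit(phen$trait2, counts)
    r2 <- variance_explained_r2(phen$trait2, geno, focal$snp_index)
    spec <- perm_spec(n_perm = config$params$n_perm,
                      seed = derive_seed(config$seed, 8L))
    cline <- clinal_test(geno, focal, phen$longitude, spec)
    res$focal <- focal
    res$additive <- fit
    res$r2 <- r2
    res$cline <- cline
    allele_tab <- data.frame(fit$class_means,
                             slope = fit$slope, r2 = r2,
                             cline_r = cline$observed_r,
                             cline_p = cline$p_value)
    if (!is.null(config$params$partner_snp) &&
        "insertion_count" %in% names(phen)) {
      partner <- config$params$partner_snp
      pidx <- if (is.numeric(partner)) as.integer(partner) else
        match(partner, geno$snps$id)
      epi <- epistasis_insertion_test(phen$insertion_count, geno, pidx,
                                      focal, spec)
      res$epistasis <- epi
      data.table::fwrite(epi, file.path(out_dir, "epistasis.tsv"), sep = "\t")
    }
    data.table::fwrite(allele_tab, file.path(out_dir, "alleles.tsv"),
                       sep = "\t")
    tick("alleles")
  }

  # --- manifest -------------------------------------------------------
  cfg_norm <- unclass(config)
  cfg_path <- file.path(out_dir, "config_normalized.yaml")
  yaml::write_yaml(cfg_norm, cfg_path)
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.yaml"))
  sums <- tools::md5sum(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("condgwas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stage_seconds = as.list(times),
    checksums = as.list(stats::setNames(unname(sums),
                                        sub(paste0(out_dir, "/"), "",
                                            names(sums), fixed = TRUE))))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  res$manifest <- manifest
  res$manifest_path <- manifest_path
  invisible(res)
}
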