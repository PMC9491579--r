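#' Read allc-style per-cytosine methylation calls
#'
#' Tab-separated with columns chrom, pos (1-based), strand, context
#' (CG/CHG/CHH), mc (methylated reads), total (total reads). Extra columns
#' are kept.
#'
#' @param path file path.
#' @return data frame of class `allc_table`.
#' @export
read_allc <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "strand", "context", "mc", "total")
  if (!all(need %in% names(d))) {
    stop("allc file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$mc > d$total | d$mc < 0)) stop("invalid counts: need 0 <= mc <= total")
  class(d) <- c("allc_table", "data.frame")
  d
}

#' Read feature annotations (BED)
#'
#' BED intervals are 0-based half-open; columns chrom, start, end, name
#' (feature id), and optionally score and strand. A 7th column, if present,
#' is taken as the feature kind (TE/gene).
#'
#' @param path BED file path.
#' @return data frame with `id`, `chrom`, `start`, `end`, `kind`.
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(d) < 4L) stop("BED file needs at least 4 columns (chrom,start,end,name)")
  out <- data.frame(id = d[[4L]], chrom = d[[1L]],
                    start = as.integer(d[[2L]]), end = as.integer(d[[3L]]),
                    kind = if (ncol(d) >= 7L) d[[7L]] else "TE",
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("invalid interval: start must be < end")
  out
}

#' Weighted methylation level of one feature
#'
#' Sum of methylated read counts divided by the sum of total read counts over
#' all cytosines of the requested context inside the feature. Annotation
#' intervals are 0-based half-open and call positions 1-based, so a cytosine
#' at position p belongs to the feature iff `start < p <= end`. Both strands
#' are pooled. A feature with zero total coverage is undefined and returns
#' `NA` (never 0).
#'
#' @param calls an `allc_table` (or compatible data frame).
#' @param feature one-row feature (list/data frame with `chrom`, `start`,
#'   `end`).
#' @param context one or more of `"CG"`, `"CHG"`, `"CHH"`.
#' @return fraction in `[0, 1]`, or `NA_real_` when no covered cytosine.
#' @export
weighted_methylation <- function(calls, feature, context = "CHH") {
  sel <- calls$chrom == feature$chrom &
    calls$context %in% context &
    calls$pos > feature$start & calls$pos <= feature$end
  tot <- sum(calls$total[sel])
  if (tot == 0) return(NA_real_)
  sum(calls$mc[sel]) / tot
}

#' Weighted methylation for many features at once
#'
#' Same statistic as [weighted_methylation()], computed for every feature by
#' a grouped aggregation; features with zero coverage get `NA`.
#'
#' @param calls an `allc_table`.
#' @param features feature data frame (`id`, `chrom`, `start`, `end`).
#' @param context context filter.
#' @return named numeric vector of per-feature levels (NA where undefined).
#' @export
weighted_methylation_all <- function(calls, features, context = "CHH") {
  d <- calls[calls$context %in% context, , drop = FALSE]
  lev <- rep(NA_real_, nrow(features))
  names(lev) <- features$id
  if (!nrow(d)) return(lev)
  for (i in seq_len(nrow(features))) {
    sel <- d$chrom == features$chrom[i] &
      d$pos > features$start[i] & d$pos <= features$end[i]
    tot <- sum(d$total[sel])
    if (tot > 0) lev[i] <- sum(d$mc[sel]) / tot
  }
  lev
}

#' Per-line average methylation over features
#'
#' Unweighted mean over all features with a defined (covered) level;
#' undefined features are excluded, not zero-filled. Mirrors per-line trait
#' construction from "all transposons with at least one mapped read".
#'
#' @param per_feature_levels numeric vector, `NA` = undefined.
#' @return mean of the defined values.
#' @export
line_average <- function(per_feature_levels) {
  ok <- !is.na(per_feature_levels)
  if (!any(ok)) stop("all feature levels undefined; no covered feature")
  mean(per_feature_levels[ok])
}

#' Classify transposons into RdDM- and CMT2-target sets
#'
#' A TE is CMT2-targeted when wild-type minus cmt2-mutant methylation exceeds
#' `threshold` (strictly), and RdDM-targeted when wild-type minus
#' drm1/drm2-mutant methylation exceeds it. By default the sets are disjoint:
#' a TE exceeding the threshold in both comparisons is assigned to the class
#' with the larger difference (ties go to CMT2); set `allow_overlap = TRUE`
#' to keep it in both. Features with an undefined level in any of the three
#' inputs are excluded.
#'
#' @param wt_levels,cmt2_levels,drm1drm2_levels named per-feature methylation
#'   fractions on a shared id space (`NA` = undefined).
#' @param threshold strict differential-methylation threshold (default 0.1).
#' @param allow_overlap keep doubly-exceeding TEs in both sets.
#' @return list of class `te_target_sets` with `rddm_ids`, `cmt2_ids`,
#'   `threshold`.
#' @export
classify_te_targets <- function(wt_levels, cmt2_levels, drm1drm2_levels,
                                threshold = 0.1, allow_overlap = FALSE) {
  ids <- intersect(intersect(names(wt_levels), names(cmt2_levels)),
                   names(drm1drm2_levels))
  wt <- wt_levels[ids]; cm <- cmt2_levels[ids]; dr <- drm1drm2_levels[ids]
  ok <- !is.na(wt) & !is.na(cm) & !is.na(dr)
  ids <- ids[ok]; wt <- wt[ok]; cm <- cm[ok]; dr <- dr[ok]
  d_cmt2 <- wt - cm
  d_rddm <- wt - dr
  is_c <- d_cmt2 > threshold
  is_r <- d_rddm > threshold
  if (!allow_overlap) {
    both <- is_c & is_r
    # assign doubly-exceeding TEs to the larger difference; ties to CMT2
    to_c <- both & d_cmt2 >= d_rddm
    is_c <- (is_c & !both) | to_c
    is_r <- (is_r & !both) | (both & !to_c)
  }
  structure(list(rddm_ids = ids[is_r], cmt2_ids = ids[is_c],
                 threshold = threshold),
            class = "te_target_sets")
}

#' Mutant-vs-wild-type differential methylation calls
#'
#' Per feature, a two-tailed Welch two-sample t-test between replicate
#' methylation levels of the two groups; a feature is flagged when
#' `p < alpha` and the absolute mean difference exceeds `delta`. Features
#' with fewer than two finite replicates in either group are skipped with a
#' warning.
#'
#' @param group_a_levels,group_b_levels numeric matrices, features x
#'   replicates, with shared rownames.
#' @param alpha significance gate (default 0.01).
#' @param delta absolute mean-difference gate (default 0.1).
#' @return data frame: `feature_id`, `mean_diff`, `p_value`, `flagged`,
#'   `skipped`.
#' @export
differential_methylation_test <- function(group_a_levels, group_b_levels,
                                          alpha = 0.01, delta = 0.1) {
  ids <- intersect(rownames(group_a_levels), rownames(group_b_levels))
  res <- data.frame(feature_id = ids, mean_diff = NA_real_,
                    p_value = NA_real_, flagged = FALSE, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    a <- group_a_levels[ids[i], ]; a <- a[is.finite(a)]
    b <- group_b_levels[ids[i], ]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      res$skipped[i] <- TRUE
      next
    }
    res$mean_diff[i] <- mean(a) - mean(b)
    res$p_value[i] <- tryCatch(
      stats::t.test(a, b, var.equal = FALSE)$p.value,
      error = function(e) NA_real_)
    res$flagged[i] <- isTRUE(res$p_value[i] < alpha) &&
      abs(res$mean_diff[i]) > delta
  }
  if (any(res$skipped)) {
    warning(sum(res$skipped), " feature(s) skipped: fewer than 2 replicates")
  }
  res
}
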