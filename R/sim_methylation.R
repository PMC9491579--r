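#' Simulate per-cytosine methylation calls over annotated features
#'
#' Produces allc-style records for a set of annotated features (transposons
#' or genes). Cytosine positions are laid out on a regular grid inside each
#' feature's 0-based half-open interval; per site the total read count is
#' Poisson(`depth`) (zero-coverage sites are emitted with zero counts, as a
#' bisulfite caller would) and the methylated count is Binomial(total,
#' feature level). Context labels are drawn from `context_probs`; the true
#' level of a feature applies to all of its contexts, which keeps the truth
#' recoverable separately per context.
#'
#' @param features data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `kind`.
#' @param true_levels numeric vector in `[0, 1]`, one per feature.
#' @param depth mean read depth (Poisson), must be `>= 0`.
#' @param seed integer seed.
#' @param site_spacing base pairs between simulated cytosines (default 20).
#' @param context_probs named probabilities for `CG`, `CHG`, `CHH`.
#' @return data frame of class `allc_table` with columns `chrom`, `pos`
#'   (1-based), `strand`, `context`, `mc`, `total`, `feature_id`.
#' @export
simulate_methylation_calls <- function(features, true_levels, depth, seed,
                                       site_spacing = 20L,
                                       context_probs = c(CG = 0.2, CHG = 0.3,
                                                         CHH = 0.5)) {
  stopifnot(is.data.frame(features), nrow(features) == length(true_levels))
  if (any(true_levels < 0 | true_levels > 1)) {
    stop("true levels must be in [0, 1]")
  }
  if (depth < 0) stop("depth must be non-negative")
  set.seed(seed)
  recs <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    # 1-based positions p with start < p <= end
    pos <- seq.int(f$start + 1L, f$end, by = site_spacing)
    ns <- length(pos)
    total <- stats::rpois(ns, depth)
    mc <- stats::rbinom(ns, total, true_levels[i])
    recs[[i]] <- data.frame(
      chrom = f$chrom, pos = as.integer(pos),
      strand = sample(c("+", "-"), ns, replace = TRUE),
      context = sample(names(context_probs), ns, replace = TRUE,
                       prob = context_probs),
      mc = mc, total = total, feature_id = f$id,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("allc_table", "data.frame")
  out
}
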