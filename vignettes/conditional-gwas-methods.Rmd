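---
title: "Models and design choices in condgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in condgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`condgwas` implements a conditional-GWAS analysis chain for pairs of
strongly correlated quantitative traits, with transposon CHG/CHH
methylation in a selfing plant panel as the motivating system. This
vignette records the models, the tunable parameters, the synthetic-data
design, and the numerical choices, so that a reader can judge what the
shipped tests do and do not demonstrate.

## The mixed model and the conditional scan

Association testing uses the kinship mixed model

$$Y = \alpha L + \beta X + g + e,
\qquad g \sim N(0, \sigma_g^2 K),\ e \sim N(0, \sigma_e^2 I),$$

where $Y$ is the phenotype, $L$ an optional correlated-trait covariate,
$X$ the tested SNP, and $K$ the identity-by-state kinship matrix (fraction
of SNPs at which two lines carry the same genotype, computed on all SNPs —
the MAF filter belongs to the scan, not to the relatedness estimate).
$Y$, $L$ and $X$ are z-scored over the included lines, so $\beta$ is in
correlation-scale units. The univariate model takes $\alpha = 0$; the
conditional model includes the second trait as $L$. Only SNPs with
MAF strictly above 5% are tested, and the genome-wide threshold is
Bonferroni over the tested count.

REML estimation profiles the restricted likelihood over the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ after a single eigendecomposition of $K$:
100 log-spaced grid points on $[10^{-5}, 10^5]$, refined by Brent
optimization around the best grid point, ties broken toward smaller
$\delta$. Pseudo-heritability is $h^2 = 1/(1+\delta)$, which is exact for a
unit-diagonal $K$. Per-SNP tests hold $\delta$ at the null-model optimum
(the EMMAX approximation) and compute a two-sided Wald $t$ with $n-p$
degrees of freedom via weighted regression in the eigenbasis; this is
algebraically identical to explicit GLS with
$V = \sigma_g^2 K + \sigma_e^2 I$, which the test suite verifies against a
brute-force implementation to $10^{-8}$. Because the variance components
are estimated and then treated as known, null scans are slightly
*conservative* under strong population structure (the spurious genetic
variance fitted to noise inflates every test's denominator); the shipped
calibration experiment quantifies the rejection rate under mild structure,
where the effect is within Monte-Carlo error, and the safe direction of the
bias is worth noting for stronger structure.

### Two-stage scan: why the top hits are refitted exactly

A strongly population-structured causal SNP poses a subtle problem for the
EMMAX approximation: its own variance contribution is structured, so the
*null* model (which excludes it) absorbs part of it into
$\hat\sigma_g^2$, inflating the denominator of its own test. For weakly
structured SNPs this is negligible; for a clinal major-effect allele it can
cost an order of magnitude in $-\log_{10} p$. `association_scan()` therefore
supports a two-stage procedure (`refit_top = 10`): after the fast genome
pass, the strongest hits are refitted with the SNP in the fixed effects and
$\delta$ re-estimated per SNP. The exact single-SNP model has no
self-absorption, and the refit reuses the cached eigendecomposition, so the
cost is ten cheap REML profiles rather than ten eigendecompositions. An
`exact = TRUE` flag refits every SNP for validation on small problems.

## The multi-trait mixed model

The bivariate model stacks the two z-scored traits with covariance
$V_g \otimes K + V_e \otimes I$. The eigenbasis of $K$ block-diagonalizes
this into $n$ independent $2\times2$ blocks $C_i = V_g \lambda_i + V_e$, so
the restricted likelihood costs $O(n)$ per evaluation. $V_g, V_e$ are
estimated under the no-SNP null by Nelder–Mead over their Cholesky factors
(6 parameters, 5 deterministic multi-starts, relative tolerance $10^{-8}$),
which keeps both matrices positive semi-definite by construction; the test
suite checks the optimum against a dense $2n \times 2n$ oracle. Per SNP,
trait-specific effects $(\beta_1, \beta_2)$ give three Wald tests: *any*
(2 df), *common* ($\beta_1 = \beta_2$ constrained fit, 1 df) and
*specific* ($\beta_1 - \beta_2 = 0$, 1 df). When the two traits are
numerically identical the difference contrast has zero variance; the
specific statistic is defined as identically zero and the common test
reduces to the univariate scan, rather than letting a numerically singular
system produce noise.

For a single-trait QTL the common and specific contrasts have *equal*
noncentrality when the traits are independent; the decomposition is
informative precisely when the traits are strongly positively correlated
(the difference contrast then has small variance), which is the regime the
package targets and the regime its tests exercise.

## Enrichment, FDR upper bound, genome rotation

Each gene is assigned the minimum p-value among tested SNPs within 15 kb of
its annotated boundaries (gene-body SNPs included; ties break to the
smaller position; genes with no SNP in the window are excluded from both
numerator and denominator). With $x_p$ the fraction of a priori candidate
genes with assigned p-value strictly below $p$ and $y_p$ the same fraction
among the remaining genes, enrichment is $x_p/y_p$ and $y_p/x_p$ (clipped
to $[0,1]$) is an upper bound on the FDR within the candidate set, obtained
by assuming every background association is false. The window is measured
from gene boundaries rather than midpoints or TSS — the natural reading of
"upstream and downstream" — and the default grid spans $-\log_{10} p$ from
1 to 12 in steps of 0.25.

Significance uses circular genome rotation: all scored genes are ordered
along the genome, and the candidate-membership vector is shifted by a
uniform random offset (3000 draws by default), preserving both the p-value
landscape and its spatial autocorrelation. The permutation p-value carries
the $+1$ correction, $(1 + \#\{\text{rot} \ge \text{obs}\})/(R+1)$, so it
is never zero. Rotations where the background fraction is zero count as
infinitely enriched; an all-candidate membership vector is invariant and
yields $p = 1$.

## Frequency-matched permutation tests

The cumulative-allele analyses compare an observed statistic against the
same statistic computed on random SNP sets that preserve allele
frequencies: by default each matched SNP must have exactly the focal SNP's
minor allele count (`exact-mac`), with a MAF-bin fallback (half-width
0.01). Matching preserves orientation: the matched SNP contributes the
allele on the same side of the frequency spectrum as the focal decreasing
allele. The clinal and LD tests are two-sided on a Pearson correlation; the
insertion-count test is one-sided (greater) per cumulative-count class,
with classes defined as exactly $k$ decreasing alleles (a $\ge k$ mode is
available); empty classes are reported as NA, never zero-filled. The choice
of the class mean as the insertion statistic is the simplest summary
consistent with plotting discrete genotype classes; it is configurable in
principle and documented here because no stronger convention exists.

## The synthetic panel

The generator is the package's study-conditions contract; its defaults are
chosen once to emulate the statistical structure the analysis assumes.

* **Genotypes**: haploid-equivalent 0/1 (a selfing species; no
  heterozygotes), Balding–Nichols demes — ancestral frequency uniform on
  $[0.05, 0.95]$, per-deme frequencies Beta-distributed with divergence
  `fst`, default five demes at $F_{st} = 0.3$; an optional stepping-stone
  mode drifts demes sequentially for a smoother kinship spectrum, and an
  optional block-copy LD mode (block length 10, flip rate 0.05) provides
  locally correlated markers. Missing data by random masking.
* **Traits**: planted QTL effects on z-scored genotype columns (so
  `effect`$^2$ is variance contributed), a unit-variance shared factor
  (structured — drawn with covariance $K$ — by default, because the shared
  CHH/CHG variation in real panels is heritable), trait-specific polygenic
  backgrounds, and Gaussian noise. Structured draws use the centered
  kinship rescaled to unit mean diagonal: the IBS baseline is a common
  shift with no cross-sectional variance, and without the rescaling a
  nominal unit-variance factor would have far less than unit variance
  across lines.
* **Geography**: longitude is a unit-variance mixture of the z-scored
  ancestry score (`cline_strength`), optionally a direct loading of the
  cumulative allele count at designated SNPs (`cline_snp_effect`, used to
  plant a cline at focal loci over and above the ancestry-wide cline), and
  noise, mapped to $[-20, 100]$ degrees.
* **Insertions**: negative-binomial counts whose log-mean jumps by
  `insertion_interaction_log_ratio` (default $\log 30$) in lines carrying
  the focal alternative allele plus at least `insertion_k = 2` modifier
  alleles.
* **Methylation calls**: cytosines on a regular grid within each feature,
  Poisson total depth (zero-coverage sites emitted), binomial methylated
  counts at the feature's true level. TE annotations in the fixture bundle
  are tiled disjointly because phenotyping is position-based and
  overlapping TEs would mix each other's cytosines.

What the generator does **not** emulate: realistic LD decay and
recombination maps, site-frequency spectra under selection, context-
specific methylation landscapes within elements, bisulfite conversion
error, or shared sequencing artefacts. Passing tests therefore demonstrate
the statistical machinery under the assumed covariance structure, not
robustness to every failure mode of real bisulfite data.

### The conditional-power architecture

`sim_conditional_architecture()` fixes the regime in which conditional GWAS
should beat univariate GWAS: 800 lines, 10,000 SNPs, ten demes at
$F_{st} = 0.3$; trait 1 is a unit-variance structured shared factor plus
noise (sd 0.2); trait 2 is $0.9\times$ the shared factor plus a
trait-2-specific QTL plus noise (sd 0.6026). Two constraints pin the free
parameters: the expected trait correlation is 0.8, and the QTL explains 10%
of the conditional variance of trait 2 given trait 1, which forces the QTL
effect to 0.2093 sd units. The QTL is planted at the common SNP whose
between-deme variance share is closest to 0.8, the way real trans-regulator
alleles of methylation are strongly clinal. Under the univariate model the
scan denominator is dominated by the structured shared factor
($\hat\sigma_g^2 \approx 0.65$ of the trait variance), so a
cluster-aligned SNP is heavily absorbed; conditioning on trait 1 removes
that component, and the two-stage refit removes the residual
self-absorption. In the shipped experiment
(`conditional_power_experiment()`, 20 replicates) the conditional scan
places the planted QTL first and past Bonferroni in essentially every
replicate while the univariate scan exceeds it rarely.

### Fixture sizes used by the tests

The validation suite scales the study down so it runs on one CPU in
minutes: oracle equivalence at $n = 25$; calibration at $n = 300$ with
1000 SNPs and 20 permuted-phenotype scans; heritability recovery at
$n = 500$ over 20 replicates (one fresh 25-deme, $F_{st} = 0.5$ panel per
replicate — a deliberately information-rich design in which the REML
profile is well identified and the estimator shows no boundary collapses);
genetic-correlation recovery from 5 bivariate fits at $n = 500$; the power
experiment at full $800 \times 10{,}000$ over 20 replicates; permutation
tests at $n = 900$ with 3000 matched sets. The analysis scripts use a
$300 \times 4000$ panel with 2 kb marker spacing so that a 15 kb gene
window is small relative to a chromosome.

## Numerical conventions and degenerate inputs

* Annotation intervals are 0-based half-open; allc positions 1-based; a
  cytosine belongs to a feature iff $\mathrm{start} < p \le \mathrm{end}$.
  Both strands are pooled.
* Zero-coverage features are undefined (`NA`) and excluded from per-line
  averages — never counted as zero. Per-line averages are unweighted over
  covered TEs; whether the source pipelines weighted by length or coverage
  is not documented anywhere we could find, and unweighted is the
  convention adopted here.
* A TE whose wild-type-minus-mutant difference exceeds the 0.1 threshold in
  both mutants is assigned to the larger difference (ties to CMT2);
  `allow_overlap = TRUE` keeps it in both sets. The threshold is strict:
  a difference of exactly 0.1 does not classify.
* Missing genotypes: pairwise exclusion in kinship; per-SNP mean imputation
  (then z-scoring) in scans — the standard choice for inbred panels with
  low missingness.
* A SNP collinear with the fixed effects gets $p = 1$ and a flag; a
  covariate identical to the phenotype leaves no residual information and
  every SNP gets $p = 1$; a constant covariate is an error.
* Permutation p-values always carry the $+1$ correction and are therefore
  bounded below by $1/(R+1)$.
* All generators are deterministic under `seed`; multi-stage runs derive
  per-stage seeds arithmetically from one global seed, and the pipeline
  manifest records the config hash and output checksums.

## Known limitations

The scan tests a single variance-component model; multi-component or
dominance models are out of scope. The MTMM handles exactly two traits.
The enrichment machinery assumes genes can be linearly ordered along
chromosomes and that the candidate list is small relative to the genome.
The two-stage refit corrects proximal self-absorption of the tested SNP
but not proximal contamination among *distinct* linked causal loci
(leave-one-chromosome-out kinship would; it is not implemented). Estimated
genetic correlations from the bivariate REML are mildly biased toward
stronger correlation at these sample sizes (documented by the recovery
tests' tolerance), a known property of boundary-respecting REML in small
panels.
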