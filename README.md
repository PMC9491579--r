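# condgwas

Conditional genome-wide association for pairs of strongly correlated
quantitative traits, built for the population epigenetics setting where it
matters most: natural variation of transposon DNA methylation in selfing
plant panels. CHG and CHH methylation of transposons are so tightly coupled
(through shared silencing pathways and shared population structure) that a
univariate scan of one context is dominated by variation belonging to the
other. Scanning one trait while including the other as a fixed covariate —
conditional GWAS — strips away the shared component and exposes the
trait-specific regulators.

The package provides the full analysis chain as reusable, tested functions:

* **Methylation phenotyping** — weighted methylation levels per transposon
  from allc-style per-cytosine calls (`sum(mc)/sum(total)` over a feature's
  cytosines), per-line averages over covered transposons, RdDM/CMT2 target
  classification from mutant differentials (strict 0.1 rule), and the
  Welch-test + effect-size rule for mutant-vs-wild-type calls.
* **Mixed-model association** — identity-by-state kinship, REML variance
  components and SNP-heritability for the model
  `Y = αL + βX + g + e`, `var(Y) = σg²K + σe²I`
  (Y, L, X z-scored; univariate scans take α = 0), EMMAX-style scans with
  an exact per-SNP REML refit of the top hits, Bonferroni thresholds over
  the MAF > 5% SNP set, and a bivariate multi-trait mixed model
  (`Vg ⊗ K + Ve ⊗ I`) decomposing SNP effects into *any* (2 df), *common*
  (shared, 1 df) and *specific* (trait-differential, 1 df) tests.
* **Candidate-gene enrichment** — each gene takes the strongest association
  within 15 kb; with `x_p` the fraction of a priori candidates below a
  p-value threshold and `y_p` the background fraction, enrichment is
  `x_p / y_p` and `y_p / x_p` is an upper bound on the FDR within the
  candidate set; significance by circular genome rotation of the candidate
  labels.
* **Allele analyses** — orientation of trait-decreasing alleles, per-line
  cumulative allele counts with an additive fit and jointly explained
  variance (r²), and permutation tests against 3000 allele-frequency-matched
  SNP sets for geographic clines, inter-locus LD, and epistatic effects on
  transposon insertion counts (negative-binomial mobilization bursts in
  specific multi-locus genotype classes).
* **Synthetic panel generator** — Balding–Nichols island or stepping-stone
  structured inbred genotypes, two correlated traits built from planted
  QTLs, a shared structured factor, polygenic backgrounds and noise, an
  ancestry-correlated longitude cline, simulated per-cytosine methylation
  calls, and insertion counts with a planted genotype × genotype
  interaction. Every planted value is written to a truth file, so the whole
  pipeline is testable offline.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
panel (300 lines x 4000 SNPs, five ancestry clusters, one shared QTL and
five trait-2-specific QTLs that also load on longitude):

```sh
Rscript analysis/01_simulate.R     # write the fixture bundle
Rscript analysis/02_phenotype.R    # per-TE weighted methylation
Rscript analysis/03_scan.R         # kinship, h2, univariate + conditional scans
Rscript analysis/04_enrichment.R   # a priori enrichment, FDR bound, rotation
Rscript analysis/05_alleles.R      # cumulative alleles, cline, epistasis
```

`03_scan.R` prints, for this panel:

```
SNP-heritability: trait1 0.93, trait2 0.87
Bonferroni threshold (3607 SNPs): p < 1.39e-05
QTL snp000400 (effect1 0.40, effect2 0.35): univariate -log10 p = 5.84, conditional = 0.12
QTL snp000706 (effect1 0.00, effect2 0.30): univariate -log10 p = 2.07, conditional = 5.08  [genome-wide significant]
QTL snp001500 (effect1 0.00, effect2 0.45): univariate -log10 p = 6.45, conditional = 14.02  [genome-wide significant]
QTL snp002200 (effect1 0.00, effect2 0.30): univariate -log10 p = 4.45, conditional = 7.54  [genome-wide significant]
QTL snp002600 (effect1 0.00, effect2 0.40): univariate -log10 p = 4.01, conditional = 6.53  [genome-wide significant]
QTL snp003400 (effect1 0.00, effect2 0.35): univariate -log10 p = 2.46, conditional = 5.80  [genome-wide significant]
```

The pattern is the method's point: the QTL shared by both traits
(snp000400) vanishes once the correlated trait is controlled for, while
every trait-2-specific QTL moves past genome-wide significance.
`04_enrichment.R` reports an 18-fold peak enrichment of the a priori
candidate genes (FDR bound 0.056, genome-rotation p = 0.0073), and
`05_alleles.R` tallies trait-decreasing alleles per line (additive slope
-0.62 per allele, joint r2 = 0.30), recovers the planted longitude cline
(r = 0.42, permutation p = 3e-4 against frequency-matched SNP sets), and
shows transposon insertion counts elevated only in lines combining the
partner-locus allele with two or more decreasing alleles.

A YAML-driven wrapper over the same stages is available as
`validate_config()` / `run_pipeline()`, which also writes a manifest with
seeds and output checksums for bit-identical re-runs.

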