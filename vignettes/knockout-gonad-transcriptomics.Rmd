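---
title: "Methods: knockout gonad transcriptome analysis on synthetic allotetraploid data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout gonad transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadtx)
```

## Scope and design

`gonadtx` analyzes gonad transcriptomes of knockout versus wildtype
individuals in an allotetraploid frog, where every autosomal gene exists as
two homeologs on the L ("large") and S ("small") subgenomes and a
female-specific gene (a *dm-w* analog, a partial duplicate of *dmrt1.S*)
triggers ovarian differentiation. The analyses answer three questions per
knockout line and sex: which genes respond to the knockout, whether the
response is concentrated in one subgenome, and whether the knockout
transcriptome shifts along the male–female axis (masculinization or
feminization).

Raw sequencing data are deliberately out of scope. All pipeline stages
consume gene × sample count matrices, and a synthetic-data generator with
known ground truth provides those matrices. This makes every stage testable
by construction: calibration claims (FDR control, permutation type-I error)
are checked against simulations whose truth is known, and closed-form
statistics are checked against independent oracles.

## The synthetic-data generator

`simulate_counts()` draws negative-binomial counts under

mean = baseline × 2^(sex effect) × 2^(knockout effect) × 2^(lane effect) × library-size factor,

with variance μ + φμ². Defaults and rationale:

* **Design**: the 42-tadpole two-line layout of `tadpole_design()` —
  *dmrt1.L* line 5 WT M / 3 WT F / 6 KO M / 6 KO F in one sequencing run;
  *dmrt1.S* line 6 WT M / 6 WT F / 3 KO M / 7 KO F split over two runs.
  These are the study conditions, fixed.
* **n_genes = 10,000**: the order of magnitude of genes surviving an
  abundance filter in a tadpole gonad transcriptome, kept at a size where a
  full pipeline run takes about a minute.
* **prop_subgenome_L = 0.57**: the genome-wide fraction of protein-coding
  genes on the L subgenome.
* **Baseline means** log-uniform on [5, 500] counts — a plausible
  post-filter expression range; the filter itself is exercised separately.
* **Dispersion trend φ = 1/μ + 0.05**: a typical bulk RNA-seq shape —
  Poisson-dominated noise at low counts, ~22% biological CV at high counts.
  The study does not report dispersions; these are plausibility defaults,
  not fidelity claims.
* **Effects**: 200 sex-biased and 300 knockout-dysregulated genes at
  |log2FC| = 1.5 with random signs. Magnitudes are chosen to be detectable
  but not trivial at n = 3–7 per group.
* **Female marker**: one gene with mean 20 in females and a structural zero
  in males. The low mean allows occasional stochastic zeros in a female,
  matching the qualitative "detected in almost all females" pattern; male
  counts are exactly zero.
* **Lane effect**: +0.5 log2 units on a random half of genes in the second
  sequencing run. The real lane effect is uncharacterized; this is the
  minimal confounder that makes the lane covariate consequential.
* **Library-size factors** are supplied explicitly (a fixed log-spaced
  0.7–1.4 spread by default) rather than drawn, so normalization recovery is
  exactly testable.
* **panel_ko_copy_sex** is a positive-control switch: panel genes receive a
  knockout effect identical to their sex effect, which should drive the
  masculinization test to significance. It exists for validation only.

What the generator does **not** emulate: isoform structure, gene–gene
correlation, outlier samples, GC/length biases, and homeolog expression
correlation between L and S copies. Passing tests therefore demonstrate
internal correctness and calibration under a clean NB world, not performance
on any particular real dataset.

`simulate_histology()` draws per-testis sperm-pixel proportions from Beta
distributions (mean m, concentration c ⇒ shapes mc, (1−m)c) and sperm-head
lengths from normals, for exercising the histology statistics.

## Count filtering

`low_count_filter()` removes genes whose mean count over all supplied
samples is strictly below 2 (a mean of exactly 2.0 is retained: "fewer than
two reads per individual" read literally). The original study does not say
whether the filter was applied per line or across all 42 samples; the
pipeline filters after subsetting to one line, since each line's analysis is
self-contained. The sex-related panel is exempt: the sexualization test runs
on the unfiltered matrix.

## The differential-expression engine

The study used two external tool chains; this package substitutes one
self-contained NB GLM stage run under two configurations, because exact
numerical replication of external tools is neither possible from the
printed record nor the point — calibration is.

* **Normalization**: median-of-ratios size factors (reference = genes
  positive in every sample, falling back to genes positive in ≥90% of
  samples), rescaled to geometric mean 1.
* **Dispersion**: per-gene method-of-moments max((var − mean)/mean², 10⁻⁸)
  on normalized counts, then shrunk toward a least-squares a/μ + b trend.
  Engine A uses shrinkage weight 0.5 (gene-wise information retained);
  engine B uses weight 1 (trend-only), the analog of trended-dispersion
  practice. Earlier, unshrunk gene-wise estimates were considered for B but
  have very little power at n ≈ 6 per group; trend-only is the more faithful
  second route. The floor 10⁻⁸ guarantees positivity.
* **Test**: per-gene NB GLM (fixed dispersion, log-size-factor offset,
  design ~ lane + group where a line spans two runs), Wald statistic of the
  contrast coefficient against N(0, 1), no independent filtering, BH
  adjustment, significance at q < 0.10. Complete separation (one group all
  zero) caps |log2FC| at 30 and flags the gene; a failed fit contributes
  p = 1 rather than silently disappearing from the BH universe.

The Wald/N(0,1) reference is mildly anti-conservative at these sample sizes
in theory; the null simulations in the test suite measure the realized
false-discovery proportion directly rather than assuming it.

## Consensus, sex-bias intersection, subgenome bias

`consensus_de()` reports calls significant in both engine runs, mirroring
the study's practice of interpreting results consistent across approaches.
`sexbias_intersection()` reports the count and percentage of significant
genes that appear in the union of supplied sex-biased sets (with a per-set
breakdown, since "biased in at least one comparison" and "biased in this
comparison" are both legitimate readings). `subgenome_proportion()` adds an
exact two-sided binomial test (minimum-likelihood method) of the L fraction
against 0.57 — the original comparison is descriptive; the test makes it
assertable.

## The sexualization permutation test

The core bespoke statistic. Choices that the verbal description leaves
open, and how they were fixed:

* **Ratio definition**: log2 of group means of normalized counts with
  pseudocount 0.5 in numerator and denominator. Normalized, because library
  size would otherwise leak into both ratio vectors; pseudocount, because
  unfiltered genes can have zero means.
* **Outlier exclusion**: 1.5×IQR fences with type-7 (linear interpolation)
  quartiles — fence positions depend on the quartile convention, so it is
  pinned and tested. Exclusion is joint: a gene flagged in either vector is
  dropped from both, so the correlation uses a common gene set. Below 4
  values the mask warns and flags nothing.
* **Permutation pool**: all genes of the (unfiltered) matrix except the
  panel, since the panel itself skips abundance filtering. Each replicate
  redraws the panel-sized gene set, recomputes both ratio vectors, reapplies
  the outlier mask, and recomputes Spearman's ρ — so the null distribution
  reflects the entire procedure, not just the correlation.
* **One-sided p with the +1 correction**: p = (1 + #{ρ_null ≥ ρ_obs})/(n_perm + 1)
  for masculinization (female knockouts), lower tail for feminization (male
  knockouts). p is never exactly 0 and lies on the k/(n_perm+1) grid.
* **n_perm = 1000** by default, matching the study; an `exhaustive` mode
  enumerates every pool subset on tiny instances so the sampled p can be
  validated against a brute-force oracle.

Both ratio vectors share the same-sex wildtype group, so their sampling
noise is positively correlated for every gene; the permutation null absorbs
this because random genes share the same structure. This is exactly why the
null is built from recomputed ratios rather than a parametric reference.

## Histology statistics

Units of analysis are testes, not individuals (the study mixes one testis
from each of three individuals with four testes from two individuals); the
within-individual correlation in the heterozygote comparison is noted, not
modeled. Summary-statistic input reconstructs SD as SE·√n, so printed
tables are usable directly; raw-value and summary input produce identical
results by construction, which the suite asserts. Reconstructions of
printed p-values from one-decimal summaries are expected only within ±0.02.
Label masks use 0 = background, 1 = non-sperm tissue, 2 = sperm; producing
masks from images is out of scope.

## Numerical choices and degenerate inputs

* BH via the standard step-up (`stats::p.adjust`), verified against a
  brute-force implementation in the tests.
* Spearman's ρ as Pearson on mean ranks; zero rank variance returns NA
  rather than a fabricated value.
* Zero pooled variance with equal means in the t-test returns p = 0.5,
  flagged `degenerate`.
* All-zero count matrices, empty sample groups, missing contrast levels,
  negative or non-integer counts, and pools smaller than the panel raise
  errors early with the offending identifiers.
* Every stochastic step (generator, permutations, pipeline) takes an
  explicit integer seed; the pipeline derives per-contrast permutation
  seeds as `seed + 1000·k`, and reruns are byte-identical.

## Problem sizes used in the validation suite

Simulation-backed checks run at sizes chosen to give stable Monte-Carlo
estimates quickly: marginal-mean recovery at 10,000 genes × 20 samples;
null FDR control over 20 seeds of 2000 genes at 6 vs 6; sexualization
type-I calibration over 200 null datasets of 1000 genes with 199
permutations each; the enumeration oracle on a 12-gene pool with a 3-gene
panel (220 subsets). The full pipeline examples use the 42-sample design at
10,000 genes with 1000 permutations.

## Known limitations

* The DE engine is a calibrated stand-in, not a reimplementation of any
  specific published tool; its numbers are not expected to match external
  software gene-by-gene.
* Dispersion and library-size defaults are plausibility choices; the study
  does not print the quantities needed to match them.
* The subgenome test treats genes as independent Bernoulli draws, ignoring
  homeolog pairing.
* The sexualization test's power depends on panel composition; with the
  default random panel the positive-control mode is the only configuration
  with a guaranteed signal.
* Sperm-head statistics from printed summaries cannot be fully verified:
  the number of heads measured is not printed, so the printed P = 0.003 and
  d = 2.55 are not jointly recoverable; U3 is evaluated at the printed d.
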