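---
title: "Comparative polygenic risk between admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative polygenic risk between admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

admixrisk asks a simple population-genetic question with careful controls:
do two population samples carry systematically different burdens of known
disease risk alleles, and is that difference structured by genetic
ancestry? The motivating setting is a contrast between two admixed Latin
American populations — an Afro-Latino population with predominantly
African ancestry and a Mestizo population with predominantly European
ancestry — scored over a catalog-derived set of type 2 diabetes risk SNPs.
Everything in the package runs on synthetic genotypes with known ground
truth, so each stage of the analysis is testable end to end without any
restricted-access data.

```{r setup, message = FALSE}
library(admixrisk)
```

## The model of the data

The simulator is the package's definition of the study conditions, and all
of its defaults are fixed once:

* **Ancestral differentiation.** Each SNP has an ancestral frequency
  `p0 ~ Uniform(0.05, 0.95)`; the truncated support keeps every simulated
  SNP polymorphic, which the odds-ratio machinery downstream needs.
  Ancestral population *k*'s frequency is a Balding–Nichols draw: a Beta
  variate with mean `p0` and variance `F_k p0 (1 - p0)`. The default
  fixation indices are `F = (0.15, 0.15, 0.20)` for the African, European
  and Native American ancestral populations — typical continental-scale
  differentiation, with the Native American component slightly higher to
  reflect its stronger historical bottlenecks. These are modelling choices:
  real reference panels do not come with a published generative
  distribution.
* **Individual ancestry.** Each study population has a Dirichlet profile
  over the K = 3 ancestries. The default cohorts mirror the admixture
  means reported for the two Colombian populations that motivate the
  package: a Chocó-like cohort (mean 76% African / 13% European / 11%
  Native American, n = 94) and an Antioquia-like cohort (7/75/18,
  n = 94). The Dirichlet concentration is 30, giving an
  individual-ancestry standard deviation of roughly 0.08 — visibly spread
  but unimodal, matching the published box-plot spread of per-individual
  fractions.
* **Genotypes.** Each allele copy independently picks an ancestry from the
  individual's fractions and then an allele
  `Bernoulli(p_ancestry)`; dosage is the sum of the two copies, and
  missing calls are injected uniformly at 1% by default. SNPs are
  independent: there is no linkage disequilibrium beyond an optional
  duplicated-column device used to test pruning.
* **Risk structure.** 165 SNPs (the size of the motivating catalog-derived
  risk set) are designated risk SNPs; their risk allele (by convention the
  alternate allele) gets a `+0.15` frequency shift in the African
  ancestral population, clamped to `[0.01, 0.99]` so that no 2×2 table is
  forced to a zero cell. With `delta = 0` and identical cohort profiles
  the generator is an exchangeable null, which is how the calibration
  tests use it.
* **Catalog.** The generated GWAS-catalog-style table contains one passing
  entry per risk SNP plus three kinds of decoy with known correct fate
  (weak p-values, under-sized studies, and weaker "shadow" entries inside
  a lead SNP's clump window), and optionally independent null-trait SNP
  sets that feed the multi-disease scan and the random-set control.

Every stage draws from a named substream of the master seed, so changing
one stage's parameters (say, the missingness rate) never perturbs the
draws of another.

What the generator does **not** emulate is worth stating: linkage
disequilibrium, allele-frequency spectra shaped by real demography,
genotyping batch effects, strand-coding chaos in real catalogs, and
phenotypes. Passing tests demonstrate that the statistical machinery is
correct and well calibrated under the stated model, not that any
particular real-data conclusion is right.

## The risk statistics

For each risk SNP, with risk/non-risk allele counts `(a, b)` in
population A and `(c, d)` in population B, the relative risk-allele burden
is the log odds ratio

$$\log OR = \ln\frac{a/b}{c/d},$$

positive when the risk allele is commoner in A. Counts come from
non-missing calls only. If any cell is zero, 0.5 is added to all four
counts (Haldane–Anscombe) and the result is flagged; the standard error is
Woolf's `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% CI is Wald. A SNP is
"significant" when its CI excludes 0. The variance model is a
declaration, not a discovery: Woolf's method is the standard for
frequency-derived odds ratios.

The per-SNP results are pooled two ways: a fixed-effects inverse-variance
mean, and a DerSimonian–Laird random-effects model whose between-SNP
variance `tau^2` truncates at zero (in which case the two models
coincide). P-values use a normal reference; with 165 SNPs the small-sample
refinement of a t reference is immaterial.

The polygenic score is deliberately unweighted:

$$PRS_j = \frac{\sum_i RA_{ij}}{\sum_i A_{ij}}$$

— the fraction of individual *j*'s callable alleles, across the risk set,
that are risk alleles. Missing SNPs drop out of numerator and denominator
alike, so the score stays in [0, 1] and is comparable across individuals
with different call rates. Effect sizes are never used as weights because
risk sets of this kind pool studies whose effect estimates are not
comparable.

## The three controls

1. **Bootstrap.** Resample the risk-SNP set with replacement (default
   10,000 replicates), recompute the fixed-effects pooled log OR each
   time, and summarize the replicate distribution against zero with
   `z = mean/sd`. This measures whether the pooled signal is carried by
   the set as a whole or by a few outlier SNPs.
2. **Random SNP sets.** Draw size-matched SNP sets without replacement
   from the catalog pool (pooled across traits), recompute the pooled log
   OR for each, and standardize the observed value against this null:
   `z = (obs - mean)/sd`. A large |z| says the risk set is exceptional
   relative to arbitrary disease-associated SNPs, i.e. the signal is not
   a genome-wide frequency offset between the populations. The headline
   design uses 500,000 replicates; the z statistic is Monte-Carlo stable
   to well under 0.1 by 10,000, which the test suite verifies, so the
   acceptance script runs 100,000.
3. **Disease scan.** For every other trait in the catalog, compute the
   difference in population-mean PRS. If allele-frequency differences
   between the populations induced a systematic scoring bias, this whole
   distribution would shift; under the null it centers at zero
   (`z = mean/sd` across traits).

The z-statistic definitions are declared in output metadata; the fixed
model is used inside replicates because it is variance-principled and
cheap enough to recompute hundreds of thousands of times.

## Ancestry estimation

The paper-scale analysis needs per-individual ancestry fractions. The
package estimates them in a supervised way: given reference allele
frequencies for the K ancestral populations (clipped into
`[1e-4, 1 - 1e-4]` to keep the likelihood finite), each individual's
fractions maximize the binomial admixture log-likelihood

$$\sum_m d_m \log\left(\textstyle\sum_k q_k p_{km}\right) +
  (2 - d_m) \log\left(\textstyle\sum_k q_k (1 - p_{km})\right)$$

over the simplex, by EM-style multiplicative updates from a uniform start
(missing loci skipped). The log-likelihood is non-decreasing by
construction and the tests assert it. Identical reference rows make the
problem non-identifiable; the estimator then returns uniform fractions
with a warning rather than an arbitrary vertex. This supervised estimator
replaces unsupervised ADMIXTURE-style joint estimation: the quantity of
interest (the fractions q) is the same, the reference frequencies are
known in simulation, and parameter recovery is directly testable
(per-individual RMSE < 0.05 at K = 3, Fst = 0.1, 5,000 SNPs).

Population structure is summarized the classical way: pairwise
allele-sharing distances (per locus, similarity `1 - |d_i - d_j|/2` over
jointly called loci; distance is one minus the mean similarity), then
classical MDS (double-centre, eigendecompose, scale by root eigenvalue).
Classical MDS is used rather than PCA of the raw distance rows because it
is the principled embedding of a distance matrix and has testable
exactness: for points on a line it recovers the line to machine
correlation. Column signs are fixed by making each dimension's
largest-magnitude loading positive, so coordinates reproduce across
platforms.

LD pruning precedes the distance/ancestry stage. The threshold parameter
applies to the squared dosage correlation, default 0.05 with window/step
of 50/5 SNPs. Published pruning cutoffs of "r ≥ 0.05" are ambiguous
about r versus r²; 0.05 on r would discard nearly everything, so this
package exposes the number on the r² scale and documents the ambiguity
rather than silently guessing. Monomorphic SNPs have no defined
correlation; they are retained untested and logged.

## Catalog filtering

Three rules extract a risk set from a catalog table: the reporting study
must have at least 100,000 genotyped SNPs; the association p-value must
be below 1e-5; and only the strongest association per genomic locus
survives. "Locus" is implemented as distance-based greedy clumping with a
configurable window (default 1 Mb): survivors are sorted by ascending
p-value — ties broken by larger study then rsid, for determinism — and a
SNP is accepted unless an already-accepted SNP sits within the window on
the same chromosome. On small catalogs this greedy rule provably matches
the "repeatedly take the globally strongest and clear its window" oracle,
and the tests check that equivalence by enumeration. Every rejected row
is recorded in an audit table with the rule that removed it.

Whether the original extraction used distance windows, named locus
labels, or catalog region fields is not recoverable; window-based
clumping is this package's declared interpretation. Similarly, a
"case-control study" flag is not machine-checkable from the TSV schema,
so only the study-size rule is enforced.

## Group comparisons

Two-population PRS comparisons use a pooled-variance two-sample t-test by
default (Welch available); three or more populations use one-way ANOVA.
Degenerate inputs (zero within-group variance) are guarded explicitly
rather than left to error. The ancestry–risk relationship is summarized
by the Pearson correlation between one ancestry fraction and the PRS,
with the exact-t p-value `t = r sqrt((n-2)/(1-r^2))`, the least-squares
line, and a decile-bin summary (equal-count bins by sample quantiles of
the ancestry fraction, per-bin PRS quartiles) matching the
box-plot-per-decile presentation convention.

## Numerical and design notes

* Risk-allele alignment matches SNPs by rsID only and never strand-flips:
  a catalog risk allele matching neither genotype allele drops the SNP
  with a warning. Silent strand guessing corrupts odds ratios; positional
  fallback matching is out of scope.
* Multi-allelic VCF records are skipped by default (configurable hard
  fail); the dosage model is biallelic.
* The log OR is computed as `(log a + log d) - (log b + log c)` and the
  Woolf SE with pairwise grouping, so swapping the two populations negates
  the estimate and reproduces the SE bit-for-bit — the antisymmetry is
  exact, not approximate, and is asserted exactly in tests.
* PLINK-text round trips are exact only under a counted-allele override:
  an allele absent from every genotype in a .ped file is unrecoverable
  from the format itself.
* All stochastic stages derive named substreams from one master seed;
  identical configuration and seed give byte-identical artifacts, which
  the pipeline manifest checksums verify.

## Problem sizes

The test suite and the acceptance script run the full design at sizes a
desktop handles in seconds to a couple of minutes, chosen as the
package's own scale-downs of the headline design: 2,000 simulated SNPs
(165 of them risk SNPs), the 94 + 94 contrast cohorts plus
European-American-like (n = 99) and African-American-like (n = 61)
cohorts for the 348-genome ancestry–risk regression, 40 null traits of 40
SNPs for the disease scan, 10,000 bootstrap replicates, and 100,000
random-set replicates (20,000 in the null-calibration run). The
Monte-Carlo stability of the random-set z at these counts is itself under
test.

## Limitations

The simulator's independence assumption means LD-aware behaviour
(pruning aggressiveness on real data, clumping of truly correlated
signals) is only lightly exercised. The supervised ancestry estimator
conditions on known reference frequencies; with estimated or mismatched
references its error will be larger than the recovery tests suggest. The
unweighted PRS is the right object for pooled heterogeneous catalogs but
is not a calibrated absolute-risk predictor, and nothing here validates
scores against phenotypes.
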