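# admixrisk

Comparative polygenic risk analysis for admixed populations.

Populations that differ in genetic ancestry can also differ in how often
they carry known disease risk alleles. admixrisk implements the full
analysis needed to quantify that difference defensibly for two (or more)
population samples:

* **Catalog filtering** — extract a lead-SNP risk set from a
  GWAS-catalog-style table under three rules: study size ≥ 100,000 SNPs,
  association p < 1e-5, and strongest association per locus
  (distance-based clumping, 1 Mb default window), with a full audit trail.
* **Per-SNP risk-allele log odds ratios** between populations A and B,

      log OR = ln[ (RA_A / NRA_A) / (RA_B / NRA_B) ],

  from allele counts with Woolf standard errors, Haldane–Anscombe
  correction for zero cells, and 95% Wald CIs; positive values mean a
  higher risk-allele burden in A.
* **Meta-analysis** of all risk SNPs jointly: fixed-effects
  inverse-variance pooling and DerSimonian–Laird random effects.
* **Three controls**: bootstrap over the risk-SNP set, size-matched
  random SNP sets drawn from the catalog pool, and a multi-disease scan
  of polygenic-score differences — each summarized by a z-test.
* **Unweighted normalized polygenic risk scores**
  PRS = Σ RA_i / Σ A_i ∈ [0, 1] (risk-allele dosages over callable
  alleles; effect sizes deliberately unused).
* **Ancestry**: allele-sharing distances, classical MDS, and supervised
  EM estimation of per-individual ancestry fractions from reference
  allele frequencies; Pearson regression of PRS on an ancestry fraction
  with decile-bin summaries.
* **A Balding–Nichols admixture simulator** that generates genotypes
  (VCF / PLINK-text), truth files and decoy-laden catalogs with known
  correct answers, so the whole pipeline is testable end to end — no
  external or restricted-access data needed.

The package is tidyverse-shaped: user-facing functions take and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and each result
type has an `autoplot()`.

## Worked example

Simulate the default study conditions — a Chocó-like cohort (mean 76%
African / 13% European / 11% Native American ancestry, n = 94) versus an
Antioquia-like cohort (7/75/18, n = 94), 2,000 SNPs of which 165 are risk
SNPs with a +0.15 risk-allele frequency shift in the African ancestral
population — then run the analysis:

```r
library(admixrisk)

cfg <- sim_config(n_snps = 2000, seed = 42)
sim <- simulate_cohort(cfg, n_null_traits = 10, snps_per_null_trait = 40)
sim$gm
#> <geno_matrix> 188 samples x 2000 variants (1.0% missing)
#> populations: antioquia_like=94, choco_like=94

risk_set <- filter_catalog(sim$catalog, "T2D")      # 165 SNPs survive
aligned  <- align_risk_alleles(sim$gm, risk_set)    # dosage counts risk allele
freqs    <- allele_frequencies(aligned)
ors      <- snp_log_or_table(freqs, "choco_like", "antioquia_like")
sum(ors$significant)
#> [1] 93

meta_analyze(ors, "fixed")
#> <meta_result> fixed-effects pooled log OR = 0.5144 (95% CI 0.4730..0.5559), p = 8.18e-131, k = 165, tau2 = 0.5388
meta_analyze(ors, "random")
#> <meta_result> random-effects pooled log OR = 0.6257 (95% CI 0.5023..0.7491), p = 2.81e-23, k = 165, tau2 = 0.5388
```

93 of the 165 SNPs have 95% CIs excluding zero, and both meta-analytic
models put the pooled log OR well above zero: the Chocó-like cohort
carries a significantly higher risk-allele burden, as the simulation's
+0.15 African-ancestry shift dictates it should. The bootstrap control
confirms the signal is not driven by a few outlier SNPs:

```r
bootstrap_meta(ors, n_reps = 10000, seed = 42)$z_test
#> <z_test> z = 8.176, p = 2.92e-16 (n = 10000)
```

Individual-level scores and their ancestry structure:

```r
prs <- polygenic_risk_score(aligned)
group_prs_test(prs, groups = c("choco_like", "antioquia_like"))
#> <group_test> t: statistic = 24.968, p = 2.68e-61
#> # A tibble: 2 x 4
#>   population         n  mean     sd
#> 1 choco_like        94 0.597 0.0244
#> 2 antioquia_like    94 0.506 0.0253

ref <- sim$truth$ancestral_freqs
colnames(ref) <- sim$gm$variants$rsid
fractions <- estimate_ancestry_supervised(sim$gm, ref)
ancestry_prs_regression(fractions, "AFR", prs)
#> <ancestry_regression> r = 0.899 (p = 1.12e-68, n = 188); PRS = 0.4950 + 0.1352 x AFR
```

The mean score is 0.597 in the Chocó-like cohort against 0.506 in the
Antioquia-like cohort (t = 25), and an individual's African ancestry
fraction predicts its score with r = 0.9 — the ancestry-correlated risk
pattern the generator encodes, recovered by the full estimation chain
(supervised ancestry EM plus unweighted PRS).

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains
every stage — simulation or file input, filtering, ancestry, ORs and
meta-analysis, all three controls, scores, comparisons — and writes
per-stage TSV/JSON artifacts plus a checksummed manifest.

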