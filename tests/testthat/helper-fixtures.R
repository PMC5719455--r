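# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A hand-specified genotype matrix. `dosage` is an N x M matrix (NA =
# missing); counted allele defaults to alt ("G") at every SNP.
toy_gm <- function(dosage, populations = NULL, counted = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  geno_matrix(
    dosage,
    samples = tibble::tibble(
      sample = paste0("s", seq_len(n)),
      population = populations %||% rep("pop", n)
    ),
    variants = tibble::tibble(
      rsid = paste0("rs", seq_len(m)),
      chrom = as.character(((seq_len(m) - 1) %% 22) + 1),
      pos = (((seq_len(m) - 1) %/% 22) + 1) * 3000000L,
      ref = "A", alt = "G",
      counted_allele = counted %||% rep("G", m)
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-population simulation with identical ancestry profiles and no risk
# shift: the exchangeable null used by the calibration tests.
null_two_pop_config <- function(seed, n_snps = 1200, n_per_pop = 94,
                                n_risk = 165) {
  alpha <- 30 * c(0.4, 0.4, 0.2)
  sim_config(
    n_snps = n_snps, n_risk_snps = n_risk, seed = seed,
    risk_shift_delta = 0,
    pop_profiles = list(
      list(label = "popA", n_individuals = n_per_pop,
           dirichlet_alpha = alpha),
      list(label = "popB", n_individuals = n_per_pop,
           dirichlet_alpha = alpha)
    )
  )
}

# The default contrast (Choco-like vs Antioquia-like) at reduced SNP count.
contrast_config <- function(seed, n_snps = 1200, n_risk = 165,
                            delta = 0.15) {
  sim_config(n_snps = n_snps, n_risk_snps = n_risk, seed = seed,
             risk_shift_delta = delta)
}

# Per-SNP OR table straight from a simulated contrast cohort.
simulated_or_table <- function(seed, n_snps = 1200, n_risk = 165,
                               delta = 0.15) {
  sim <- suppressMessages(simulate_cohort(contrast_config(
    seed, n_snps = n_snps, n_risk = n_risk, delta = delta
  )))
  rs <- suppressWarnings(filter_catalog(sim$catalog, "T2D"))
  al <- suppressMessages(align_risk_alleles(sim$gm, rs))
  fr <- suppressMessages(allele_frequencies(al))
  suppressMessages(snp_log_or_table(fr, "choco_like", "antioquia_like"))
}

# Random 2x2 allele-count tables, occasionally with zero cells.
random_count_tables <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = rbinom(n, 200, runif(n, 0.02, 0.98)),
      b = rbinom(n, 200, runif(n, 0.02, 0.98)),
      c = rbinom(n, 200, runif(n, 0.02, 0.98)),
      d = rbinom(n, 200, runif(n, 0.02, 0.98))
    )
  })
}
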