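#' Configure an admixed-cohort simulation
#'
#' Defines the generative model behind every synthetic dataset: K ancestral
#' populations with Balding-Nichols-differentiated allele frequencies, study
#' populations whose individual ancestry fractions are Dirichlet draws around
#' population-specific means, designated risk SNPs whose risk-allele
#' frequency is shifted in one ancestral population, and uniform missingness.
#'
#' The defaults emulate a two-cohort Afro-Latino vs Mestizo contrast: a
#' Choco-like sample (mean ancestry 76% African / 13% European / 11% Native
#' American, n = 94) against an Antioquia-like sample (7/75/18, n = 94),
#' 165 risk SNPs with a +0.15 risk-allele frequency shift in the African
#' ancestral population.
#'
#' @param n_ancestral_pops integer K >= 2.
#' @param ancestry_labels character vector of K labels.
#' @param fst_per_pop numeric vector of K fixation indices, each in (0, 1).
#' @param n_snps total number of simulated SNPs.
#' @param pop_profiles list of profiles, each a list with `label`,
#'   `n_individuals`, and `dirichlet_alpha` (length-K positive vector).
#' @param n_risk_snps number of designated risk SNPs (<= n_snps).
#' @param risk_shift_delta signed risk-allele frequency shift in [-0.5, 0.5]
#'   applied in one ancestral population.
#' @param shift_target_ancestry 1-based index of the ancestral population
#'   receiving the shift.
#' @param missing_rate per-call missingness probability in [0, 1).
#' @param seed master integer seed; every stage draws from a named substream
#'   derived from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_ancestral_pops = 3,
                       ancestry_labels = c("AFR", "EUR", "NAM"),
                       fst_per_pop = c(0.15, 0.15, 0.2),
                       n_snps = 2000,
                       pop_profiles = list(
                         list(label = "choco_like", n_individuals = 94,
                              dirichlet_alpha = 30 * c(0.76, 0.13, 0.11)),
                         list(label = "antioquia_like", n_individuals = 94,
                              dirichlet_alpha = 30 * c(0.07, 0.75, 0.18))
                       ),
                       n_risk_snps = 165,
                       risk_shift_delta = 0.15,
                       shift_target_ancestry = 1,
                       missing_rate = 0.01,
                       seed = 1L) {
  K <- n_ancestral_pops
  if (!is.numeric(K) || K < 2) abort("n_ancestral_pops must be an integer >= 2")
  if (length(ancestry_labels) != K) abort("need one ancestry label per ancestral population")
  if (length(fst_per_pop) != K) abort("need one Fst value per ancestral population")
  if (any(fst_per_pop <= 0) || any(fst_per_pop >= 1)) {
    abort("fst_per_pop values must lie strictly in (0, 1)")
  }
  if (n_risk_snps > n_snps) abort("n_risk_snps cannot exceed n_snps")
  if (abs(risk_shift_delta) > 0.5) abort("risk_shift_delta must lie in [-0.5, 0.5]")
  if (!(shift_target_ancestry %in% seq_len(K))) {
    abort("shift_target_ancestry must index an ancestral population (1..K)")
  }
  assert_prob(missing_rate, "missing_rate", open_upper = TRUE)
  for (p in pop_profiles) {
    if (!all(c("label", "n_individuals", "dirichlet_alpha") %in% names(p))) {
      abort("each pop profile needs label, n_individuals, dirichlet_alpha")
    }
    if (length(p$dirichlet_alpha) != K || any(p$dirichlet_alpha <= 0)) {
      abort("dirichlet_alpha must be a length-K vector of positive values")
    }
  }
  structure(
    list(
      n_ancestral_pops = as.integer(K),
      ancestry_labels = ancestry_labels,
      fst_per_pop = as.numeric(fst_per_pop),
      n_snps = as.integer(n_snps),
      pop_profiles = pop_profiles,
      n_risk_snps = as.integer(n_risk_snps),
      risk_shift_delta = as.numeric(risk_shift_delta),
      shift_target_ancestry = as.integer(shift_target_ancestry),
      missing_rate = as.numeric(missing_rate),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Variant metadata shared by all simulator outputs. SNPs rotate across 22
# chromosomes with 3 Mb spacing within a chromosome, so distinct simulated
# SNPs never fall inside the default 1 Mb clump window of one another.
sim_variant_table <- function(n_snps) {
  idx <- seq_len(n_snps)
  tibble(
    rsid = paste0("rs", idx),
    chrom = as.character(((idx - 1L) %% 22L) + 1L),
    pos = (((idx - 1L) %/% 22L) + 1L) * 3000000L,
    ref = "A",
    alt = "G",
    counted_allele = "G"
  )
}

#' Draw ancestral allele frequencies under the Balding-Nichols model
#'
#' Each SNP gets a common ancestral frequency p0 ~ Uniform(0.05, 0.95)
#' (truncated support keeps every SNP polymorphic), and ancestral population
#' k's frequency is a Beta draw with mean p0 and variance F_k p0 (1 - p0).
#'
#' @param config a [sim_config()].
#' @return a K x M matrix of alternate-allele frequencies, with the per-SNP
#'   ancestral frequency in attribute `p0`.
#' @export
draw_ancestral_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_ancestral_pops
  M <- config$n_snps
  with_substream(config$seed, "frequencies", {
    p0 <- runif(M, 0.05, 0.95)
    freqs <- matrix(NA_real_, K, M,
                    dimnames = list(config$ancestry_labels, NULL))
    for (k in seq_len(K)) {
      f <- config$fst_per_pop[k]
      shape <- (1 - f) / f
      freqs[k, ] <- rbeta(M, p0 * shape, (1 - p0) * shape)
    }
    attr(freqs, "p0") <- p0
    freqs
  })
}

#' Designate risk SNPs and shift their risk-allele frequency
#'
#' Selects `n_risk_snps` SNPs without replacement, designates the alternate
#' allele of each as the risk allele, and adds `risk_shift_delta` to the
#' risk-allele frequency in the target ancestral population, clamping the
#' result to [0.01, 0.99] so no cell of a downstream 2x2 table is forced to
#' zero.
#'
#' @param config a [sim_config()].
#' @param freqs K x M ancestral frequency matrix from
#'   [draw_ancestral_frequencies()].
#' @return list with `freqs` (modified matrix) and `risk_set`, a
#'   [risk_snp_set] tibble (rsid, chrom, pos, risk_allele, p_value = NA).
#' @export
designate_risk_snps <- function(config, freqs) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dim(freqs) == c(config$n_ancestral_pops, config$n_snps))) {
    abort("freqs dimensions do not match config")
  }
  variants <- sim_variant_table(config$n_snps)
  with_substream(config$seed, "risk", {
    risk_idx <- sort(sample.int(config$n_snps, config$n_risk_snps))
    tgt <- config$shift_target_ancestry
    if (config$risk_shift_delta != 0) {
      freqs[tgt, risk_idx] <- pmin(
        pmax(freqs[tgt, risk_idx] + config$risk_shift_delta, 0.01), 0.99
      )
    }
    risk_set <- new_risk_snp_set(
      tibble(
        rsid = variants$rsid[risk_idx],
        chrom = variants$chrom[risk_idx],
        pos = variants$pos[risk_idx],
        risk_allele = variants$alt[risk_idx],
        p_value = NA_real_
      ),
      trait = "T2D"
    )
    list(freqs = freqs, risk_set = risk_set, risk_idx = risk_idx)
  })
}

# Dirichlet draws, one row per individual.
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Draw admixed genotypes for all configured study populations
#'
#' Per individual, ancestry fractions q are a Dirichlet draw from the
#' individual's population profile. Each of the two allele copies at each SNP
#' picks an ancestral population from q and then an allele
#' Bernoulli(p_ancestry); the dosage is the sum of the two copies. Missing
#' calls are injected uniformly at `missing_rate` after generation.
#'
#' @param config a [sim_config()].
#' @param freqs K x M ancestral frequency matrix (after any risk shift).
#' @return list with `gm` (a [geno_matrix()]) and `ancestry_fractions`
#'   (tibble: sample, population, one column per ancestry label; rows on the
#'   simplex).
#' @export
draw_admixed_genotypes <- function(config, freqs) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dim(freqs) == c(config$n_ancestral_pops, config$n_snps))) {
    abort("freqs dimensions do not match config")
  }
  K <- config$n_ancestral_pops
  M <- config$n_snps
  n_total <- sum(vapply(config$pop_profiles, function(p) p$n_individuals, 1))
  q_all <- with_substream(config$seed, "fractions", {
    do.call(rbind, lapply(config$pop_profiles, function(p) {
      rdirichlet(p$n_individuals, p$dirichlet_alpha)
    }))
  })
  pop_labels <- unlist(lapply(config$pop_profiles, function(p) {
    rep(p$label, p$n_individuals)
  }))
  sample_ids <- paste0(pop_labels, "_", unlist(lapply(
    config$pop_profiles, function(p) seq_len(p$n_individuals)
  )))

  dosage <- with_substream(config$seed, "genotypes", {
    d <- matrix(0L, n_total, M)
    for (i in seq_len(n_total)) {
      for (copy in 1:2) {
        anc <- sample.int(K, M, replace = TRUE, prob = q_all[i, ])
        p <- freqs[cbind(anc, seq_len(M))]
        d[i, ] <- d[i, ] + rbinom(M, 1L, p)
      }
    }
    d
  })
  if (config$missing_rate > 0) {
    dosage <- with_substream(config$seed, "missing", {
      drop_mask <- matrix(
        runif(n_total * M) < config$missing_rate, n_total, M
      )
      dosage[drop_mask] <- NA_integer_
      dosage
    })
  }

  fractions <- as_tibble(q_all, .name_repair = ~config$ancestry_labels)
  fractions <- dplyr::bind_cols(
    tibble(sample = sample_ids, population = pop_labels), fractions
  )
  gm <- geno_matrix(
    dosage,
    samples = tibble(sample = sample_ids, population = pop_labels),
    variants = sim_variant_table(M)
  )
  list(gm = gm, ancestry_fractions = fractions)
}

#' Generate a GWAS-catalog-style table with known correct filter output
#'
#' Emits one passing entry per truth risk SNP (association p < 1e-5 from a
#' study of >= 100,000 SNPs) plus three kinds of decoy whose removal the
#' catalog filter must reproduce: entries with weak p-values, entries from
#' small studies, and "shadow" entries at positions inside the clump window
#' of a truth SNP but with a weaker p-value. Optionally adds independent
#' null-trait SNP sets (no frequency shift) for the multi-disease scan and
#' the random-SNP-set control.
#'
#' @param truth list from [simulate_cohort()] holding `risk_set` and the
#'   variant table.
#' @param config a [sim_config()].
#' @param n_weak_p,n_small_study,n_shadow decoy counts.
#' @param n_null_traits number of additional traits with unshifted SNP sets.
#' @param snps_per_null_trait SNPs per null trait.
#' @param clump_window_bp window within which shadow decoys are placed.
#' @return a catalog tibble with columns rsid, chrom, pos, trait,
#'   risk_allele, p_value, study_snp_count, study_id.
#' @export
generate_catalog <- function(truth, config,
                             n_weak_p = 10, n_small_study = 5, n_shadow = 20,
                             n_null_traits = 0, snps_per_null_trait = 50,
                             clump_window_bp = 1000000) {
  stopifnot(inherits(config, "sim_config"))
  variants <- sim_variant_table(config$n_snps)
  risk_set <- truth$risk_set
  non_risk <- variants[!(variants$rsid %in% risk_set$rsid), ]
  if (n_null_traits * snps_per_null_trait > nrow(non_risk)) {
    abort("not enough non-risk SNPs for the requested null traits")
  }
  if (n_weak_p + n_small_study > nrow(non_risk)) {
    n_weak_p <- min(n_weak_p, nrow(non_risk))
    n_small_study <- min(n_small_study, nrow(non_risk) - n_weak_p)
    log_note("generate_catalog: decoy counts capped by available non-risk SNPs")
  }
  with_substream(config$seed, "catalog", {
    main <- tibble(
      rsid = risk_set$rsid,
      chrom = risk_set$chrom,
      pos = risk_set$pos,
      trait = "T2D",
      risk_allele = risk_set$risk_allele,
      p_value = 10^-runif(nrow(risk_set), 6, 20),
      study_snp_count = sample(100000:1000000, nrow(risk_set), replace = TRUE),
      study_id = paste0("study_", sample.int(29, nrow(risk_set), replace = TRUE))
    )
    decoys <- list()
    if (n_weak_p > 0) {
      pick <- non_risk[sample.int(nrow(non_risk), n_weak_p), ]
      decoys$weak <- tibble(
        rsid = pick$rsid, chrom = pick$chrom, pos = pick$pos, trait = "T2D",
        risk_allele = pick$alt,
        p_value = 10^-runif(n_weak_p, 1, 4.9), # all >= 1e-5
        study_snp_count = sample(100000:1000000, n_weak_p, replace = TRUE),
        study_id = "study_weak"
      )
    }
    if (n_small_study > 0) {
      pick <- non_risk[sample.int(nrow(non_risk), n_small_study), ]
      decoys$small <- tibble(
        rsid = pick$rsid, chrom = pick$chrom, pos = pick$pos, trait = "T2D",
        risk_allele = pick$alt,
        p_value = 10^-runif(n_small_study, 6, 12),
        study_snp_count = sample(10000:99999, n_small_study, replace = TRUE),
        study_id = "study_small"
      )
    }
    if (n_shadow > 0) {
      parent <- main[sample.int(nrow(main), n_shadow, replace = TRUE), ]
      # weaker than the parent by 1-4 orders of magnitude, still < 1e-5
      shadow_p <- pmin(parent$p_value * 10^runif(n_shadow, 1, 4), 9e-6)
      decoys$shadow <- tibble(
        rsid = paste0("rs_shadow", seq_len(n_shadow)),
        chrom = parent$chrom,
        pos = parent$pos + sample.int(clump_window_bp - 1L, n_shadow,
                                      replace = TRUE),
        trait = "T2D",
        risk_allele = "G",
        p_value = shadow_p,
        study_snp_count = sample(100000:1000000, n_shadow, replace = TRUE),
        study_id = "study_shadow"
      )
    }
    nulls <- list()
    if (n_null_traits > 0) {
      pool_idx <- sample.int(nrow(non_risk),
                             n_null_traits * snps_per_null_trait)
      for (tnum in seq_len(n_null_traits)) {
        take <- pool_idx[((tnum - 1) * snps_per_null_trait + 1):
                           (tnum * snps_per_null_trait)]
        pick <- non_risk[take, ]
        # null traits count either allele as "risk" at random
        use_alt <- runif(nrow(pick)) < 0.5
        nulls[[tnum]] <- tibble(
          rsid = pick$rsid, chrom = pick$chrom, pos = pick$pos,
          trait = paste0("trait_", tnum),
          risk_allele = ifelse(use_alt, pick$alt, pick$ref),
          p_value = 10^-runif(nrow(pick), 6, 12),
          study_snp_count = sample(100000:1000000, nrow(pick), replace = TRUE),
          study_id = paste0("study_null_", tnum)
        )
      }
    }
    dplyr::bind_rows(c(list(main), decoys, nulls))
  })
}

#' Simulate a complete admixed cohort with truth files and catalog
#'
#' One-call orchestration of the generator: ancestral frequencies, risk-SNP
#' designation, admixed genotypes with missingness, and a decoy-laden
#' catalog. Identical (config, seed) give bit-identical outputs; each stage
#' draws from its own named substream of the master seed.
#'
#' @param config a [sim_config()].
#' @param ... passed to [generate_catalog()] (decoy and null-trait counts).
#' @return list with `gm` ([geno_matrix()]), `truth` (list: ancestral_freqs
#'   with risk shift applied, ancestry_fractions tibble, risk_set), and
#'   `catalog` (tibble).
#' @export
simulate_cohort <- function(config = sim_config(), ...) {
  freqs0 <- draw_ancestral_frequencies(config)
  des <- designate_risk_snps(config, freqs0)
  geno <- draw_admixed_genotypes(config, des$freqs)
  truth <- list(
    ancestral_freqs = des$freqs,
    ancestry_fractions = geno$ancestry_fractions,
    risk_set = des$risk_set
  )
  catalog <- generate_catalog(truth, config, ...)
  list(gm = geno$gm, truth = truth, catalog = catalog)
}
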