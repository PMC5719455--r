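# The admixture simulator: Balding-Nichols frequencies, Dirichlet ancestry,
# genotype draws, risk-SNP designation, and the decoy-laden catalog.

small_profiles <- list(
  list(label = "p1", n_individuals = 15, dirichlet_alpha = c(4, 3, 2)),
  list(label = "p2", n_individuals = 10, dirichlet_alpha = c(1, 6, 2))
)

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- sim_config(n_snps = 120, n_risk_snps = 20, seed = 9,
                    pop_profiles = small_profiles)
  s1 <- suppressMessages(simulate_cohort(cfg, n_null_traits = 2,
                                         snps_per_null_trait = 10))
  s2 <- suppressMessages(simulate_cohort(cfg, n_null_traits = 2,
                                         snps_per_null_trait = 10))
  expect_identical(s1$gm$dosage, s2$gm$dosage)
  expect_identical(s1$truth$ancestral_freqs, s2$truth$ancestral_freqs)
  expect_identical(s1$catalog, s2$catalog)
})

test_that("changing one stage's substream leaves earlier stages untouched", {
  c1 <- sim_config(n_snps = 100, n_risk_snps = 10, seed = 4,
                   pop_profiles = small_profiles, missing_rate = 0)
  c2 <- sim_config(n_snps = 100, n_risk_snps = 10, seed = 4,
                   pop_profiles = small_profiles, missing_rate = 0.2)
  expect_identical(draw_ancestral_frequencies(c1),
                   draw_ancestral_frequencies(c2))
  g1 <- draw_admixed_genotypes(c1, draw_ancestral_frequencies(c1))
  g2 <- draw_admixed_genotypes(c2, draw_ancestral_frequencies(c2))
  d1 <- g1$gm$dosage
  d2 <- g2$gm$dosage
  both <- !is.na(d2)
  expect_identical(d1[both], d2[both]) # missingness only removes calls
})

test_that("Balding-Nichols frequencies have the right limit and variance", {
  # near-zero Fst: all population frequencies collapse onto p0
  cfg0 <- sim_config(n_snps = 200, n_risk_snps = 1, seed = 2,
                     fst_per_pop = c(1e-9, 1e-9, 1e-9))
  f0 <- draw_ancestral_frequencies(cfg0)
  p0 <- attr(f0, "p0")
  expect_lt(max(abs(sweep(f0, 2, p0))), 1e-3)

  # F = 0.1: empirical variance of the standardized residual matches F
  cfg <- sim_config(n_snps = 10000, n_risk_snps = 1, seed = 2,
                    fst_per_pop = c(0.1, 0.1, 0.1))
  f <- draw_ancestral_frequencies(cfg)
  p0 <- attr(f, "p0")
  std <- (f[1, ] - p0) / sqrt(p0 * (1 - p0))  # variance should be F
  v <- var(std)
  mc_se <- sd((std - mean(std))^2) / sqrt(length(std))
  expect_lt(abs(v - 0.1), 3 * mc_se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fst_per_pop = c(0, 0.1, 0.1)), "strictly")
  expect_error(sim_config(fst_per_pop = c(1, 0.1, 0.1)), "strictly")
  expect_error(sim_config(n_snps = 10, n_risk_snps = 11), "exceed")
  expect_error(sim_config(risk_shift_delta = 0.7), "0.5")
  expect_error(sim_config(shift_target_ancestry = 4), "index")
})

test_that("concentrated Dirichlet gives pure-ancestry Hardy-Weinberg genotypes", {
  cfg <- sim_config(
    n_snps = 60, n_risk_snps = 1, seed = 31, missing_rate = 0,
    pop_profiles = list(list(
      label = "pure1", n_individuals = 800,
      dirichlet_alpha = c(1e6, 1e-6, 1e-6)
    ))
  )
  f <- draw_ancestral_frequencies(cfg)
  g <- draw_admixed_genotypes(cfg, f)
  q <- as.matrix(g$ancestry_fractions[, c("AFR", "EUR", "NAM")])
  expect_true(all(q[, 1] > 0.999))
  # observed genotype-class frequencies match p^2, 2pq, q^2 within 4 SE
  p <- f[1, ]
  for (gclass in 0:2) {
    expected <- switch(gclass + 1, (1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- colMeans(g$gm$dosage == gclass)
    se <- sqrt(expected * (1 - expected) / 800)
    expect_true(all(abs(obs - expected) < 4 * se + 1e-9))
  }
})

test_that("expected dosage equals 2 sum_k q_k p_k (law of total expectation)", {
  cfg <- sim_config(
    n_snps = 50, n_risk_snps = 1, seed = 12, missing_rate = 0,
    pop_profiles = list(list(label = "mix", n_individuals = 5000,
                             dirichlet_alpha = c(2, 3, 1)))
  )
  f <- draw_ancestral_frequencies(cfg)
  g <- draw_admixed_genotypes(cfg, f)
  q <- as.matrix(g$ancestry_fractions[, c("AFR", "EUR", "NAM")])
  expected <- 2 * (q %*% f)          # N x M expected dosages
  mu_exp <- colMeans(expected)
  mu_obs <- colMeans(g$gm$dosage)
  se <- apply(g$gm$dosage, 2, sd) / sqrt(5000)
  expect_true(all(abs(mu_obs - mu_exp) < 3.5 * se))
})

test_that("ancestry fraction rows lie on the simplex", {
  cfg <- sim_config(n_snps = 40, n_risk_snps = 4, seed = 8,
                    pop_profiles = small_profiles)
  g <- draw_admixed_genotypes(cfg, draw_ancestral_frequencies(cfg))
  q <- as.matrix(g$ancestry_fractions[, c("AFR", "EUR", "NAM")])
  expect_true(all(q >= 0))
  expect_lt(max(abs(rowSums(q) - 1)), 1e-12)
})

test_that("missing_rate = 0 yields no missing entries", {
  cfg <- sim_config(n_snps = 80, n_risk_snps = 5, seed = 6,
                    missing_rate = 0, pop_profiles = small_profiles)
  g <- draw_admixed_genotypes(cfg, draw_ancestral_frequencies(cfg))
  expect_false(anyNA(g$gm$dosage))
})

test_that("risk designation shifts only target-ancestry frequencies by delta", {
  cfg <- sim_config(n_snps = 500, n_risk_snps = 100, seed = 13,
                    risk_shift_delta = 0.15, shift_target_ancestry = 1,
                    pop_profiles = small_profiles)
  f0 <- draw_ancestral_frequencies(cfg)
  des <- designate_risk_snps(cfg, f0)
  idx <- match(des$risk_set$rsid, paste0("rs", seq_len(cfg$n_snps)))
  shift <- des$freqs[1, idx] - f0[1, idx]
  # clamping can shrink (or near the upper bound reverse) the shift, never
  # push the shifted frequency outside [0.01, 0.99] or past delta
  expect_true(all(shift <= 0.15 + 1e-12))
  expect_true(all(des$freqs[1, idx] >= 0.01 & des$freqs[1, idx] <= 0.99))
  expect_gt(mean(abs(shift - 0.15) < 1e-12), 0.5)
  expect_identical(des$freqs[2:3, ], f0[2:3, ])
  non_risk <- setdiff(seq_len(cfg$n_snps), idx)
  expect_identical(des$freqs[1, non_risk], f0[1, non_risk])
  # delta = 0 leaves the matrix untouched
  cfg0 <- sim_config(n_snps = 500, n_risk_snps = 100, seed = 13,
                     risk_shift_delta = 0, pop_profiles = small_profiles)
  des0 <- designate_risk_snps(cfg0, f0)
  expect_identical(des0$freqs, f0)
})

test_that("pure-ancestry samples separated by delta differ by about delta", {
  cfg <- sim_config(
    n_snps = 400, n_risk_snps = 400, seed = 21, missing_rate = 0,
    risk_shift_delta = 0.15, shift_target_ancestry = 1,
    pop_profiles = list(
      list(label = "pure1", n_individuals = 400,
           dirichlet_alpha = c(1e6, 1e-6, 1e-6)),
      list(label = "pure2", n_individuals = 400,
           dirichlet_alpha = c(1e-6, 1e6, 1e-6))
    )
  )
  sim <- suppressMessages(simulate_cohort(cfg))
  d <- sim$gm$dosage
  pop <- sim$gm$samples$population
  diff_freq <- colMeans(d[pop == "pure1", ]) / 2 -
    colMeans(d[pop == "pure2", ]) / 2
  # frequency-difference oracle: the truth matrix carries the applied shift
  # (slightly below the nominal 0.15 where clamping at 0.99 bites)
  truth_diff <- mean(sim$truth$ancestral_freqs[1, ] -
                       sim$truth$ancestral_freqs[2, ])
  expect_equal(mean(diff_freq), truth_diff, tolerance = 0.01)
  expect_gt(truth_diff, 0.10)
  expect_lt(truth_diff, 0.17)
})

test_that("default configuration reproduces the 165-SNP risk-set size", {
  cfg <- sim_config()
  f <- draw_ancestral_frequencies(cfg)
  des <- designate_risk_snps(cfg, f)
  expect_identical(nrow(des$risk_set), 165L)
})

test_that("catalog decoys are exactly removed by the filter", {
  cfg <- sim_config(n_snps = 300, n_risk_snps = 30, seed = 17,
                    pop_profiles = small_profiles)
  sim <- suppressMessages(simulate_cohort(
    cfg, n_weak_p = 10, n_small_study = 5, n_shadow = 20
  ))
  filtered <- filter_catalog(sim$catalog, "T2D")
  expect_setequal(filtered$rsid, sim$truth$risk_set$rsid)
  # and with zero decoys the filter returns the catalog's own SNPs
  sim0 <- suppressMessages(simulate_cohort(
    cfg, n_weak_p = 0, n_small_study = 0, n_shadow = 0
  ))
  filtered0 <- filter_catalog(sim0$catalog, "T2D")
  expect_setequal(filtered0$rsid, sim0$catalog$rsid)
})

test_that("shadow entries land inside a truth SNP's clump window and lose", {
  cfg <- sim_config(n_snps = 300, n_risk_snps = 30, seed = 23,
                    pop_profiles = small_profiles)
  sim <- suppressMessages(simulate_cohort(
    cfg, n_weak_p = 0, n_small_study = 0, n_shadow = 15
  ))
  shadows <- dplyr::filter(sim$catalog, grepl("^rs_shadow", rsid))
  expect_identical(nrow(shadows), 15L)
  truth <- sim$truth$risk_set
  for (i in seq_len(nrow(shadows))) {
    near <- truth$chrom == shadows$chrom[i] &
      abs(truth$pos - shadows$pos[i]) <= 1000000
    expect_true(any(near))
  }
  filtered <- filter_catalog(sim$catalog, "T2D")
  expect_false(any(grepl("^rs_shadow", filtered$rsid)))
})
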