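# Allele frequencies, LD pruning, allele-sharing distances, MDS, and the
# supervised ancestry estimator.

test_that("allele counting follows the hand-worked examples", {
  gm <- toy_gm(matrix(c(2L, 1L, 0L,
                        2L, NA, 0L,
                        2L, 2L, 2L), nrow = 3))
  fr <- allele_frequencies(gm, by_population = FALSE)
  expect_equal(fr$risk_allele_count, c(3, 2, 6))
  expect_equal(fr$nonrisk_allele_count, c(3, 2, 0))
  expect_equal(fr$risk_allele_freq, c(0.5, 0.5, 1))
  # count conservation against non-missing calls
  expect_equal(fr$risk_allele_count + fr$nonrisk_allele_count,
               unname(2 * colSums(!is.na(gm$dosage))))
})

test_that("zero-call population cells are flagged undefined", {
  gm <- toy_gm(matrix(c(1L, NA, 2L, NA), nrow = 2),
               populations = c("a", "b"))
  expect_message(fr <- allele_frequencies(gm), "zero non-missing")
  undef <- fr[fr$population == "b", ]
  expect_true(all(is.na(undef$risk_allele_freq)))
})

test_that("perfect-LD duplicates lose exactly one of the pair", {
  base <- withr::with_seed(1, matrix(rbinom(200 * 20, 2, 0.4), 200, 20))
  dup <- cbind(base, base[, 3])   # column 21 duplicates column 3
  gm <- toy_gm(dup)
  kept <- suppressMessages(ld_prune(gm, r2_threshold = 0.8,
                                    window_snps = 30))
  expect_true(xor("rs3" %in% kept, "rs21" %in% kept))
  expect_true(all(paste0("rs", c(1, 2, 4:20)) %in% kept))
})

test_that("independent SNPs are almost never pruned at a high threshold", {
  gm <- toy_gm(withr::with_seed(2, matrix(rbinom(500 * 1000, 2, 0.3),
                                          500, 1000)))
  kept <- suppressMessages(ld_prune(gm, r2_threshold = 0.8))
  expect_gte(length(kept) / 1000, 0.99)
})

test_that("degenerate pruning windows and monomorphic SNPs are safe", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, 1L,
                        2L, 2L, 2L, 2L,   # monomorphic
                        0L, 1L, 2L, 1L), nrow = 4))
  expect_message(kept <- ld_prune(gm, r2_threshold = 0.5, window_snps = 3),
                 "monomorphic")
  expect_true("rs2" %in% kept)        # monomorphic retained untested
  expect_length(kept, 2)              # rs3 pruned (duplicate of rs1)
  # a 1-SNP window has no pairs: nothing pruned
  kept1 <- suppressMessages(ld_prune(gm, r2_threshold = 0.5,
                                     window_snps = 1))
  expect_length(kept1, 3)
  expect_error(ld_prune(gm_subset(gm, variants = 1)), "at least 2")
})

test_that("allele-sharing distances match the hand-worked cases", {
  gm <- toy_gm(matrix(c(0L, 2L), nrow = 2))          # single locus, 0 vs 2
  d <- allele_sharing_distance(gm)
  expect_equal(unname(d[1, 2]), 1)
  gm2 <- toy_gm(matrix(c(0L, 2L, 1L, 1L), nrow = 2)) # (0,1) vs (2,1)
  d2 <- allele_sharing_distance(gm2)
  expect_equal(unname(d2[1, 2]), 0.5)
  gm3 <- toy_gm(matrix(rep(c(0L, 1L, 2L), 2), nrow = 1)) # self only
  gm4 <- toy_gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))     # identical rows
  expect_equal(unname(allele_sharing_distance(gm4)[1, 2]), 0)
})

test_that("distances are bounded, symmetric and permutation-consistent", {
  cfg <- sim_config(n_snps = 100, n_risk_snps = 5, seed = 14,
                    missing_rate = 0.1,
                    pop_profiles = list(list(label = "p", n_individuals = 12,
                                             dirichlet_alpha = c(2, 2, 2))))
  gm <- draw_admixed_genotypes(cfg, draw_ancestral_frequencies(cfg))$gm
  d <- allele_sharing_distance(gm)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  perm <- withr::with_seed(3, sample.int(12))
  d_perm <- allele_sharing_distance(gm_subset(gm, samples = perm))
  expect_equal(unname(d_perm), unname(d[perm, perm]))
})

test_that("pairs sharing no called loci raise a named error", {
  gm <- toy_gm(matrix(c(1L, NA, NA, 2L), nrow = 2))
  expect_error(allele_sharing_distance(gm), "zero jointly-called")
})

test_that("classical MDS recovers collinear points and separates populations", {
  # points on a line: first coordinate reproduces the line exactly
  x <- seq(0, 1, length.out = 20)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("s", 1:20), paste0("s", 1:20))
  co <- suppressWarnings(project_mds(dm, 2))
  expect_gt(abs(cor(co$MDS1, x)), 0.999)

  # two well-differentiated populations separate in 2D (silhouette > 0.5)
  cfg <- sim_config(
    n_snps = 300, n_risk_snps = 5, seed = 19, missing_rate = 0,
    fst_per_pop = c(0.2, 0.2, 0.2),
    pop_profiles = list(
      list(label = "a", n_individuals = 25,
           dirichlet_alpha = c(1e6, 1e-6, 1e-6)),
      list(label = "b", n_individuals = 25,
           dirichlet_alpha = c(1e-6, 1e6, 1e-6))
    )
  )
  gm <- draw_admixed_genotypes(cfg, draw_ancestral_frequencies(cfg))$gm
  co2 <- project_mds(allele_sharing_distance(gm), 2)
  pts <- as.matrix(co2[, c("MDS1", "MDS2")])
  lab <- gm$samples$population
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    dd <- sqrt(colSums((t(pts) - pts[i, ])^2))
    a <- mean(dd[lab == lab[i] & seq_along(lab) != i])
    b <- mean(dd[lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("MDS handles zero matrices and rejects asymmetry", {
  dm0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(co <- project_mds(dm0, 2), "padding")
  expect_true(all(co$MDS1 == 0 & co$MDS2 == 0))
  dm_bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(project_mds(dm_bad, 1), "symmetric")
})

# direct mixture draw: dosage ~ Binomial(2, q' p) marginally
mixture_gm <- function(q, freqs, n, seed) {
  p_mix <- as.vector(q %*% freqs)
  d <- withr::with_seed(seed, {
    matrix(rbinom(n * length(p_mix), 2, rep(p_mix, each = n)),
           nrow = n, byrow = FALSE)
  })
  toy_gm(d)
}

bn_reference <- function(k, m, fst, seed) {
  withr::with_seed(seed, {
    p0 <- runif(m, 0.05, 0.95)
    shape <- (1 - fst) / fst
    f <- t(vapply(seq_len(k), function(i) rbeta(m, p0 * shape,
                                                (1 - p0) * shape),
                  numeric(m)))
    rownames(f) <- paste0("anc", seq_len(k))
    colnames(f) <- paste0("rs", seq_len(m))
    f
  })
}

test_that("pure-ancestry individuals are assigned to their source", {
  f <- bn_reference(3, 2000, 0.1, 41)
  gm <- mixture_gm(matrix(c(1, 0, 0), 1), f, n = 5, seed = 42)
  est <- estimate_ancestry_supervised(gm, f)
  expect_true(all(est$anc1 >= 0.95))
})

test_that("a 50/50 admixed individual is recovered within 0.05", {
  f <- bn_reference(2, 10000, 0.1, 43)
  gm <- mixture_gm(matrix(c(0.5, 0.5), 1), f, n = 4, seed = 44)
  est <- estimate_ancestry_supervised(gm, f)
  expect_true(all(abs(est$anc1 - 0.5) < 0.05))
})

test_that("identical reference rows give uniform fractions with a warning", {
  f <- bn_reference(1, 500, 0.1, 45)
  f3 <- rbind(anc1 = f[1, ], anc2 = f[1, ], anc3 = f[1, ])
  colnames(f3) <- colnames(f)
  gm <- mixture_gm(matrix(c(1, 0, 0), 1), f3, n = 3, seed = 46)
  expect_warning(est <- estimate_ancestry_supervised(gm, f3),
                 "non-identifiable")
  expect_true(all(abs(as.matrix(est[, c("anc1", "anc2", "anc3")]) -
                        1 / 3) < 1e-12))
})

test_that("EM log-likelihood never decreases and rows stay on the simplex", {
  f <- bn_reference(3, 800, 0.1, 47)
  gm <- mixture_gm(matrix(c(0.3, 0.5, 0.2), 1), f, n = 10, seed = 48)
  gm$dosage[1, 1:100] <- NA   # missing loci are skipped, not fatal
  est <- estimate_ancestry_supervised(gm, f, trace = TRUE)
  for (tr in attr(est, "loglik_trace")) {
    expect_true(all(diff(tr) >= -1e-8))
  }
  q <- as.matrix(est[, c("anc1", "anc2", "anc3")])
  expect_true(all(q >= 0))
  expect_lt(max(abs(rowSums(q) - 1)), 1e-9)
})

test_that("disjoint SNP sets between genotypes and reference error out", {
  f <- bn_reference(2, 50, 0.1, 49)
  colnames(f) <- paste0("other", 1:50)
  gm <- toy_gm(matrix(0:1, 2, 10))
  expect_error(estimate_ancestry_supervised(gm, f), "no overlapping")
})
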