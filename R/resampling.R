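# Resampling controls: bootstrap over the risk-SNP set, size-matched
# random-SNP-set null distributions, and a multi-disease risk-score bias
# scan, each summarized by a z-test.

#' Two-sided normal tail probability for a z statistic
#'
#' @param z a z statistic (vectorized; must be finite).
#' @return p = 2 (1 - Phi(|z|)).
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) abort("z must be finite")
  2 * pnorm(-abs(z))
}

new_z_test <- function(z, p, n, mean, sd, degenerate = FALSE) {
  structure(
    list(z = z, p = p, n = n, mean = mean, sd = sd,
         degenerate = degenerate),
    class = "z_test"
  )
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf("<z_test> z = %.3f, p = %.3g (n = %d)%s\n",
              x$z, x$p, x$n,
              if (x$degenerate) " [degenerate: zero spread]" else ""))
  invisible(x)
}

new_null_distribution <- function(values, kind, seed, observed, z_test) {
  structure(
    list(values = values, n_replicates = length(values), kind = kind,
         seed = seed, observed = observed, z_test = z_test),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> kind = %s, %d replicates, observed = %.4f, z = %.3f, p = %.3g\n",
    x$kind, x$n_replicates, x$observed, x$z_test$z, x$z_test$p
  ))
  invisible(x)
}

# Fixed-model pooled estimates for many resampled SNP index sets at once.
# idx is an n_reps x set_size integer matrix into (y, w).
pooled_over_sets <- function(y, w, idx) {
  wy <- w * y
  rowSums(matrix(wy[idx], nrow = nrow(idx))) /
    rowSums(matrix(w[idx], nrow = nrow(idx)))
}

#' Bootstrap the meta-analysis over the risk-SNP set
#'
#' Resamples the per-SNP log odds ratios with replacement `n_reps` times,
#' recomputing the fixed-effects pooled log OR for each replicate set, and
#' summarizes the bootstrap distribution against zero with
#' z = mean(replicates) / sd(replicates).
#'
#' @param or_table per-SNP results (columns log_or, se).
#' @param n_reps number of bootstrap replicates (default 10,000).
#' @param seed integer seed for the resampling stream.
#' @return list with `null` (a `null_distribution`, kind `"bootstrap"`,
#'   `observed` = full-set fixed meta log OR) and `z_test`. If every
#'   replicate is identical the z is signed infinity with p = 0 and the
#'   result is flagged degenerate.
#' @export
bootstrap_meta <- function(or_table, n_reps = 10000, seed = 1L) {
  if (n_reps < 100) abort("n_reps must be at least 100")
  k <- nrow(or_table)
  if (k < 2) abort("need at least 2 per-SNP results")
  observed <- meta_analyze(or_table, "fixed")$pooled_log_or
  y <- or_table$log_or
  w <- 1 / or_table$se^2
  reps <- with_substream(seed, "bootstrap", {
    vals <- numeric(n_reps)
    chunk <- 2000L
    done <- 0L
    while (done < n_reps) {
      nb <- min(chunk, n_reps - done)
      idx <- matrix(sample.int(k, nb * k, replace = TRUE), nrow = nb)
      vals[(done + 1):(done + nb)] <- pooled_over_sets(y, w, idx)
      done <- done + nb
    }
    vals
  })
  mu <- mean(reps)
  sdev <- sd(reps)
  if (sdev == 0) {
    zt <- new_z_test(sign(mu) * Inf, 0, n_reps, mu, 0, degenerate = TRUE)
  } else {
    z <- mu / sdev
    zt <- new_z_test(z, z_to_p(z), n_reps, mu, sdev)
  }
  nd <- new_null_distribution(reps, "bootstrap", seed, observed, zt)
  list(null = nd, z_test = zt)
}

#' Random size-matched SNP-set null distribution for the meta log OR
#'
#' Draws `n_reps` SNP sets of `set_size` without replacement from a pool of
#' disease-associated SNPs with per-SNP log ORs between the two populations,
#' computes the fixed-effects pooled log OR of each set, and standardizes
#' the observed pooled value against this null:
#' z = (observed - mean(null)) / sd(null).
#'
#' @param pool_or_table per-SNP results for the whole catalog pool (columns
#'   log_or, se); must have at least `set_size` rows.
#' @param set_size SNPs per replicate set (the size of the observed set).
#' @param n_reps number of replicate sets (the headline design uses
#'   500,000; smaller values are Monte-Carlo-stable well below that).
#' @param seed integer seed.
#' @param observed a `meta_result` (or a number): the observed pooled log
#'   OR to standardize.
#' @return list with `null` (a `null_distribution`, kind `"random_set"`)
#'   and `z_test`.
#' @export
random_snpset_null <- function(pool_or_table, set_size, n_reps = 500000,
                               seed = 1L, observed) {
  k_pool <- nrow(pool_or_table)
  if (k_pool < set_size) {
    abort(sprintf("pool has %d SNPs, smaller than set_size %d",
                  k_pool, set_size))
  }
  obs <- if (inherits(observed, "meta_result")) observed$pooled_log_or
         else as.numeric(observed)
  y <- pool_or_table$log_or
  w <- 1 / pool_or_table$se^2
  reps <- with_substream(seed, "random_set", {
    vals <- numeric(n_reps)
    chunk <- 2000L
    done <- 0L
    while (done < n_reps) {
      nb <- min(chunk, n_reps - done)
      idx <- t(replicate(nb, sample.int(k_pool, set_size)))
      vals[(done + 1):(done + nb)] <- pooled_over_sets(y, w, idx)
      done <- done + nb
    }
    vals
  })
  mu <- mean(reps)
  sdev <- sd(reps)
  if (sdev == 0) {
    zt <- new_z_test(sign(obs - mu) * Inf, 0, n_reps, mu, 0,
                     degenerate = TRUE)
  } else {
    z <- (obs - mu) / sdev
    zt <- new_z_test(z, z_to_p(z), n_reps, mu, sdev)
  }
  nd <- new_null_distribution(reps, "random_set", seed, obs, zt)
  list(null = nd, z_test = zt)
}

#' Multi-disease polygenic-score difference scan
#'
#' For every trait SNP set, aligns both genotype matrices to the set,
#' computes the unweighted polygenic risk score in each population sample,
#' and records the difference of population means (A - B). A systematic
#' allele-frequency bias between the populations would shift the whole
#' distribution of differences away from zero; the summary z-test is
#' z = mean(differences) / sd(differences) across traits.
#'
#' @param gm_a,gm_b genotype matrices for the two population samples.
#' @param trait_sets named list of `risk_snp_set` objects (e.g. from
#'   [multi_trait_split()]).
#' @return list with `table` (tibble: trait, n_snps, mean_prs_a,
#'   mean_prs_b, difference) and `z_test`. Traits with zero alignable SNPs
#'   are excluded and logged.
#' @export
disease_scan <- function(gm_a, gm_b, trait_sets) {
  rows <- purrr::imap(trait_sets, function(rs, tr) {
    al_a <- tryCatch(suppressMessages(align_risk_alleles(gm_a, rs)),
                     error = function(e) NULL)
    al_b <- tryCatch(suppressMessages(align_risk_alleles(gm_b, rs)),
                     error = function(e) NULL)
    if (is.null(al_a) || is.null(al_b)) return(NULL)
    pa <- suppressMessages(polygenic_risk_score(al_a))
    pb <- suppressMessages(polygenic_risk_score(al_b))
    tibble(
      trait = tr,
      n_snps = ncol(al_a$dosage),
      mean_prs_a = mean(pa$score, na.rm = TRUE),
      mean_prs_b = mean(pb$score, na.rm = TRUE)
    )
  })
  dropped <- names(trait_sets)[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    log_note("disease_scan: excluding trait(s) with no alignable SNPs: ",
             paste(dropped, collapse = ", "))
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) < 2) abort("disease_scan needs at least 2 usable traits")
  tab$difference <- tab$mean_prs_a - tab$mean_prs_b
  sdev <- sd(tab$difference)
  mu <- mean(tab$difference)
  if (sdev == 0) {
    zt <- new_z_test(if (mu == 0) 0 else sign(mu) * Inf,
                     if (mu == 0) 1 else 0,
                     nrow(tab), mu, 0, degenerate = TRUE)
  } else {
    z <- mu / sdev
    zt <- new_z_test(z, z_to_p(z), nrow(tab), mu, sdev)
  }
  list(table = tab, z_test = zt)
}
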