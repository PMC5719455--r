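# Core risk mathematics: per-SNP risk-allele log odds ratios between two
# populations, fixed- and random-effects meta-analysis, and the unweighted
# normalized polygenic risk score.

#' Per-SNP risk-allele log odds ratio between two populations
#'
#' For one SNP with risk/non-risk allele counts (a, b) in population A and
#' (c, d) in population B, the relative genetic risk is
#' log OR = ln((a/b) / (c/d)); positive values mean a higher risk-allele
#' burden in A. If any cell is zero, 0.5 is added to all four counts
#' (Haldane-Anscombe) and the result is flagged `corrected`. The standard
#' error is Woolf's sqrt(1/a + 1/b + 1/c + 1/d) over the (possibly
#' corrected) counts, and the 95% CI is log OR +/- 1.96 se. `significant`
#' means the CI excludes 0.
#'
#' @param risk_a,nonrisk_a,risk_b,nonrisk_b allele counts (vectorized).
#' @return tibble: log_or, se, ci_low, ci_high, significant, corrected.
#' @export
snp_log_or <- function(risk_a, nonrisk_a, risk_b, nonrisk_b) {
  n <- length(risk_a)
  stopifnot(length(nonrisk_a) == n, length(risk_b) == n,
            length(nonrisk_b) == n)
  if (any(c(risk_a, nonrisk_a, risk_b, nonrisk_b) < 0, na.rm = TRUE)) {
    abort("allele counts must be non-negative")
  }
  corrected <- risk_a == 0 | nonrisk_a == 0 | risk_b == 0 | nonrisk_b == 0
  a <- risk_a + 0.5 * corrected
  b <- nonrisk_a + 0.5 * corrected
  cc <- risk_b + 0.5 * corrected
  dd <- nonrisk_b + 0.5 * corrected
  # grouped so that swapping the two populations negates log_or and leaves
  # se bit-identical (floating-point addition is commutative)
  log_or <- (log(a) + log(dd)) - (log(b) + log(cc))
  se <- sqrt((1 / a + 1 / b) + (1 / cc + 1 / dd))
  ci_low <- log_or - 1.96 * se
  ci_high <- log_or + 1.96 * se
  tibble(
    log_or = log_or, se = se, ci_low = ci_low, ci_high = ci_high,
    significant = ci_low > 0 | ci_high < 0, corrected = corrected
  )
}

#' Per-SNP log odds ratios from a two-population frequency table
#'
#' Joins the [allele_frequencies()] records of two populations by rsID and
#' computes [snp_log_or()] for every shared SNP. SNPs undefined (zero
#' non-missing calls) in either population are skipped with a log message.
#'
#' @param freqs tibble from [allele_frequencies()].
#' @param pop_a,pop_b population labels; the ratio is A over B.
#' @return an `or_table` tibble: rsid, log_or, se, ci_low, ci_high,
#'   significant, corrected.
#' @export
snp_log_or_table <- function(freqs, pop_a, pop_b) {
  fa <- dplyr::filter(freqs, .data$population == pop_a)
  fb <- dplyr::filter(freqs, .data$population == pop_b)
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    abort("one of the requested populations has no frequency records")
  }
  j <- dplyr::inner_join(fa, fb, by = "rsid", suffix = c("_a", "_b"))
  usable <- !is.na(j$risk_allele_freq_a) & !is.na(j$risk_allele_freq_b)
  if (any(!usable)) {
    log_note("snp_log_or_table: skipping ", sum(!usable),
             " SNP(s) undefined in one population")
  }
  j <- j[usable, , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(rsid = j$rsid),
    snp_log_or(j$risk_allele_count_a, j$nonrisk_allele_count_a,
               j$risk_allele_count_b, j$nonrisk_allele_count_b)
  )
  structure(out, pop_a = pop_a, pop_b = pop_b,
            class = c("or_table", class(out)))
}

#' Fixed- or random-effects meta-analysis of per-SNP log odds ratios
#'
#' Fixed model: inverse-variance weights w_i = 1/se_i^2, pooled estimate
#' sum(w y)/sum(w), se 1/sqrt(sum w). Random model: DerSimonian-Laird
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)) with the fixed
#' weights, then inverse-variance pooling with weights 1/(se_i^2 + tau^2).
#' Q is Cochran's heterogeneity statistic about the fixed pooled value.
#' The p-value is two-sided normal on pooled/se (k is large in the intended
#' use, so no small-sample t reference is applied).
#'
#' @param or_table tibble with columns log_or and se (e.g. from
#'   [snp_log_or_table()]); needs at least 2 rows.
#' @param model `"fixed"` or `"random"`.
#' @return a `meta_result` object (list): model, pooled_log_or, se, ci_low,
#'   ci_high, p_value, tau2, Q, k.
#' @export
meta_analyze <- function(or_table, model = c("fixed", "random")) {
  model <- match.arg(model)
  y <- or_table$log_or
  s2 <- or_table$se^2
  k <- length(y)
  if (k < 2) abort("meta-analysis needs at least 2 per-SNP results")
  if (any(!is.finite(y)) || any(!is.finite(s2)) || any(s2 <= 0)) {
    abort("log_or and se must be finite with se > 0")
  }
  w <- 1 / s2
  pooled_fixed <- sum(w * y) / sum(w)
  q_stat <- sum(w * (y - pooled_fixed)^2)
  tau2 <- max(0, (q_stat - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (model == "fixed") {
    pooled <- pooled_fixed
    se <- sqrt(1 / sum(w))
  } else {
    wr <- 1 / (s2 + tau2)
    pooled <- sum(wr * y) / sum(wr)
    se <- sqrt(1 / sum(wr))
  }
  z <- pooled / se
  structure(
    list(
      model = model, pooled_log_or = pooled, se = se,
      ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
      p_value = 2 * pnorm(-abs(z)), tau2 = tau2, Q = q_stat, k = k
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s-effects pooled log OR = %.4f (95%% CI %.4f..%.4f), p = %.3g, k = %d, tau2 = %.4g\n",
    x$model, x$pooled_log_or, x$ci_low, x$ci_high, x$p_value, x$k, x$tau2
  ))
  invisible(x)
}

#' Unweighted normalized polygenic risk score
#'
#' Per individual, the score is the sum of risk-allele dosages over SNPs
#' with basecalls divided by twice the number of called SNPs — the fraction
#' of callable alleles that are risk alleles, in [0, 1]. Missing SNPs
#' contribute to neither numerator nor denominator. Association effect
#' sizes are never used: the SNP sets this score is designed for pool
#' heterogeneous studies whose effect sizes are not comparable.
#'
#' @param gm a [geno_matrix()] already aligned so the counted allele is the
#'   risk allele at every SNP (see [align_risk_alleles()]).
#' @return a `prs_result` tibble: sample, population, score,
#'   n_called_alleles. Samples with zero called SNPs get `NA` scores and
#'   are logged.
#' @export
polygenic_risk_score <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  num <- rowSums(gm$dosage, na.rm = TRUE)
  n_called <- 2 * rowSums(!is.na(gm$dosage))
  score <- unname(ifelse(n_called > 0, num / n_called, NA_real_))
  if (any(n_called == 0)) {
    log_note("polygenic_risk_score: ", sum(n_called == 0),
             " sample(s) with zero called SNPs; score undefined")
  }
  out <- tibble(
    sample = gm$samples$sample,
    population = gm$samples$population,
    score = score,
    n_called_alleles = as.integer(n_called)
  )
  structure(out, class = c("prs_result", class(out)))
}
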