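# Population-genetic primitives: allele frequencies, LD pruning,
# allele-sharing distances, classical MDS projection, and supervised
# ancestry-fraction estimation.

#' Per-population counted-allele frequencies
#'
#' Counts copies of each variant's counted allele (the risk allele, after
#' [align_risk_alleles()]) over non-missing calls. Missing calls contribute
#' to neither the numerator nor the denominator. Populations with zero
#' non-missing calls at a SNP get an undefined (NA) frequency and are
#' logged; downstream odds-ratio code skips them.
#'
#' @param gm a [geno_matrix()].
#' @param by_population split counts by the sample population label
#'   (default TRUE); otherwise a single pooled population `"all"`.
#' @return tibble: population, rsid, risk_allele, risk_allele_count,
#'   nonrisk_allele_count, risk_allele_freq.
#' @export
allele_frequencies <- function(gm, by_population = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  pops <- if (by_population) gm$samples$population else
    rep("all", nrow(gm$dosage))
  out <- lapply(unique(pops), function(p) {
    d <- gm$dosage[pops == p, , drop = FALSE]
    called <- colSums(!is.na(d))
    risk <- colSums(d, na.rm = TRUE)
    nonrisk <- 2 * called - risk
    tibble(
      population = p,
      rsid = gm$variants$rsid,
      risk_allele = gm$variants$counted_allele,
      risk_allele_count = as.double(risk),
      nonrisk_allele_count = as.double(nonrisk),
      risk_allele_freq = unname(ifelse(called > 0, risk / (2 * called),
                                       NA_real_))
    )
  })
  out <- dplyr::bind_rows(out)
  n_undef <- sum(is.na(out$risk_allele_freq))
  if (n_undef > 0) {
    log_note("allele_frequencies: ", n_undef,
             " population x SNP cell(s) with zero non-missing calls")
  }
  out
}

#' Sliding-window LD pruning on genotype dosages
#'
#' Windows of `window_snps` variants advance by `step_snps`; within a
#' window, for any pair of retained SNPs whose squared dosage correlation
#' exceeds `r2_threshold`, the later-positioned SNP is removed. Monomorphic
#' SNPs have no defined correlation; they are retained, never tested, and
#' logged.
#'
#' The default threshold applies the conventional published pruning cutoff
#' of 0.05 to the squared correlation; whether such cutoffs are meant on r
#' or r-squared is often ambiguous in the literature, so the parameter is
#' explicit.
#'
#' @param gm a [geno_matrix()] with at least 2 variants.
#' @param r2_threshold squared-correlation cutoff in (0, 1].
#' @param window_snps,step_snps window size and stride in SNPs.
#' @return character vector of retained rsIDs, in original variant order.
#' @export
ld_prune <- function(gm, r2_threshold = 0.05, window_snps = 50,
                     step_snps = 5) {
  stopifnot(inherits(gm, "geno_matrix"))
  m <- ncol(gm$dosage)
  if (m < 2) abort("ld_prune needs at least 2 variants")
  vars <- apply(gm$dosage, 2, var, na.rm = TRUE)
  mono <- which(is.na(vars) | vars == 0)
  if (length(mono) > 0) {
    log_note("ld_prune: ", length(mono),
             " monomorphic SNP(s) retained untested")
  }
  keep <- rep(TRUE, m)
  testable <- setdiff(seq_len(m), mono)
  starts <- seq(1L, m, by = step_snps)
  for (s in starts) {
    win <- intersect(s:min(s + window_snps - 1L, m), testable)
    win <- win[keep[win]]
    if (length(win) < 2) next
    cc <- suppressWarnings(
      cor(gm$dosage[, win, drop = FALSE], use = "pairwise.complete.obs")
    )
    for (a in seq_along(win)) {
      if (!keep[win[a]]) next
      for (b in seq_along(win)) {
        if (b <= a || !keep[win[b]]) next
        r2 <- cc[a, b]^2
        if (!is.na(r2) && r2 > r2_threshold) keep[win[b]] <- FALSE
      }
    }
  }
  gm$variants$rsid[keep]
}

#' Pairwise allele-sharing distance matrix
#'
#' For each sample pair, over loci called in both: per-locus similarity
#' s = 1 - |d_i - d_j| / 2 (identical genotypes 1, heterozygote vs
#' homozygote 0.5, opposite homozygotes 0); the distance is 1 - mean(s).
#' A pair sharing zero called loci is an error naming the pair.
#'
#' @param gm a [geno_matrix()].
#' @return symmetric N x N matrix in [0, 1] with zero diagonal and
#'   sample-ID dimnames.
#' @export
allele_sharing_distance <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  d <- gm$dosage
  called <- !is.na(d)
  # sum over joint loci of |d_i - d_j| via dosage-class indicator products
  g0 <- (called & d == 0) * 1
  g1 <- (called & d == 1) * 1
  g2 <- (called & d == 2) * 1
  abs_sum <- tcrossprod(g0, g1) + tcrossprod(g1, g0) +
    tcrossprod(g1, g2) + tcrossprod(g2, g1) +
    2 * (tcrossprod(g0, g2) + tcrossprod(g2, g0))
  n_joint <- tcrossprod(called * 1)
  if (any(n_joint == 0)) {
    bad <- which(n_joint == 0, arr.ind = TRUE)[1, ]
    abort(paste0("samples share zero jointly-called loci: ",
                 gm$samples$sample[bad[1]], " and ",
                 gm$samples$sample[bad[2]]))
  }
  dist <- abs_sum / (2 * n_joint)
  diag(dist) <- 0
  dimnames(dist) <- list(gm$samples$sample, gm$samples$sample)
  dist
}

#' Project a distance matrix to low dimensions by classical MDS
#'
#' Classical (Torgerson) multidimensional scaling: double-centre the squared
#' distances and scale the leading eigenvectors by the square root of their
#' eigenvalues. Requested dimensions beyond the positive eigenvalues come
#' back as zero coordinates with a warning. Column signs are fixed by making
#' each dimension's largest-magnitude loading positive, so coordinates are
#' reproducible across platforms.
#'
#' @param dm symmetric distance matrix with sample-ID dimnames.
#' @param n_dims number of output dimensions (default 2).
#' @return tibble: sample, MDS1..MDSk.
#' @export
project_mds <- function(dm, n_dims = 2) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8) {
    abort("distance matrix must be symmetric")
  }
  fit <- suppressWarnings(cmdscale(dm, k = n_dims, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < n_dims) {
    got <- if (is.null(pts)) 0 else ncol(pts)
    warn(sprintf(
      "only %d positive-eigenvalue dimension(s) available; padding with zeros",
      got
    ))
    pad <- matrix(0, nrow(dm), n_dims - got)
    pts <- cbind(pts, pad)
  }
  for (j in seq_len(ncol(pts))) {
    if (any(pts[, j] != 0)) {
      lead <- which.max(abs(pts[, j]))
      if (pts[lead, j] < 0) pts[, j] <- -pts[, j]
    }
  }
  colnames(pts) <- paste0("MDS", seq_len(n_dims))
  dplyr::bind_cols(
    tibble(sample = rownames(dm) %||% paste0("s", seq_len(nrow(dm)))),
    as_tibble(pts)
  )
}

#' Supervised ancestry-fraction estimation from reference frequencies
#'
#' For each individual, maximizes the binomial log-likelihood of its
#' counted-allele dosages under a K-way admixture of fixed reference allele
#' frequencies,
#' sum_m d_m log(sum_k q_k p_km) + (2 - d_m) log(sum_k q_k (1 - p_km)),
#' over the probability simplex, using EM-style multiplicative updates from
#' a uniform start. Missing loci are skipped. The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param gm a [geno_matrix()].
#' @param reference_freqs K x M matrix of counted-allele frequencies with
#'   ancestry labels as rownames and rsIDs as colnames; intersected with the
#'   genotype variants by rsID and clipped into [1e-4, 1 - 1e-4].
#' @param tol stop when the largest fraction change falls below this
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1000); non-converged individuals
#'   are returned at the last iterate and flagged.
#' @param trace if TRUE, attach per-individual log-likelihood trajectories
#'   as attribute `loglik_trace`.
#' @return tibble: sample, population, one fraction column per ancestry
#'   label (rows on the simplex), converged, loglik.
#' @export
estimate_ancestry_supervised <- function(gm, reference_freqs, tol = 1e-6,
                                         max_iter = 1000, trace = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  P <- as.matrix(reference_freqs)
  if (is.null(colnames(P))) abort("reference_freqs needs rsID colnames")
  labels <- rownames(P) %||% paste0("anc", seq_len(nrow(P)))
  shared <- intersect(gm$variants$rsid, colnames(P))
  if (length(shared) == 0) {
    abort("no overlapping SNPs between genotypes and reference frequencies")
  }
  P <- P[, shared, drop = FALSE]
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)
  K <- nrow(P)
  if (K >= 2 && max(apply(P, 2, function(x) diff(range(x)))) < 1e-12) {
    warn("all reference populations have identical frequencies; ancestry is non-identifiable, returning uniform fractions")
    q <- matrix(1 / K, nrow(gm$dosage), K)
    out <- dplyr::bind_cols(
      gm$samples,
      as_tibble(q, .name_repair = ~labels),
      tibble(converged = TRUE, loglik = NA_real_)
    )
    return(out)
  }
  D <- gm$dosage[, match(shared, gm$variants$rsid), drop = FALSE]
  n <- nrow(D)
  Q <- matrix(NA_real_, n, K)
  converged <- logical(n)
  loglik <- numeric(n)
  traces <- if (trace) vector("list", n) else NULL
  for (i in seq_len(n)) {
    d <- D[i, ]
    ok <- !is.na(d)
    di <- d[ok]
    Pi <- P[, ok, drop = FALSE]
    m <- length(di)
    if (m == 0) {
      Q[i, ] <- 1 / K
      converged[i] <- FALSE
      loglik[i] <- NA_real_
      next
    }
    q <- rep(1 / K, K)
    ll_old <- -Inf
    tr <- numeric(0)
    for (it in seq_len(max_iter)) {
      f <- as.vector(q %*% Pi)          # mixture freq per locus
      ll <- sum(di * log(f) + (2 - di) * log1p(-f))
      if (trace) tr <- c(tr, ll)
      resp <- Pi %*% (di / f) + (1 - Pi) %*% ((2 - di) / (1 - f))
      q_new <- q * as.vector(resp) / (2 * m)
      q_new <- q_new / sum(q_new)       # guard against rounding drift
      delta <- max(abs(q_new - q))
      q <- q_new
      if (delta < tol) {
        converged[i] <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    Q[i, ] <- q
    loglik[i] <- ll_old
    if (trace) traces[[i]] <- tr
  }
  if (any(!converged)) {
    log_note("estimate_ancestry_supervised: ", sum(!converged),
             " individual(s) did not converge within max_iter")
  }
  out <- dplyr::bind_cols(
    gm$samples,
    as_tibble(Q, .name_repair = ~labels),
    tibble(converged = converged, loglik = loglik)
  )
  if (trace) attr(out, "loglik_trace") <- traces
  out
}
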