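# Catalog filtering: extract lead trait-associated SNPs from a
# GWAS-catalog-style table under three rules: minimum study size, strongest
# association per locus (distance-based clumping), and an association
# p-value threshold.

new_risk_snp_set <- function(tbl, trait) {
  tbl <- as_tibble(tbl)
  structure(tbl, trait = trait,
            class = c("risk_snp_set", class(tbl)))
}

#' Filter a GWAS-catalog table to a set of lead risk SNPs
#'
#' Keeps entries for `trait` that (1) come from a study of at least
#' `min_study_snps` genotyped SNPs and (3) have association
#' p-value < `p_threshold`; rule (2) — the SNP with the strongest
#' association for its genomic locus — is applied by greedy distance
#' clumping: survivors are sorted by ascending p-value (ties broken by
#' larger study, then rsid) and each SNP is accepted unless an
#' already-accepted SNP lies within `clump_window_bp` on the same
#' chromosome.
#'
#' @param catalog tibble of catalog entries (see [read_catalog()] schema).
#' @param trait trait label to extract.
#' @param p_threshold association p-value cutoff (default 1e-5).
#' @param min_study_snps minimum genotyped SNPs in the reporting study
#'   (default 100,000).
#' @param clump_window_bp locus window in base pairs (default 1 Mb).
#' @return a `risk_snp_set` tibble (rsid, chrom, pos, risk_allele, p_value)
#'   sorted by (chrom, pos), with attributes `trait` and `audit` (a tibble
#'   recording the rule that removed every rejected row). Zero survivors
#'   give a zero-row set with a warning, never a silent success.
#' @export
filter_catalog <- function(catalog, trait,
                           p_threshold = 1e-5,
                           min_study_snps = 100000,
                           clump_window_bp = 1000000) {
  catalog <- as_tibble(catalog)
  need <- c("rsid", "chrom", "pos", "trait", "risk_allele", "p_value",
            "study_snp_count")
  missing_cols <- setdiff(need, names(catalog))
  if (length(missing_cols) > 0) {
    abort(paste("catalog is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  rows <- dplyr::filter(catalog, .data$trait == !!trait)
  if (nrow(rows) == 0) {
    warn(paste0("no catalog entries for trait '", trait, "'"))
    return(new_risk_snp_set(
      tibble(rsid = character(), chrom = character(), pos = integer(),
             risk_allele = character(), p_value = double()),
      trait = trait
    ))
  }
  audit <- list()
  fail_study <- rows$study_snp_count < min_study_snps
  audit$study <- tibble(rsid = rows$rsid[fail_study], rule = "min_study_snps")
  rows <- rows[!fail_study, , drop = FALSE]
  fail_p <- rows$p_value >= p_threshold
  audit$p <- tibble(rsid = rows$rsid[fail_p], rule = "p_threshold")
  rows <- rows[!fail_p, , drop = FALSE]

  # greedy clumping; canonical order makes the result input-order invariant
  ord <- order(rows$p_value, -rows$study_snp_count, rows$rsid)
  rows <- rows[ord, , drop = FALSE]
  keep <- logical(nrow(rows))
  clumped <- character()
  for (i in seq_len(nrow(rows))) {
    acc <- which(keep)
    blocked <- any(
      rows$chrom[acc] == rows$chrom[i] &
        abs(rows$pos[acc] - rows$pos[i]) <= clump_window_bp
    )
    if (blocked) clumped <- c(clumped, rows$rsid[i]) else keep[i] <- TRUE
  }
  audit$clump <- tibble(rsid = clumped, rule = "clumped")
  out <- rows[keep, c("rsid", "chrom", "pos", "risk_allele", "p_value")]
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  if (nrow(out) == 0) warn(paste0("all entries for trait '", trait,
                                  "' were filtered out"))
  res <- new_risk_snp_set(out, trait = trait)
  attr(res, "audit") <- dplyr::bind_rows(audit)
  res
}

#' Split a multi-trait catalog into per-trait lead-SNP sets
#'
#' Applies [filter_catalog()] independently to every trait present; traits
#' whose filtered set comes back empty are reported and omitted.
#'
#' @inheritParams filter_catalog
#' @return named list of `risk_snp_set` objects, one per surviving trait.
#' @export
multi_trait_split <- function(catalog,
                              p_threshold = 1e-5,
                              min_study_snps = 100000,
                              clump_window_bp = 1000000) {
  catalog <- as_tibble(catalog)
  traits <- unique(catalog$trait)
  sets <- lapply(traits, function(tr) {
    suppressWarnings(filter_catalog(
      catalog, tr, p_threshold = p_threshold,
      min_study_snps = min_study_snps, clump_window_bp = clump_window_bp
    ))
  })
  names(sets) <- traits
  empty <- vapply(sets, function(s) nrow(s) == 0, logical(1))
  if (any(empty)) {
    log_note("multi_trait_split: omitting traits with empty filtered sets: ",
             paste(traits[empty], collapse = ", "))
  }
  sets[!empty]
}
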