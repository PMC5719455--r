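#' Construct a genotype matrix object
#'
#' The central genotype container: an N samples by M variants matrix of
#' counted-allele dosages in \{0, 1, 2\} with `NA` for missing calls, plus
#' sample metadata (population labels) and variant metadata (rsID,
#' chromosome, 1-based position, ref/alt alleles, and which allele the
#' dosage counts).
#'
#' @param dosage integer matrix, samples x variants, entries 0/1/2/NA.
#' @param samples tibble with columns `sample` (unique IDs) and `population`.
#' @param variants tibble with columns `rsid` (unique), `chrom`, `pos`,
#'   `ref`, `alt`, `counted_allele` (one of ref/alt; dosage counts copies of
#'   this allele).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, samples, variants) {
  dosage <- as.matrix(dosage)
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  if (!all(c("sample", "population") %in% names(samples))) {
    abort("`samples` needs columns: sample, population")
  }
  need <- c("rsid", "chrom", "pos", "ref", "alt", "counted_allele")
  if (!all(need %in% names(variants))) {
    abort(paste("`variants` needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants)) {
    abort("dosage dimensions do not match samples/variants metadata")
  }
  if (anyDuplicated(samples$sample)) abort("sample IDs must be unique")
  if (anyDuplicated(variants$rsid)) abort("variant rsIDs must be unique")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  if (any(variants$pos < 1)) abort("positions are 1-based and must be >= 1")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) abort("non-missing dosages must be 0, 1 or 2")
  dimnames(dosage) <- list(samples$sample, variants$rsid)
  structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%.1f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * miss
  ))
  pops <- table(x$samples$population)
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a [geno_matrix()].
#' @param samples character sample IDs or logical/integer index; NULL keeps all.
#' @param variants character rsIDs or logical/integer index; NULL keeps all.
#' @return a `geno_matrix` restricted (and reordered) to the selection.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- seq_len(nrow(gm$dosage))
  vi <- seq_len(ncol(gm$dosage))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples$sample) else si[samples]
    if (anyNA(si)) abort("unknown sample IDs in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, gm$variants$rsid) else vi[variants]
    if (anyNA(vi)) abort("unknown variant rsIDs in subset")
  }
  geno_matrix(gm$dosage[si, vi, drop = FALSE],
              gm$samples[si, ], gm$variants[vi, ])
}

#' Bind two genotype matrices that share the same variants
#'
#' @param a,b `geno_matrix` objects over an identical variant table.
#' @return a combined `geno_matrix` with a's samples followed by b's.
#' @export
gm_bind_samples <- function(a, b) {
  stopifnot(inherits(a, "geno_matrix"), inherits(b, "geno_matrix"))
  if (!identical(a$variants$rsid, b$variants$rsid)) {
    abort("genotype matrices do not share an identical variant set")
  }
  geno_matrix(rbind(a$dosage, b$dosage),
              dplyr::bind_rows(a$samples, b$samples), a$variants)
}

#' Genotype dosages as a tidy tibble
#'
#' One row per (sample, variant) call; missing calls are kept as `NA`.
#'
#' @param gm a [geno_matrix()].
#' @return a tibble with columns sample, population, rsid, dosage.
#' @export
gm_tidy <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  tibble(
    sample = rep(gm$samples$sample, times = ncol(gm$dosage)),
    population = rep(gm$samples$population, times = ncol(gm$dosage)),
    rsid = rep(gm$variants$rsid, each = nrow(gm$dosage)),
    dosage = as.vector(gm$dosage)
  )
}
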