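# Readers and writers for the standard formats the pipeline touches:
# VCF v4.2 (GT only, biallelic), PLINK-text .ped/.map, and the catalog TSV.

#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.2 file (GT field, biallelic records) into a
#' [geno_matrix()] whose dosage counts copies of the alternate allele;
#' `./.` calls become missing. Multi-allelic records are skipped with a
#' log message by default, or rejected outright.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param populations optional named character vector mapping sample ID to
#'   population label; unlisted samples get `"unknown"`.
#' @param on_multiallelic `"skip"` (default) or `"error"`.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, populations = NULL,
                     on_multiallelic = c("skip", "error")) {
  on_multiallelic <- match.arg(on_multiallelic)
  if (!file.exists(path)) abort(paste("no such VCF file:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% character()) | is.na(fix$ALT)
  if (any(multi)) {
    if (on_multiallelic == "error") {
      abort(paste("multi-allelic records at rows:",
                  paste(which(multi), collapse = ", ")))
    }
    log_note("read_vcf: skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # alt-allele dosage from the GT string; "." on either side => missing
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dos[is.na(gt) | a1 == "." | a2 == "."] <- NA_integer_
  dosage <- t(matrix(dos, nrow = nrow(fix),
                     dimnames = list(NULL, colnames(gt))))
  ids <- colnames(gt)
  pops <- if (is.null(populations)) {
    rep("unknown", length(ids))
  } else {
    unname(ifelse(ids %in% names(populations), populations[ids], "unknown"))
  }
  rsid <- fix$ID
  rsid[is.na(rsid) | rsid == "."] <- paste0(
    fix$CHROM[is.na(rsid) | rsid == "."], ":",
    fix$POS[is.na(rsid) | rsid == "."]
  )
  geno_matrix(
    dosage,
    samples = tibble(sample = ids, population = pops),
    variants = tibble(
      rsid = rsid, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, counted_allele = fix$ALT
    )
  )
}

#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' Emits GT-only records with 1-based positions. Dosages are converted back
#' to alternate-allele genotype calls (`0/0`, `0/1`, `1/1`, `./.`)
#' regardless of which allele the in-memory dosage counts.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  vt <- gm$variants
  alt_dos <- t(gm$dosage)
  flip <- vt$counted_allele != vt$alt
  alt_dos[flip, ] <- 2L - alt_dos[flip, , drop = FALSE]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(alt_dos)], nrow = nrow(vt))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample), collapse = "\t")
  )
  body <- paste(
    vt$chrom, vt$pos, vt$rsid, vt$ref, vt$alt, ".", ".", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read PLINK-text .ped/.map files into a genotype matrix
#'
#' The counted allele at each variant defaults to the first non-missing
#' allele observed in the .ped file; a `0 0` allele pair is a missing call.
#'
#' @param ped_path path to the .ped file (FID IID PAT MAT SEX PHENO then two
#'   allele columns per variant).
#' @param map_path path to the .map file (chrom, rsid, genetic distance,
#'   position).
#' @param counted_alleles optional named character vector (rsid -> allele)
#'   overriding the counted-allele choice.
#' @return a [geno_matrix()]; population labels are taken from the family ID
#'   column.
#' @export
read_plink_text <- function(ped_path, map_path, counted_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) != 4) abort(".map must have 4 columns")
  names(map) <- c("chrom", "rsid", "cm", "pos")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(toks)
  if (length(unique(widths)) != 1) {
    abort(paste0("ragged .ped rows: widths ", paste(unique(widths),
                                                    collapse = ", ")))
  }
  if (widths[1] != 6 + 2 * m) {
    abort(sprintf(".ped has %d allele columns but .map lists %d variants",
                  widths[1] - 6, m))
  }
  ped <- do.call(rbind, toks)
  fam <- ped[, 1]
  iid <- ped[, 2]
  alle <- ped[, -(1:6), drop = FALSE]
  a1 <- alle[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- alle[, seq(2, 2 * m, by = 2), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  dosage <- matrix(NA_integer_, nrow(ped), m)
  counted <- character(m)
  other <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    seen <- unique(obs[!is.na(obs)])
    counted[j] <- if (!is.null(counted_alleles) &&
                      map$rsid[j] %in% names(counted_alleles)) {
      counted_alleles[[map$rsid[j]]]
    } else if (length(seen) > 0) seen[1] else "N"
    other[j] <- setdiff(seen, counted[j])[1]
    if (is.na(other[j])) other[j] <- if (counted[j] == "A") "N" else "A"
    called <- !is.na(a1[, j]) & !is.na(a2[, j])
    dosage[called, j] <- (a1[called, j] == counted[j]) +
      (a2[called, j] == counted[j])
  }
  geno_matrix(
    dosage,
    samples = tibble(sample = iid, population = fam),
    variants = tibble(
      rsid = map$rsid, chrom = map$chrom, pos = as.integer(map$pos),
      ref = other, alt = counted, counted_allele = counted
    )
  )
}

#' Write a genotype matrix as PLINK-text .ped/.map files
#'
#' @param gm a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, a list of both paths.
#' @export
write_plink_text <- function(gm, ped_path, map_path) {
  stopifnot(inherits(gm, "geno_matrix"))
  vt <- gm$variants
  utils::write.table(
    data.frame(vt$chrom, vt$rsid, 0, vt$pos),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  counted <- vt$counted_allele
  other <- ifelse(counted == vt$alt, vt$ref, vt$alt)
  n <- nrow(gm$dosage)
  rows <- vapply(seq_len(n), function(i) {
    d <- gm$dosage[i, ]
    one <- ifelse(is.na(d), "0", ifelse(d >= 1, counted, other))
    two <- ifelse(is.na(d), "0", ifelse(d == 2, counted, other))
    paste(c(gm$samples$population[i], gm$samples$sample[i], "0", "0", "0",
            "-9", rbind(one, two)), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

#' Read a GWAS-catalog-style TSV
#'
#' Expects the tab-separated schema: rsid, chrom, pos, trait, risk_allele,
#' p_value, study_snp_count, study_id. Rows with unparseable p-values or an
#' absent risk allele are logged and dropped.
#'
#' @param path TSV path.
#' @return a typed catalog tibble.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste("no such catalog file:", path))
  need <- c("rsid", "chrom", "pos", "trait", "risk_allele", "p_value",
            "study_snp_count", "study_id")
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  missing_cols <- setdiff(need, header)
  if (length(missing_cols) > 0) {
    abort(paste("catalog is missing required columns:",
                paste(missing_cols, collapse = ", ")))
  }
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      rsid = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), trait = readr::col_character(),
      risk_allele = readr::col_character(), p_value = readr::col_double(),
      study_snp_count = readr::col_integer(),
      study_id = readr::col_character()
    )
  )
  need <- c("rsid", "chrom", "pos", "trait", "risk_allele", "p_value",
            "study_snp_count", "study_id")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste("catalog is missing required columns:",
                paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(tbl$p_value) | tbl$p_value <= 0 | tbl$p_value > 1 |
    is.na(tbl$risk_allele) | tbl$risk_allele == ""
  if (any(bad)) {
    log_note("read_catalog: dropping ", sum(bad),
             " row(s) with unparseable p-value or absent risk allele")
    tbl <- tbl[!bad, , drop = FALSE]
  }
  tbl
}

#' Write a catalog or risk-SNP-set tibble as TSV
#'
#' @param x a tibble (catalog or `risk_snp_set`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Align a genotype matrix to a risk-SNP set
#'
#' Restricts the matrix to risk SNPs found by rsID and re-expresses every
#' dosage as a count of the catalog risk allele: if the risk allele is the
#' currently counted allele the dosage is kept; if it is the other allele of
#' the pair the dosage is flipped (d -> 2 - d, missing stays missing); if it
#' matches neither allele the SNP is dropped with a log message (this
#' includes strand-ambiguous mismatches — no strand flipping is attempted).
#' Output variant order follows the risk set.
#'
#' @param gm a [geno_matrix()].
#' @param risk_set a `risk_snp_set` from [filter_catalog()] (or any tibble
#'   with rsid and risk_allele columns).
#' @return a [geno_matrix()] whose counted allele is the risk allele at
#'   every retained SNP.
#' @export
align_risk_alleles <- function(gm, risk_set) {
  stopifnot(inherits(gm, "geno_matrix"))
  rs <- as_tibble(risk_set)
  idx <- match(rs$rsid, gm$variants$rsid)
  found <- !is.na(idx)
  if (!any(found)) abort("no risk SNPs found in the genotype matrix")
  if (any(!found)) {
    log_note("align_risk_alleles: ", sum(!found),
             " risk SNP(s) absent from genotypes")
  }
  rs <- rs[found, , drop = FALSE]
  idx <- idx[found]
  vt <- gm$variants[idx, ]
  keep_as_is <- rs$risk_allele == vt$counted_allele
  other <- ifelse(vt$counted_allele == vt$alt, vt$ref, vt$alt)
  flip <- !keep_as_is & rs$risk_allele == other
  drop <- !keep_as_is & !flip
  if (any(drop)) {
    log_note("align_risk_alleles: dropping ", sum(drop),
             " SNP(s) whose risk allele matches neither genotype allele: ",
             paste(head(rs$rsid[drop], 5), collapse = ", "))
  }
  sel <- which(!drop)
  if (length(sel) == 0) abort("no risk SNPs alignable to genotype alleles")
  idx <- idx[sel]
  dosage <- gm$dosage[, idx, drop = FALSE]
  flip_sel <- flip[sel]
  dosage[, flip_sel] <- 2L - dosage[, flip_sel, drop = FALSE]
  vt <- gm$variants[idx, ]
  vt$counted_allele <- rs$risk_allele[sel]
  geno_matrix(dosage, gm$samples, vt)
}
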