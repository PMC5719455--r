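# End-to-end orchestration: simulate (or load) genotypes, filter the
# catalog, estimate ancestry, compute per-SNP ORs and the meta-analysis,
# run the three resampling controls, score individuals, and compare groups,
# writing every intermediate artifact plus a checksummed manifest.

#' Build and validate a pipeline configuration
#'
#' Exactly one of `simulation` or `inputs` must be supplied. With
#' `simulation`, genotypes, truth files and a catalog are generated; with
#' `inputs`, they are read from disk (`vcf`, `catalog`,
#' `reference_freqs` — a long TSV with columns ancestry, rsid, freq — and
#' an optional `populations` TSV with columns sample, population).
#'
#' @param simulation a [sim_config()], or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param contrast length-2 character: population labels A and B; the
#'   analysis reports risk of A relative to B.
#' @param trait trait label of the primary risk-SNP set.
#' @param regress_ancestry ancestry label for the ancestry-risk regression.
#' @param p_threshold,min_study_snps,clump_window_bp catalog filter rules.
#' @param n_bootstrap,n_random_sets resampling replicate counts.
#' @param catalog_opts list passed to [generate_catalog()] (simulation
#'   mode): decoy counts and null-trait structure for the disease scan.
#' @param seed master integer seed (mandatory; all stochastic stages derive
#'   named substreams from it).
#' @param out_dir output directory for stage artifacts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            contrast = c("choco_like", "antioquia_like"),
                            trait = "T2D",
                            regress_ancestry = "AFR",
                            p_threshold = 1e-5, min_study_snps = 100000,
                            clump_window_bp = 1000000,
                            n_bootstrap = 10000, n_random_sets = 500000,
                            catalog_opts = list(n_null_traits = 10,
                                                snps_per_null_trait = 50),
                            seed = NULL, out_dir = tempfile("admixrisk_run")) {
  if (is.null(simulation) == is.null(inputs)) {
    abort("exactly one of `simulation` or `inputs` must be given")
  }
  if (is.null(seed)) abort("a master seed is mandatory")
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    abort("`simulation` must be a sim_config object")
  }
  if (!is.null(inputs)) {
    need <- c("vcf", "catalog", "reference_freqs")
    if (!all(need %in% names(inputs))) {
      abort(paste("`inputs` needs paths:", paste(need, collapse = ", ")))
    }
  }
  if (length(contrast) != 2) abort("`contrast` must name two populations")
  structure(
    list(simulation = simulation, inputs = inputs, contrast = contrast,
         trait = trait, regress_ancestry = regress_ancestry,
         p_threshold = p_threshold, min_study_snps = min_study_snps,
         clump_window_bp = clump_window_bp, n_bootstrap = n_bootstrap,
         n_random_sets = n_random_sets, catalog_opts = catalog_opts,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

write_tsv_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(as_tibble(x), path)
  path
}

write_json_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full comparative-risk pipeline
#'
#' Executes the stages in dependency order — data, catalog filter, ancestry
#' (LD pruning, allele-sharing distances, MDS, supervised fractions),
#' per-SNP ORs and meta-analysis, the three controls (bootstrap, random SNP
#' sets, disease scan), polygenic scores, and group/regression comparisons
#' — writing each stage's artifacts under `config$out_dir` and a manifest
#' JSON with parameters, per-stage outputs and md5 checksums. Any stage
#' failure halts with the stage name and cause. Inputs are never modified.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  artifacts <- character()
  stages <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    log_note(sprintf("stage %-14s done in %.1fs", name,
                     as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  # -- data ----------------------------------------------------------------
  data <- run_stage("data", function() {
    if (!is.null(config$simulation)) {
      sim <- do.call(
        simulate_cohort,
        c(list(config = config$simulation),
          config$catalog_opts,
          list(clump_window_bp = config$clump_window_bp))
      )
      ref <- sim$truth$ancestral_freqs
      colnames(ref) <- sim$gm$variants$rsid
      artifacts <<- c(
        artifacts,
        write_vcf(sim$gm, file.path(out, "genotypes.vcf")),
        unlist(write_plink_text(sim$gm, file.path(out, "genotypes.ped"),
                                file.path(out, "genotypes.map"))),
        write_tsv_artifact(sim$truth$ancestry_fractions, out,
                           "truth_ancestry_fractions.tsv"),
        write_tsv_artifact(
          tidyr::pivot_longer(
            dplyr::bind_cols(tibble(ancestry = rownames(ref)),
                             as_tibble(ref)),
            -"ancestry", names_to = "rsid", values_to = "freq"
          ),
          out, "truth_ancestral_freqs.tsv"
        ),
        write_tsv_artifact(sim$truth$risk_set, out, "truth_risk_snps.tsv"),
        write_tsv_artifact(sim$catalog, out, "catalog.tsv")
      )
      list(gm = sim$gm, catalog = sim$catalog, reference_freqs = ref,
           truth = sim$truth)
    } else {
      pops <- NULL
      if (!is.null(config$inputs$populations)) {
        ptab <- readr::read_tsv(config$inputs$populations,
                                col_types = readr::cols())
        pops <- setNames(ptab$population, ptab$sample)
      }
      gm <- read_vcf(config$inputs$vcf, populations = pops)
      catalog <- read_catalog(config$inputs$catalog)
      rf <- readr::read_tsv(config$inputs$reference_freqs,
                            col_types = readr::cols())
      ref <- tidyr::pivot_wider(rf, names_from = "rsid",
                                values_from = "freq")
      ref_m <- as.matrix(ref[, -1])
      rownames(ref_m) <- ref$ancestry
      list(gm = gm, catalog = catalog, reference_freqs = ref_m,
           truth = NULL)
    }
  })

  # -- catalog filter ------------------------------------------------------
  risk_set <- run_stage("filter", function() {
    rs <- filter_catalog(
      data$catalog, config$trait, p_threshold = config$p_threshold,
      min_study_snps = config$min_study_snps,
      clump_window_bp = config$clump_window_bp
    )
    if (nrow(rs) == 0) abort("primary trait has no surviving risk SNPs")
    artifacts <<- c(
      artifacts,
      write_tsv_artifact(rs, out, "risk_set.tsv"),
      write_tsv_artifact(attr(rs, "audit"), out, "filter_audit.tsv")
    )
    rs
  })

  # -- ancestry ------------------------------------------------------------
  ancestry <- run_stage("ancestry", function() {
    kept <- ld_prune(data$gm)
    gm_pruned <- gm_subset(data$gm, variants = kept)
    dm <- allele_sharing_distance(gm_pruned)
    coords <- project_mds(dm, 2)
    fractions <- estimate_ancestry_supervised(gm_pruned,
                                              data$reference_freqs)
    artifacts <<- c(
      artifacts,
      write_tsv_artifact(
        dplyr::bind_cols(tibble(sample = rownames(dm)), as_tibble(dm)),
        out, "distance_matrix.tsv"
      ),
      write_tsv_artifact(coords, out, "mds_coordinates.tsv"),
      write_tsv_artifact(fractions, out, "ancestry_fractions.tsv")
    )
    list(pruned_rsids = kept, distance = dm, mds = coords,
         fractions = fractions)
  })

  # -- per-SNP ORs and meta ------------------------------------------------
  popA <- config$contrast[1]
  popB <- config$contrast[2]
  ormeta <- run_stage("or_meta", function() {
    in_contrast <- data$gm$samples$population %in% config$contrast
    if (!any(in_contrast)) abort("contrast populations not found in samples")
    gm_ab <- gm_subset(data$gm, samples = in_contrast)
    aligned <- align_risk_alleles(gm_ab, risk_set)
    freqs <- allele_frequencies(aligned)
    ors <- snp_log_or_table(freqs, popA, popB)
    meta_fixed <- meta_analyze(ors, "fixed")
    meta_random <- meta_analyze(ors, "random")
    artifacts <<- c(
      artifacts,
      write_tsv_artifact(freqs, out, "allele_frequencies.tsv"),
      write_tsv_artifact(ors, out, "or_table.tsv"),
      write_json_artifact(
        list(fixed = unclass(meta_fixed), random = unclass(meta_random)),
        out, "meta_result.json"
      )
    )
    list(aligned = aligned, freqs = freqs, or_table = ors,
         meta_fixed = meta_fixed, meta_random = meta_random)
  })

  # -- controls ------------------------------------------------------------
  controls <- run_stage("controls", function() {
    boot <- bootstrap_meta(ormeta$or_table, n_reps = config$n_bootstrap,
                           seed = substream_seed(config$seed, "ctrl_boot"))
    trait_sets <- multi_trait_split(
      data$catalog, p_threshold = config$p_threshold,
      min_study_snps = config$min_study_snps,
      clump_window_bp = config$clump_window_bp
    )
    gm_ab <- gm_subset(data$gm,
                       samples = data$gm$samples$population %in%
                         config$contrast)
    pool_entries <- dplyr::distinct(
      dplyr::bind_rows(lapply(trait_sets, as_tibble)), .data$rsid,
      .keep_all = TRUE
    )
    pool_aligned <- align_risk_alleles(gm_ab, pool_entries)
    pool_freqs <- allele_frequencies(pool_aligned)
    pool_ors <- snp_log_or_table(pool_freqs, popA, popB)
    rnd <- random_snpset_null(
      pool_ors, set_size = min(nrow(risk_set), nrow(pool_ors)),
      n_reps = config$n_random_sets,
      seed = substream_seed(config$seed, "ctrl_random"),
      observed = ormeta$meta_fixed
    )
    scan_sets <- trait_sets[setdiff(names(trait_sets), config$trait)]
    scan <- NULL
    if (length(scan_sets) >= 2) {
      gm_a <- gm_subset(data$gm,
                        samples = data$gm$samples$population == popA)
      gm_b <- gm_subset(data$gm,
                        samples = data$gm$samples$population == popB)
      scan <- disease_scan(gm_a, gm_b, scan_sets)
      artifacts <<- c(artifacts,
                      write_tsv_artifact(scan$table, out,
                                         "disease_scan.tsv"))
    } else {
      log_note("controls: fewer than 2 secondary traits; disease scan skipped")
    }
    artifacts <<- c(
      artifacts,
      write_tsv_artifact(tibble(value = boot$null$values), out,
                         "bootstrap_null.tsv"),
      write_json_artifact(tidy(boot$null), out, "bootstrap_null.json"),
      write_tsv_artifact(tibble(value = rnd$null$values), out,
                         "random_set_null.tsv"),
      write_json_artifact(tidy(rnd$null), out, "random_set_null.json")
    )
    list(bootstrap = boot, random_set = rnd, disease_scan = scan)
  })

  # -- PRS and comparisons -------------------------------------------------
  comparison <- run_stage("compare", function() {
    aligned_all <- align_risk_alleles(data$gm, risk_set)
    prs <- polygenic_risk_score(aligned_all)
    gtest <- group_prs_test(prs, groups = config$contrast)
    reg <- ancestry_prs_regression(ancestry$fractions,
                                   config$regress_ancestry, prs)
    artifacts <<- c(
      artifacts,
      write_tsv_artifact(prs, out, "prs.tsv"),
      write_json_artifact(
        list(test = tidy(gtest), groups = gtest$groups),
        out, "group_test.json"
      ),
      write_json_artifact(glance(reg), out, "ancestry_regression.json"),
      write_tsv_artifact(reg$deciles, out, "regression_deciles.tsv")
    )
    list(prs = prs, group_test = gtest, regression = reg)
  })

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    contrast = config$contrast,
    trait = config$trait,
    parameters = list(
      p_threshold = config$p_threshold,
      min_study_snps = config$min_study_snps,
      clump_window_bp = config$clump_window_bp,
      n_bootstrap = config$n_bootstrap,
      n_random_sets = config$n_random_sets
    ),
    mode = if (is.null(config$simulation)) "inputs" else "simulation",
    artifacts = lapply(
      setNames(artifacts, basename(artifacts)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    )
  )
  write_json_artifact(manifest, out, "manifest.json")
  invisible(list(
    data = data, risk_set = risk_set, ancestry = ancestry,
    or_meta = ormeta, controls = controls, comparison = comparison,
    manifest = manifest
  ))
}
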