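# End-to-end driver: preprocess -> genotype QC / kinship -> per-trait GWAS
# (+ alpha-diversity traits) -> chip heritability -> heritability/GWAS
# overlap -> candidate-tissue enrichment, with a manifest recording the
# resolved configuration, seed and per-stage output checksums. The
# functions themselves are the user interface; this wrapper exists so a
# whole synthetic study can be reproduced from one seed.

#' Pipeline configuration
#'
#' All thresholds default to the canonical analysis values: 2e6-read
#' subsampling, 75% prevalence, pruning at r >= 0.9, QC MAF 5% / call rate
#' 95% / HWE 0.001, analysis MAF 10%, q-value cutoffs 0.1 and 0.2, the
#' 12-step enrichment ladder with a 50-SNP minimum bin.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param max_depth,prevalence,prune_r preprocessing thresholds.
#' @param qc_maf,call_rate,hwe_p,analysis_maf genotype thresholds.
#' @param q_cutoffs q-value significance cutoffs.
#' @param n_perm_overlap,n_perm_enrich permutation counts.
#' @param enrich_thresholds,enrich_min_snps enrichment bin ladder.
#' @param n_tissue_clusters number of tissue groups to cut.
#' @param seed root seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            max_depth = 2e6,
                            prevalence = 0.75,
                            prune_r = 0.9,
                            qc_maf = 0.05,
                            call_rate = 0.95,
                            hwe_p = 0.001,
                            analysis_maf = 0.10,
                            q_cutoffs = c(0.1, 0.2),
                            n_perm_overlap = 1000,
                            n_perm_enrich = 200,
                            enrich_thresholds = ENRICHMENT_THRESHOLDS,
                            enrich_min_snps = 50,
                            n_tissue_clusters = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_tissue_clusters)) cfg$n_tissue_clusters <- sim$n_tissues
  cfg$sim$seed <- seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic study from `config$sim`, runs every analysis stage
#' and writes results plus a `manifest.json` (resolved config, seed,
#' per-file md5 checksums) into `out_dir`. Identical config and seed
#' reproduce every output byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param exact_gwas per-SNP lambda re-optimization in the trait GWAS
#'   (default FALSE for tractable whole-study runs).
#' @param inputs optional named list of file paths (`genotypes`, `taxa`,
#'   `covariates`, and optionally `peaks_dir` + `cell_lines`) to analyze
#'   instead of simulating a study; formats as documented in the readers.
#' @return list with the main stage outputs (invisible components are all
#'   also written under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, exact_gwas = FALSE, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- if (is.null(inputs)) simulate_study(config$sim, with_dhs = TRUE)
  else load_study_inputs(inputs)

  # -- preprocessing, per season then combined ------------------------------
  seasons <- unique(study$taxa$samples$season)
  season_tables <- lapply(seasons, function(s) {
    keep <- study$taxa$samples$season == s
    taxa_count_table(study$taxa$counts[keep, , drop = FALSE],
                     study$taxa$samples[keep, , drop = FALSE],
                     study$taxa$taxonomy)
  })
  names(season_tables) <- seasons
  pre <- lapply(seasons, function(s)
    preprocess_taxa(season_tables[[s]], max_depth = config$max_depth,
                    min_fraction = config$prevalence,
                    r_threshold = config$prune_r,
                    seed = child_seed(config$seed, 10L)))
  names(pre) <- seasons
  combined <- NULL
  if (length(seasons) >= 2) {
    # combined analysis: re-normalize within season over both-season taxa,
    # average, then prune
    pre_np <- lapply(seasons[1:2], function(s)
      preprocess_taxa(season_tables[[s]], max_depth = config$max_depth,
                      min_fraction = config$prevalence, r_threshold = NULL,
                      seed = child_seed(config$seed, 10L)))
    avg <- combine_seasons(pre_np[[1]]$values, pre_np[[2]]$values)
    taxonomy <- study$taxa$taxonomy[
      match(colnames(avg), study$taxa$taxonomy$taxon), ]
    prc <- correlation_prune(avg, taxonomy, r_threshold = config$prune_r)
    combined <- prc$values
  }

  # -- genotype QC and kinship ---------------------------------------------
  qc <- snp_qc(study$genotypes, maf_min = config$qc_maf,
               call_rate_min = config$call_rate, hwe_p_min = config$hwe_p)
  K <- kinship_matrix(qc$genotypes)

  # -- association stage on the combined (or first-season) matrix ----------
  values <- if (!is.null(combined)) combined else pre[[1]]$values
  ids <- rownames(values)
  covars <- study$covariates[match(ids, study$covariates$individual), ]
  design <- covariate_design(covars)
  eig <- eigendecompose_kinship(K[ids, ids])
  ga <- analysis_maf_filter(qc$genotypes, ids, maf_min = config$analysis_maf)
  gwas <- list()
  pve <- list()
  for (tx in colnames(values)) {
    y <- setNames(residualize(values[, tx], design), ids)
    gwas[[tx]] <- run_gwas(y, ga, eig, maf_min = config$analysis_maf,
                           exact = exact_gwas, trait = tx)
    pve[[tx]] <- estimate_pve(y, eig)
  }
  summary_tab <- gwas_significance_summary(gwas)
  nonzero <- vapply(pve, function(p) p$nonzero, logical(1))
  overlap <- herit_gwas_overlap_test(nonzero, summary_tab$total_significant,
                                     n_perm = config$n_perm_overlap,
                                     seed = child_seed(config$seed, 20L))

  # -- diversity traits -----------------------------------------------------
  genus_cols <- study$taxa$taxonomy$level == "genus"
  comb_counts <- combine_replicates(study$taxa)
  first_season <- comb_counts$samples$season == seasons[1]
  div_counts <- comb_counts$counts[first_season, genus_cols, drop = FALSE]
  rownames(div_counts) <- comb_counts$samples$individual[first_season]
  diversity <- alpha_diversity(div_counts)

  # -- candidate-tissue enrichment for the top trait ------------------------
  assignment <- NULL; prof <- list(profile = NULL); enrich_p <- NULL
  if (!is.null(study$dhs)) {
  assignment <- cluster_cell_lines(study$dhs$peaks,
                                   k = config$n_tissue_clusters)
  tp <- tissue_peaks(assignment, study$dhs$peaks)
  mask <- snp_in_peak_mask(ga$snp_meta, tp)
  top_trait <- summary_tab$trait[which.min(summary_tab$min_p)]
  prof <- enrichment_profile(gwas[[top_trait]],
                             mask[gwas[[top_trait]]$id, , drop = FALSE],
                             thresholds = config$enrich_thresholds,
                             min_snps = config$enrich_min_snps)
  if (!is.null(prof$smallest_bin) && nrow(prof$smallest_bin)) {
    n_top <- prof$smallest_bin$n_top[which.min(prof$smallest_bin$threshold)]
    y_top <- setNames(residualize(values[, top_trait], design), ids)
    enrich_p <- enrichment_permutation_test(
      y_top, ga, eig, mask, n_top = n_top, n_perm = config$n_perm_enrich,
      seed = child_seed(config$seed, 30L),
      actual_fold = setNames(prof$smallest_bin$fold, prof$smallest_bin$tissue)[
        colnames(mask)])
  }
  }

  # -- write outputs and manifest ------------------------------------------
  for (s in seasons) {
    write.table(pre[[s]]$values, file.path(out_dir, paste0("normalized_", s, ".tsv")),
                sep = "\t", quote = FALSE)
  }
  if (!is.null(combined))
    write.table(combined, file.path(out_dir, "normalized_combined.tsv"),
                sep = "\t", quote = FALSE)
  write_kinship(K, file.path(out_dir, "kinship.tsv"))
  write.table(summary_tab, file.path(out_dir, "gwas_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(diversity, file.path(out_dir, "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE)
  pve_tab <- data.frame(taxon = names(pve),
                        pve = vapply(pve, `[[`, numeric(1), "pve"),
                        se = vapply(pve, `[[`, numeric(1), "se"),
                        nonzero = nonzero, row.names = NULL)
  write.table(pve_tab, file.path(out_dir, "pve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(prof$profile))
    write.table(prof$profile, file.path(out_dir, "enrichment_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(enrich_p)) {
    con <- file.path(out_dir, "enrichment_p.tsv")
    writeLines("# empirical p-values, not corrected across tissues", con)
    suppressWarnings(write.table(
      data.frame(tissue = names(enrich_p$p), p = enrich_p$p,
                 fold = enrich_p$actual_fold, row.names = NULL),
      con, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE,
      col.names = TRUE))
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("microgwas")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    sim = unclass(config$sim),
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(preprocessed = pre, combined = combined, qc = qc,
                 study = study,
                 kinship = K, gwas = gwas, summary = summary_tab,
                 pve = pve_tab, overlap = overlap, diversity = diversity,
                 tissue_assignment = assignment, enrichment = prof,
                 enrichment_p = enrich_p, manifest = manifest))
}

# Load a study from files: genotype TSV/VCF, long-format taxa TSV,
# covariate TSV, and optionally a directory of per-cell-line BED files
# with a cell-line -> tissue TSV. Every missing path aborts with the stage
# and path named.
load_study_inputs <- function(inputs) {
  need <- c("genotypes", "taxa", "covariates")
  for (nm in intersect(c(need, "cell_lines"), names(inputs))) {
    if (!file.exists(inputs[[nm]]))
      stop_mg("input loading: %s file not found: %s", nm, inputs[[nm]])
  }
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop_mg("input loading: missing input path(s): %s",
            paste(miss, collapse = ", "))
  geno <- read_genotypes(inputs$genotypes)
  taxa <- read_taxa_table(inputs$taxa)
  covars <- read_covariates(inputs$covariates)
  dhs <- NULL
  if (!is.null(inputs$peaks_dir)) {
    if (!dir.exists(inputs$peaks_dir))
      stop_mg("input loading: peaks_dir not found: %s", inputs$peaks_dir)
    beds <- list.files(inputs$peaks_dir, pattern = "\\.bed(\\.gz)?$",
                       full.names = TRUE)
    peaks <- lapply(beds, read_bed)
    names(peaks) <- sub("\\.bed(\\.gz)?$", "", basename(beds))
    for (nm in names(peaks)) peaks[[nm]]$label <- nm
    cl <- if (!is.null(inputs$cell_lines)) open_tsv(inputs$cell_lines)
    else data.frame(cell_line = names(peaks), tissue = names(peaks))
    dhs <- list(peaks = peaks, cell_lines = cl)
  }
  list(genotypes = geno, covariates = covars, taxa = taxa, dhs = dhs,
       truth = NULL, kinship = NULL, family = NULL, config = NULL)
}
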