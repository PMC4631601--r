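# Synthetic founder-population study generator. Three generators share one
# root seed (child streams by fixed offsets): family-structured genotypes
# with a known block kinship, compositional taxon counts with planted SNP,
# polygenic and covariate effects, and per-cell-line open-chromatin peak
# sets in which the causal SNPs of chosen taxa sit inside peaks of one
# "true" tissue.

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list.
#' Individuals are grouped into non-overlapping sibships (two unobserved
#' parents each), giving a block-structured true kinship of ~0.5 within
#' families and 0 between.
#'
#' @param n_individuals number of sampled individuals.
#' @param n_snps number of biallelic SNPs (independent given the pedigree).
#' @param n_families,family_size sibship layout; must satisfy
#'   `n_families * family_size >= n_individuals`.
#' @param maf_range allele-frequency range, a pair within (0, 0.5]; per-SNP
#'   frequencies are drawn uniformly from it.
#' @param monozygotic if TRUE, all siblings within a family are genetically
#'   identical (true kinship 1 within families).
#' @param n_taxa number of bacterial taxa.
#' @param planted_effects data.frame with columns `taxon`, `snp`, `effect`
#'   (per-allele effect on the latent trait, in residual-SD units).
#' @param taxon_h2 named numeric vector, taxon -> polygenic heritability in
#'   [0, 1) of the latent trait.
#' @param sex_effects,age_effects named numeric vectors, taxon -> additive
#'   covariate effect in latent-SD units (sex effect = male minus female;
#'   age effect per SD of age).
#' @param seasons,replicates_per_season sampling design (defaults 2 and 2).
#' @param reads_per_replicate sequencing depth per technical replicate.
#' @param genome_length genome size in bp (single chromosome "chr1").
#' @param n_cell_lines,n_tissues,causal_tissue open-chromatin design; the
#'   causal tissue's peaks are guaranteed to cover all causal SNPs.
#' @param n_groups number of collection-date groups.
#' @param seed root seed; all three generators derive child streams from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100,
                       n_snps = 1000,
                       n_families = 25,
                       family_size = 4,
                       maf_range = c(0.05, 0.5),
                       monozygotic = FALSE,
                       n_taxa = 40,
                       planted_effects = NULL,
                       taxon_h2 = NULL,
                       sex_effects = NULL,
                       age_effects = NULL,
                       seasons = 2,
                       replicates_per_season = 2,
                       reads_per_replicate = 20000,
                       genome_length = 1e6,
                       n_cell_lines = 12,
                       n_tissues = 4,
                       causal_tissue = "tissue1",
                       n_groups = 3,
                       seed = 1) {
  for (nm in c("n_individuals", "n_snps", "n_families", "family_size",
               "n_taxa", "seasons", "replicates_per_season",
               "reads_per_replicate", "genome_length", "n_cell_lines",
               "n_tissues", "n_groups")) {
    if (!is_count(get(nm))) stop_mg("'%s' must be a positive integer", nm)
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_mg("maf_range must be an increasing pair within (0, 0.5]")
  if (n_families * family_size < n_individuals)
    stop_mg("n_families * family_size must be >= n_individuals")
  if (!is.null(taxon_h2)) {
    if (any(taxon_h2 < 0) || any(taxon_h2 >= 1))
      stop_mg("heritabilities must lie in [0, 1)")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    if (!all(c("taxon", "snp", "effect") %in% names(planted_effects)))
      stop_mg("planted_effects needs columns taxon, snp, effect")
  }
  if (n_tissues > n_cell_lines)
    stop_mg("n_tissues cannot exceed n_cell_lines")
  cfg <- list(n_individuals = n_individuals, n_snps = n_snps,
              n_families = n_families, family_size = family_size,
              maf_range = maf_range, monozygotic = monozygotic,
              n_taxa = n_taxa, planted_effects = planted_effects,
              taxon_h2 = taxon_h2, sex_effects = sex_effects,
              age_effects = age_effects, seasons = seasons,
              replicates_per_season = replicates_per_season,
              reads_per_replicate = reads_per_replicate,
              genome_length = genome_length, n_cell_lines = n_cell_lines,
              n_tissues = n_tissues, causal_tissue = causal_tissue,
              n_groups = n_groups, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

taxon_names <- function(n) sprintf("genus_%03d", seq_len(n))

#' Simulate family-structured genotypes with a known kinship
#'
#' Each family has two unobserved parents with haplotypes drawn at the SNP's
#' allele frequency; each child inherits one random parental allele from
#' each. Siblings therefore share alleles identically by descent and the
#' expected (true) kinship is block diagonal: 1 on the diagonal, 0.5 between
#' siblings, 0 between families (1 between monozygotic siblings).
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `kinship`
#'   (the true expected kinship, individuals x individuals).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_snps
  fam <- rep(seq_len(config$n_families),
             each = config$family_size)[seq_len(n)]
  ids <- sprintf("ind%04d", seq_len(n))
  with_seed(child_seed(config$seed, 1L), {
    f <- runif(m, config$maf_range[1], config$maf_range[2])
    dos <- matrix(0L, n, m, dimnames = list(ids, NULL))
    for (fi in unique(fam)) {
      members <- which(fam == fi)
      # parental haplotypes: 2 parents x 2 alleles per SNP
      par <- matrix(rbinom(4 * m, 1, rep(f, each = 4)), nrow = 4)
      if (config$monozygotic) {
        pick_m <- sample(1:2, m, replace = TRUE)       # maternal allele index
        pick_p <- sample(1:2, m, replace = TRUE) + 2L  # paternal allele index
        child <- par[cbind(pick_m, seq_len(m))] + par[cbind(pick_p, seq_len(m))]
        dos[members, ] <- matrix(child, length(members), m, byrow = TRUE)
      } else {
        for (i in members) {
          pick_m <- sample(1:2, m, replace = TRUE)
          pick_p <- sample(1:2, m, replace = TRUE) + 2L
          dos[i, ] <- par[cbind(pick_m, seq_len(m))] +
            par[cbind(pick_p, seq_len(m))]
        }
      }
    }
    pos <- sort(sample.int(config$genome_length, m)) - 1L  # 0-based
    snp_ids <- sprintf("snp%05d", seq_len(m))
    colnames(dos) <- snp_ids
    geno <- genotype_matrix(dos, data.frame(id = snp_ids, chrom = "chr1",
                                            pos = pos))
    within <- if (config$monozygotic) 1 else 0.5
    K <- outer(fam, fam, function(a, b) ifelse(a == b, within, 0))
    diag(K) <- 1
    dimnames(K) <- list(ids, ids)
    list(genotypes = geno, kinship = K, family = setNames(fam, ids))
  })
}

#' Simulate covariates for the synthetic study
#'
#' Ages uniform on \[16, 85\], sex Bernoulli(0.5), and `n_groups`
#' collection-date groups assigned by family (colonies are sampled on
#' separate days, so collection date tracks family blocks).
#'
#' @param config a [sim_config()].
#' @param family named family index per individual from
#'   [simulate_genotypes()].
#' @return A [covariate_table()].
#' @export
simulate_covariates <- function(config, family) {
  with_seed(child_seed(config$seed, 2L), {
    ids <- names(family)
    covariate_table(
      individual = ids,
      age = round(runif(length(ids), 16, 85)),
      sex = ifelse(rbinom(length(ids), 1, 0.5) == 1, "M", "F"),
      collection_group = paste0("g", (family %% config$n_groups) + 1L))
  })
}

#' Simulate taxon counts with planted genetic and covariate effects
#'
#' Latent model per taxon j and individual i:
#' z_ij = sum of planted per-allele SNP effects + polygenic term with
#' variance h2_j (independent N(0, h2_j/m) effects on all m standardized
#' SNPs, so the heritable part is genuinely tagged by the genotyped
#' variants) + covariate effects + N(0, 1 - h2_j) noise. Counts per
#' replicate are multinomial draws of `reads_per_replicate` reads over
#' softmax(baseline + z + season shift), giving compositional counts with
#' realistic skew.
#'
#' @param genotypes a [genotype_matrix()].
#' @param kinship true kinship matrix (for the polygenic draw).
#' @param covariates a [covariate_table()].
#' @param config a [sim_config()].
#' @return list with `table` (a [taxa_count_table()]) and `truth` (latent
#'   traits, causal map, per-taxon h2, covariate effects).
#' @export
simulate_taxa_counts <- function(genotypes, kinship, covariates, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  n <- n_individuals(genotypes)
  ids <- rownames(genotypes$dosages)
  if (!all(covariates$individual == ids))
    stop_mg("covariates must be aligned to genotype individuals")
  taxa <- taxon_names(config$n_taxa)
  h2 <- setNames(rep(0, config$n_taxa), taxa)
  if (!is.null(config$taxon_h2)) {
    bad <- setdiff(names(config$taxon_h2), taxa)
    if (length(bad)) stop_mg("unknown taxa in taxon_h2: %s",
                             paste(bad, collapse = ", "))
    h2[names(config$taxon_h2)] <- config$taxon_h2
  }
  pe <- config$planted_effects
  if (!is.null(pe)) {
    missing_snp <- setdiff(pe$snp, genotypes$snp_meta$id)
    if (length(missing_snp))
      stop_mg("planted snp id(s) absent from genotypes: %s",
              paste(missing_snp, collapse = ", "))
    if (length(setdiff(pe$taxon, taxa)))
      stop_mg("planted effect names a taxon outside the table")
  }
  with_seed(child_seed(config$seed, 3L), {
    # standardized dosages carry the polygenic effects
    Gs <- genotypes$dosages
    mu_g <- colMeans(Gs, na.rm = TRUE)
    for (j in which(colSums(is.na(Gs)) > 0)) Gs[is.na(Gs[, j]), j] <- mu_g[j]
    sdv <- apply(Gs, 2, sd)
    poly_cols <- which(sdv > 0)
    Gs <- sweep(sweep(Gs[, poly_cols, drop = FALSE], 2, mu_g[poly_cols], "-"),
                2, sdv[poly_cols], "/")
    m_poly <- ncol(Gs)
    sexn <- as.numeric(covariates$sex == "M")
    agen <- as.numeric(scale(covariates$age))
    grp <- as.factor(covariates$collection_group)
    grp_shift <- rnorm(nlevels(grp), 0, 0.3)
    z <- matrix(0, n, config$n_taxa, dimnames = list(ids, taxa))
    for (j in seq_len(config$n_taxa)) {
      tj <- taxa[j]
      g_part <- rep(0, n)
      if (!is.null(pe)) {
        for (r in which(pe$taxon == tj)) {
          dos <- genotypes$dosages[, pe$snp[r]]
          dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
          g_part <- g_part + pe$effect[r] * (dos - mean(dos))
        }
      }
      poly <- if (h2[j] > 0)
        as.vector(Gs %*% rnorm(m_poly, 0, sqrt(h2[j] / m_poly))) else rep(0, n)
      cov_part <- grp_shift[as.integer(grp)]
      if (!is.null(config$sex_effects) && tj %in% names(config$sex_effects))
        cov_part <- cov_part + config$sex_effects[[tj]] * sexn
      if (!is.null(config$age_effects) && tj %in% names(config$age_effects))
        cov_part <- cov_part + config$age_effects[[tj]] * agen
      z[, j] <- g_part + poly + cov_part + rnorm(n, 0, sqrt(1 - h2[j]))
    }
    # compositional link: baseline log-abundances spread over ~4 orders of
    # magnitude, season shifts per taxon, softmax then multinomial reads
    baseline <- rnorm(config$n_taxa, 0, 2)
    season_shift <- matrix(rnorm(config$n_taxa * config$seasons, 0, 0.4),
                           config$seasons, config$n_taxa)
    season_shift[1, ] <- 0
    nrep <- config$replicates_per_season
    samples <- expand.grid(replicate = seq_len(nrep),
                           season = seq_len(config$seasons),
                           individual = ids, stringsAsFactors = FALSE)
    samples <- samples[, c("individual", "season", "replicate")]
    samples$season <- c("winter", "summer",
                        paste0("season", 3:10))[samples$season]
    counts <- matrix(0L, nrow(samples), config$n_taxa,
                     dimnames = list(NULL, taxa))
    for (r in seq_len(nrow(samples))) {
      i <- match(samples$individual[r], ids)
      s <- match(samples$season[r], unique(samples$season))
      eta <- baseline + z[i, ] + season_shift[s, ]
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      counts[r, ] <- rmultinom(1, config$reads_per_replicate, pr)[, 1]
    }
    lineage <- paste0("bacteria;", taxa)
    table <- taxa_count_table(counts, samples,
                              data.frame(taxon = taxa, level = "genus",
                                         lineage = lineage))
    truth <- list(latent = z, h2 = h2, planted_effects = pe,
                  sex_effects = config$sex_effects,
                  age_effects = config$age_effects,
                  kinship = kinship)
    list(table = table, truth = truth)
  })
}

#' Simulate per-cell-line open-chromatin peak sets with a causal tissue
#'
#' Lays a universe of non-overlapping candidate peaks over the genome; each
#' tissue activates a random subset, and every cell line of a tissue carries
#' the tissue's peaks minus a small random dropout (~2%) plus a matching
#' number of private peaks, so lines of the same tissue share >= 90% of
#' intervals. Peaks covering causal SNP positions are added to the causal
#' tissue and never dropped, so each causal SNP lies inside a peak common to
#' all causal-tissue cell lines.
#'
#' @param config a [sim_config()].
#' @param causal_snps data.frame with columns `chrom`, `pos` (0-based) of
#'   causal variants; may be empty.
#' @param peak_width peak width in bp (default 400).
#' @param peaks_per_tissue number of active peaks per tissue (default 150).
#' @return list with `peaks` (named list of `peak_set`, one per cell line)
#'   and `cell_lines` (data.frame cell_line, tissue — the truth table).
#' @export
simulate_dhs_peaks <- function(config, causal_snps = NULL, peak_width = 400,
                               peaks_per_tissue = 150) {
  stopifnot(inherits(config, "sim_config"))
  gl <- config$genome_length
  slot_w <- 2 * peak_width
  n_slots <- floor(gl / slot_w)
  if (n_slots < 4 * peaks_per_tissue)
    stop_mg("genome too small for the requested peak layout")
  if (!is.null(causal_snps) && nrow(causal_snps) &&
      any(causal_snps$pos + peak_width > gl))
    stop_mg("causal SNP cannot be covered: genome too small")
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  if (!config$causal_tissue %in% tissues)
    stop_mg("causal_tissue must be one of %s", paste(tissues, collapse = ", "))
  with_seed(child_seed(config$seed, 4L), {
    # slot-aligned candidate peaks guarantee non-overlap within a line
    slot_start <- (seq_len(n_slots) - 1L) * slot_w
    tissue_slots <- lapply(tissues, function(t)
      sort(sample.int(n_slots, peaks_per_tissue)))
    names(tissue_slots) <- tissues
    # peaks that must cover causal SNPs: the slot containing each position
    causal_iv <- NULL
    if (!is.null(causal_snps) && nrow(causal_snps)) {
      cslot <- unique(pmin(floor(causal_snps$pos / slot_w) + 1L, n_slots))
      offset <- causal_snps$pos - slot_start[pmin(floor(causal_snps$pos / slot_w) + 1L, n_slots)]
      if (any(offset >= slot_w))
        stop_mg("causal SNP cannot be covered: genome too small")
      causal_iv <- cslot
      tissue_slots[[config$causal_tissue]] <-
        sort(union(tissue_slots[[config$causal_tissue]], cslot))
    }
    line_tissue <- tissues[((seq_len(config$n_cell_lines) - 1L) %%
                              config$n_tissues) + 1L]
    line_ids <- sprintf("line%03d", seq_len(config$n_cell_lines))
    peaks <- vector("list", config$n_cell_lines)
    for (l in seq_len(config$n_cell_lines)) {
      slots <- tissue_slots[[line_tissue[l]]]
      droppable <- setdiff(slots, causal_iv)
      n_drop <- floor(0.02 * length(slots))
      drop <- if (n_drop > 0 && length(droppable))
        sample(droppable, min(n_drop, length(droppable))) else integer()
      free <- setdiff(seq_len(n_slots), slots)
      add <- if (length(drop)) sample(free, length(drop)) else integer()
      use <- sort(union(setdiff(slots, drop), add))
      # full slot width covers any SNP position inside the slot
      st <- slot_start[use]
      peaks[[l]] <- peak_set(rep("chr1", length(use)), st, st + slot_w,
                             label = line_ids[l])
    }
    names(peaks) <- line_ids
    list(peaks = peaks,
         cell_lines = data.frame(cell_line = line_ids, tissue = line_tissue))
  })
}

#' Simulate a complete synthetic study
#'
#' One call producing aligned genotypes, kinship, covariates, taxon counts
#' and open-chromatin peaks, plus the full ground truth. This is the entry
#' point the pipeline and the validation suites use.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes`, `kinship`, `family`,
#'   `covariates`, `taxa`, `truth`, `dhs` (NULL unless peaks requested via
#'   `with_dhs`), and `config`.
#' @param with_dhs also generate open-chromatin peaks keyed to the planted
#'   causal SNPs (default FALSE).
#' @export
simulate_study <- function(config, with_dhs = FALSE) {
  g <- simulate_genotypes(config)
  covars <- simulate_covariates(config, g$family)
  tc <- simulate_taxa_counts(g$genotypes, g$kinship, covars, config)
  dhs <- NULL
  if (with_dhs) {
    causal <- NULL
    if (!is.null(config$planted_effects)) {
      idx <- match(config$planted_effects$snp, g$genotypes$snp_meta$id)
      causal <- g$genotypes$snp_meta[idx, c("chrom", "pos")]
    }
    dhs <- simulate_dhs_peaks(config, causal)
  }
  list(genotypes = g$genotypes, kinship = g$kinship, family = g$family,
       covariates = covars, taxa = tc$table, truth = tc$truth, dhs = dhs,
       config = config)
}

#' Write a simulated study to disk
#'
#' Writes the genotype dosage TSV, long-format taxa TSV, covariate TSV,
#' per-cell-line BED files with a cell-line/tissue table (when peaks were
#' generated), the true kinship, the latent traits, and a machine-readable
#' `truth.json` sidecar (planted effects, per-taxon heritabilities,
#' covariate effects, causal tissue).
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_taxa_table(study$taxa, file.path(dir, "taxa.tsv"))
  write_covariates(study$covariates, file.path(dir, "covariates.tsv"))
  write_kinship(study$kinship, file.path(dir, "true_kinship.tsv"))
  write.table(study$truth$latent, file.path(dir, "latent_traits.tsv"),
              sep = "\t", quote = FALSE)
  if (!is.null(study$dhs)) {
    pk <- file.path(dir, "peaks")
    dir.create(pk, showWarnings = FALSE)
    for (nm in names(study$dhs$peaks))
      write_bed(study$dhs$peaks[[nm]], file.path(pk, paste0(nm, ".bed")))
    write.table(study$dhs$cell_lines, file.path(dir, "cell_lines.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(
    h2 = as.list(study$truth$h2),
    planted_effects = study$truth$planted_effects,
    sex_effects = as.list(study$truth$sex_effects),
    age_effects = as.list(study$truth$age_effects),
    causal_tissue = study$config$causal_tissue,
    seed = study$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
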