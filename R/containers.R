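# Core containers. Deliberately light-weight S3: a genotype matrix is a
# dosage matrix (individuals x SNPs, entries 0/1/2/NA) plus SNP metadata;
# a taxa count table is a sample x taxon count matrix plus sample labels
# (individual, season, replicate) and a taxonomy table.

TAXON_LEVELS <- c("phylum", "class", "order", "family", "genus")

#' Construct a genotype matrix
#'
#' @param dosages numeric matrix, individuals in rows and SNPs in columns,
#'   entries in \{0, 1, 2\} or NA for missing. Row names are individual ids,
#'   column names SNP ids.
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos` (0-based
#'   internal convention), one row per SNP, in column order of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop_mg("dosage matrix needs individual row names and SNP column names")
  if (anyDuplicated(rownames(dosages)))
    stop_mg("duplicated individual ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop_mg("duplicated SNP ids in genotype matrix")
  if (!all(c("id", "chrom", "pos") %in% names(snp_meta)))
    stop_mg("snp_meta must have columns id, chrom, pos")
  if (nrow(snp_meta) != ncol(dosages) ||
      !identical(as.character(snp_meta$id), colnames(dosages)))
    stop_mg("snp_meta rows must match dosage columns (same ids, same order)")
  if (any(snp_meta$pos < 0)) stop_mg("SNP positions must be non-negative")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop_mg("dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d SNPs, %.2f%% missing>\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer.
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(g) ncol(g$dosages)

# Minor allele frequency per SNP from non-missing dosages.
snp_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Construct a taxa count table
#'
#' @param counts non-negative integer matrix, samples in rows (one row per
#'   individual x season x replicate) and taxa in columns.
#' @param samples data.frame with columns `individual`, `season`,
#'   `replicate`, one row per row of `counts`.
#' @param taxonomy data.frame with columns `taxon`, `level` (one of phylum,
#'   class, order, family, genus) and optionally `lineage`, one row per
#'   column of `counts`.
#' @return An object of class `taxa_count_table`.
#' @export
taxa_count_table <- function(counts, samples, taxonomy) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0) || any(counts != floor(counts)) || anyNA(counts))
    stop_mg("taxon counts must be non-negative integers")
  if (nrow(samples) != nrow(counts))
    stop_mg("samples must have one row per count row")
  if (!all(c("individual", "season", "replicate") %in% names(samples)))
    stop_mg("samples needs columns individual, season, replicate")
  if (!all(c("taxon", "level") %in% names(taxonomy)))
    stop_mg("taxonomy needs columns taxon, level")
  if (nrow(taxonomy) != ncol(counts) ||
      !identical(as.character(taxonomy$taxon), colnames(counts)))
    stop_mg("taxonomy rows must match count columns (same taxa, same order)")
  bad <- setdiff(unique(as.character(taxonomy$level)), TAXON_LEVELS)
  if (length(bad))
    stop_mg("unknown taxonomy level(s): %s", paste(bad, collapse = ", "))
  structure(list(counts = counts,
                 samples = as.data.frame(samples),
                 taxonomy = as.data.frame(taxonomy)),
            class = "taxa_count_table")
}

#' @export
print.taxa_count_table <- function(x, ...) {
  cat(sprintf(
    "<taxa_count_table: %d samples (%d individuals) x %d taxa, seasons: %s>\n",
    nrow(x$counts), length(unique(x$samples$individual)), ncol(x$counts),
    paste(unique(x$samples$season), collapse = "/")))
  invisible(x)
}

#' Construct a covariate table
#'
#' @param individual character vector of ids.
#' @param age numeric, years.
#' @param sex character or factor with levels F/M (coded F = 0, M = 1 in all
#'   model designs).
#' @param collection_group categorical collection-date/colony factor.
#' @return data.frame of class `covariate_table`.
#' @export
covariate_table <- function(individual, age, sex, collection_group) {
  if (anyDuplicated(individual)) stop_mg("duplicated individual ids")
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M"))) stop_mg("sex must be 'F' or 'M'")
  out <- data.frame(individual = as.character(individual),
                    age = as.numeric(age), sex = sex,
                    collection_group = as.character(collection_group),
                    stringsAsFactors = FALSE)
  if (anyNA(out)) stop_mg("covariates must not contain missing values")
  class(out) <- c("covariate_table", "data.frame")
  out
}
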