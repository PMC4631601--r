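# Readers/writers for the tabular and VCF-subset formats the pipeline
# touches. TSV layouts (documented in the README):
#   genotypes: columns id, chrom, pos (1-based in the file, like VCF),
#              then one column per individual with dosages 0/1/2/NA
#   taxa:      long format with columns individual, season, replicate,
#              taxon, level, count
#   covariates: individual, age, sex, collection_group
# VCF parsing is delegated to vcfR; only the GT field is interpreted,
# phasing is ignored and multi-allelic records are rejected.

open_tsv <- function(path) {
  if (!file.exists(path)) stop_mg("file not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

#' Read genotypes from TSV dosages or a minimal VCF
#'
#' @param path input file (`.gz` accepted).
#' @param format `"tsv"` (dosage table) or `"vcf"`. Guessed from the file
#'   extension by default.
#' @return A [genotype_matrix()]; positions are converted to the internal
#'   0-based convention on load.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(read_genotypes_vcf(path))
  tab <- open_tsv(path)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop_mg("%s: genotype TSV must have columns id, chrom, pos", path)
  ids <- setdiff(names(tab), need)
  if (!length(ids)) stop_mg("%s: no individual columns", path)
  dos <- t(as.matrix(tab[, ids, drop = FALSE]))
  colnames(dos) <- tab$id
  rownames(dos) <- ids
  genotype_matrix(dos, data.frame(id = as.character(tab$id),
                                  chrom = as.character(tab$chrom),
                                  pos = as.integer(tab$pos) - 1L))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT)))
    stop_mg("%s: multi-allelic records are not supported", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  # "0/1", "0|1", "./." -> dosage; phasing ignored
  dose1 <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(!a %in% 0:1))
      stop_mg("%s: unsupported genotype call '%s'", path, s)
    sum(a)
  }
  dos <- t(apply(gt, c(1, 2), dose1))
  colnames(dos) <- fix$ID
  genotype_matrix(dos, data.frame(id = as.character(fix$ID),
                                  chrom = as.character(fix$CHROM),
                                  pos = as.integer(fix$POS) - 1L))
}

#' Write genotypes
#'
#' `write_genotypes_tsv()` writes the dosage-table layout;
#' `write_genotypes_vcf()` writes a minimal VCF 4.2 subset (GT only,
#' unphased, REF/ALT as placeholder A/G). Both store positions 1-based.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(id = g$snp_meta$id, chrom = g$snp_meta$chrom,
                    pos = g$snp_meta$pos + 1L,
                    t(g$dosages), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (s in seq_len(n_snps(g))) {
    d <- g$dosages[, s]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    writeLines(paste(c(g$snp_meta$chrom[s], g$snp_meta$pos[s] + 1L,
                       g$snp_meta$id[s], "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a long-format taxon count table
#'
#' @param path TSV with columns individual, season, replicate, taxon, level,
#'   count (and optionally lineage).
#' @return A [taxa_count_table()].
#' @export
read_taxa_table <- function(path) {
  tab <- open_tsv(path)
  need <- c("individual", "season", "replicate", "taxon", "level", "count")
  if (!all(need %in% names(tab)))
    stop_mg("%s: taxa TSV must have columns %s", path, paste(need, collapse = ", "))
  if (any(tab$count < 0) || any(tab$count != floor(tab$count)))
    stop_mg("%s: counts must be non-negative integers", path)
  sample_key <- interaction(tab$individual, tab$season, tab$replicate,
                            drop = TRUE, lex.order = TRUE)
  taxa <- unique(tab$taxon)
  counts <- matrix(0, nrow = nlevels(sample_key), ncol = length(taxa),
                   dimnames = list(levels(sample_key), taxa))
  counts[cbind(as.integer(sample_key), match(tab$taxon, taxa))] <- tab$count
  first <- !duplicated(sample_key)
  samples <- data.frame(individual = tab$individual[first],
                        season = tab$season[first],
                        replicate = tab$replicate[first])[order(sample_key[first]), ]
  tax_first <- !duplicated(tab$taxon)
  taxonomy <- data.frame(taxon = tab$taxon[tax_first],
                         level = tab$level[tax_first])
  if ("lineage" %in% names(tab)) taxonomy$lineage <- tab$lineage[tax_first]
  taxonomy <- taxonomy[match(taxa, taxonomy$taxon), ]
  taxa_count_table(counts, samples, taxonomy)
}

#' Write a taxon count table in long format
#' @param table a [taxa_count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(table, path) {
  stopifnot(inherits(table, "taxa_count_table"))
  long <- data.frame(
    individual = rep(table$samples$individual, times = ncol(table$counts)),
    season = rep(table$samples$season, times = ncol(table$counts)),
    replicate = rep(table$samples$replicate, times = ncol(table$counts)),
    taxon = rep(colnames(table$counts), each = nrow(table$counts)),
    level = rep(table$taxonomy$level, each = nrow(table$counts)),
    count = as.vector(table$counts))
  if ("lineage" %in% names(table$taxonomy))
    long$lineage <- rep(table$taxonomy$lineage, each = nrow(table$counts))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a covariate table
#' @param path TSV with columns individual, age, sex, collection_group.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  tab <- open_tsv(path)
  need <- c("individual", "age", "sex", "collection_group")
  if (!all(need %in% names(tab)))
    stop_mg("%s: covariate TSV must have columns %s", path,
            paste(need, collapse = ", "))
  covariate_table(tab$individual, tab$age, tab$sex, tab$collection_group)
}

#' @rdname read_covariates
#' @param covars a [covariate_table()].
#' @export
write_covariates <- function(covars, path) {
  write.table(covars, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a kinship matrix as square TSV with an id header
#' @param path TSV path.
#' @return numeric matrix with matching row/column names.
#' @export
read_kinship <- function(path) {
  tab <- open_tsv(path)
  K <- as.matrix(tab)
  rownames(K) <- colnames(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop_mg("%s: kinship not symmetric", path)
  K
}

#' @rdname read_kinship
#' @param K symmetric numeric matrix with individual ids as dimnames.
#' @export
write_kinship <- function(K, path) {
  write.table(as.data.frame(K), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
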