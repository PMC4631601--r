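# Candidate-tissue identification: cluster cell lines into tissues from
# their open-chromatin peak profiles, build per-tissue peak sets by
# intersecting member cell lines, compute fold enrichment of top GWAS SNPs
# in peaks over a ladder of p-value thresholds, and calibrate the smallest
# retained bin by full phenotype-permutation GWAS.

ENRICHMENT_THRESHOLDS <- c(1.0, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 5e-4,
                           1e-4, 5e-5, 1e-5, 5e-6)

#' Cluster cell lines into tissue groups from peak profiles
#'
#' Builds a binary presence matrix of cell lines over the disjoint atomic
#' intervals of the union of all peaks, computes pairwise Euclidean
#' distances and cuts an average-linkage hierarchical tree into `k` groups.
#' Deterministic given the input order (hclust ties resolve by order).
#'
#' @param peaksets named list of `peak_set`, one per cell line.
#' @param k number of tissue groups (default 16).
#' @return data.frame with columns cell_line, tissue (tissue labels
#'   "cluster01"...).
#' @export
cluster_cell_lines <- function(peaksets, k = 16) {
  if (k > length(peaksets)) stop_mg("k exceeds the number of cell lines")
  if (is.null(names(peaksets))) names(peaksets) <-
      vapply(peaksets, function(p) p$label, character(1))
  grl <- lapply(peaksets, peakset_to_gr)
  atoms <- GenomicRanges::disjoin(do.call(c, unname(grl)))
  prof <- vapply(grl, function(gr)
    as.integer(IRanges::overlapsAny(atoms, gr)), integer(length(atoms)))
  tree <- hclust(dist(t(prof), method = "euclidean"), method = "average")
  grp <- cutree(tree, k = k)
  data.frame(cell_line = names(peaksets),
             tissue = sprintf("cluster%02d", grp),
             row.names = NULL)
}

#' Per-tissue peak sets by intersection over member cell lines
#'
#' Each tissue's peaks are the base pairs present in *every* member cell
#' line (iterated [intersect_peaks()]); a singleton tissue keeps its own
#' peaks. The optional union rule pools member peaks instead.
#'
#' @param assignment data.frame with columns cell_line, tissue.
#' @param peaksets named list of `peak_set` covering every assigned line.
#' @param rule `"intersection"` (default) or `"union"`.
#' @return named list of `peak_set`, one per tissue.
#' @export
tissue_peaks <- function(assignment, peaksets,
                         rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  miss <- setdiff(assignment$cell_line, names(peaksets))
  if (length(miss)) stop_mg("no peak set for cell line(s): %s",
                            paste(head(miss, 5), collapse = ", "))
  tissues <- unique(assignment$tissue)
  out <- lapply(tissues, function(t) {
    members <- assignment$cell_line[assignment$tissue == t]
    if (!length(members)) stop_mg("tissue '%s' has no member cell lines", t)
    grl <- lapply(peaksets[members], peakset_to_gr)
    gr <- if (rule == "intersection") Reduce(GenomicRanges::intersect, grl)
    else GenomicRanges::reduce(do.call(c, unname(grl)))
    ps <- list(label = t, intervals = gr_to_intervals(gr))
    class(ps) <- "peak_set"
    ps
  })
  names(out) <- tissues
  out
}

#' SNP-in-peak membership mask
#'
#' Logical matrix, SNPs x tissues: TRUE iff the SNP position (0-based)
#' falls inside some peak interval, i.e. start <= pos < end. SNPs on
#' chromosomes absent from a tissue's peaks are FALSE, not an error. The
#' mask is computed once and reused across traits and permutations.
#'
#' @param snp_meta data.frame with columns id, chrom, pos (0-based).
#' @param tissue_peaksets named list of per-tissue `peak_set`.
#' @return logical matrix with SNP ids as row names, tissues as columns.
#' @export
snp_in_peak_mask <- function(snp_meta, tissue_peaksets) {
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snp_meta$chrom),
    ranges = IRanges::IRanges(start = snp_meta$pos + 1L, width = 1L))
  # a SNP chromosome absent from a peak set is simply not in a peak;
  # GenomicRanges warns about disjoint seqlevels, which is expected here
  mask <- vapply(tissue_peaksets, function(ps)
    suppressWarnings(IRanges::overlapsAny(snp_gr, peakset_to_gr(ps))),
    logical(nrow(snp_meta)))
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = nrow(snp_meta))
  rownames(mask) <- snp_meta$id
  colnames(mask) <- names(tissue_peaksets)
  mask
}

#' Fold-enrichment profile of GWAS SNPs in tissue peaks
#'
#' For each tissue and each p-value threshold with at least `min_snps`
#' SNPs at or below the cutoff, the fold enrichment is the in-peak fraction
#' among those SNPs divided by the in-peak fraction among all tested SNPs.
#' Bins below `min_snps` are omitted; the smallest retained bin is flagged
#' for permutation testing. Tissues with zero genome-wide in-peak fraction
#' are skipped with a warning.
#'
#' @param gwas a `gwas_result` data.frame (needs columns id, p_lrt).
#' @param mask logical SNP x tissue matrix from [snp_in_peak_mask()],
#'   aligned to the GWAS SNPs.
#' @param thresholds p-value ladder (default the standard 12-step ladder
#'   from 1.0 down to 5e-6).
#' @param min_snps minimum SNPs per retained bin (default 50).
#' @return list with `profile` (data.frame tissue, threshold, n_snps,
#'   fold), `smallest_bin` (per-tissue threshold + n_top of the smallest
#'   retained bin), `background` (per-tissue genome-wide in-peak fraction).
#' @export
enrichment_profile <- function(gwas, mask,
                               thresholds = ENRICHMENT_THRESHOLDS,
                               min_snps = 50) {
  if (nrow(gwas) != nrow(mask) || !identical(as.character(gwas$id),
                                             rownames(mask)))
    stop_mg("mask rows must match GWAS SNPs (same ids, same order)")
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  bg <- colMeans(mask)
  skip <- bg == 0
  if (any(skip))
    warn_mg("skipping tissue(s) with no tested SNP in peaks: %s",
            paste(names(bg)[skip], collapse = ", "))
  prof <- list()
  smallest <- list()
  for (t in colnames(mask)[!skip]) {
    rows <- lapply(thresholds, function(th) {
      sel <- gwas$p_lrt <= th
      n <- sum(sel)
      if (n < min_snps) return(NULL)
      data.frame(tissue = t, threshold = th, n_snps = n,
                 fold = mean(mask[sel, t]) / bg[[t]])
    })
    rows <- do.call(rbind, rows)
    prof[[t]] <- rows
    if (!is.null(rows) && nrow(rows)) {
      last <- rows[nrow(rows), ]
      smallest[[t]] <- data.frame(tissue = t, threshold = last$threshold,
                                  n_top = last$n_snps, fold = last$fold)
    }
  }
  list(profile = do.call(rbind, c(prof, list(make.row.names = FALSE))),
       smallest_bin = do.call(rbind, c(smallest, list(make.row.names = FALSE))),
       background = bg)
}

#' Permutation calibration of tissue enrichment
#'
#' Shuffles the trait across individuals `n_perm` times; each permutation
#' re-runs the full GWAS (fast mode by default: the kinship
#' eigendecomposition is reused and the variance ratio is re-estimated
#' only under the null model), takes the `n_top` smallest-p SNPs and
#' recomputes the per-tissue fold enrichment. The empirical p-value per
#' tissue is the fraction of permutations whose fold is greater than or
#' equal to the observed fold. Reported p-values are not corrected across
#' tissues.
#'
#' @param y named trait residual vector.
#' @param g a [genotype_matrix()] already restricted to the analysis SNPs
#'   (post MAF filter).
#' @param K kinship matrix or eigendecomposition aligned to `names(y)`.
#' @param mask SNP x tissue logical matrix aligned to the columns of `g`.
#' @param n_top number of top SNPs per permutation — must equal the size of
#'   the actual GWAS's smallest retained bin.
#' @param n_perm number of permutations (default 1000).
#' @param seed permutation seed.
#' @param actual_fold named per-tissue observed fold (from
#'   [enrichment_profile()]); if NULL it is computed from the unpermuted
#'   trait with the same `n_top`.
#' @param exact per-SNP lambda re-optimization in each permutation GWAS
#'   (default FALSE = fast mode).
#' @param plus_one use (count + 1) / (n_perm + 1) (default FALSE).
#' @return list with `p` (named per-tissue empirical p), `actual_fold`,
#'   `null` (n_perm x tissue matrix of permuted folds).
#' @export
enrichment_permutation_test <- function(y, g, K, mask, n_top,
                                        n_perm = 1000, seed = NULL,
                                        actual_fold = NULL, exact = FALSE,
                                        plus_one = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- names(y)
  G <- g$dosages[ids, , drop = FALSE]
  if (n_top > ncol(G)) stop_mg("n_top exceeds the number of SNPs")
  if (nrow(mask) != ncol(G)) stop_mg("mask must cover every SNP")
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  eig <- if (inherits(K, "kinship_eigen")) K else
    eigendecompose_kinship(K[ids, ids])
  bg <- colMeans(mask)
  fold_top <- function(p) {
    top <- order(p)[seq_len(n_top)]
    colMeans(mask[top, , drop = FALSE]) / bg
  }
  UtG <- crossprod(eig$vectors, G)
  if (is.null(actual_fold)) {
    scan <- lmm_scan(y, G, eig, exact = exact, UtG = UtG)
    actual_fold <- fold_top(scan$p_lrt)
  }
  null <- matrix(NA_real_, n_perm, ncol(mask),
                 dimnames = list(NULL, colnames(mask)))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      scan <- lmm_scan(yp, G, eig, exact = exact, UtG = UtG)
      null[b, ] <- fold_top(scan$p_lrt)
    }
  })
  counts <- colSums(sweep(null, 2, actual_fold, ">=" ))
  p <- if (plus_one) (counts + 1) / (n_perm + 1) else counts / n_perm
  list(p = p, actual_fold = actual_fold, null = null)
}
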