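# Taxon-table processing, mirroring the microbiome-GWAS preprocessing
# ladder: subsample reads -> combine technical replicates -> relative
# abundance -> prevalence filter -> rank-based inverse normal transform ->
# correlated-taxon pruning (per season); the combined analysis additionally
# restricts to taxa common to both seasons before transforming and prunes
# after averaging.

#' Randomly subsample reads to a maximum depth per replicate
#'
#' Replicates whose total read count exceeds `max_depth` are downsampled
#' without replacement (multivariate hypergeometric draw over taxa) to
#' exactly `max_depth` reads; replicates at or below the depth are left
#' untouched.
#'
#' @param table a [taxa_count_table()].
#' @param max_depth maximum reads retained per replicate.
#' @param seed seed for the draw (deterministic given the seed).
#' @return A [taxa_count_table()] with subsampled counts.
#' @export
subsample_counts <- function(table, max_depth = 2e6, seed = NULL) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (!is_count(max_depth)) stop_mg("max_depth must be a positive integer")
  counts <- table$counts
  with_seed(seed, {
    for (r in seq_len(nrow(counts))) {
      tot <- sum(counts[r, ])
      if (tot > max_depth)
        counts[r, ] <- rmvhyper(counts[r, ], max_depth)
    }
  })
  table$counts <- counts
  table
}

# Multivariate hypergeometric draw: sample `n` reads without replacement
# from an urn with `k[j]` reads of taxon j, via chained univariate
# hypergeometric draws.
rmvhyper <- function(k, n) {
  out <- integer(length(k))
  remaining <- sum(k)
  for (j in seq_along(k)) {
    if (n <= 0) break
    out[j] <- rhyper(1, m = k[j], n = remaining - k[j], k = n)
    n <- n - out[j]
    remaining <- remaining - k[j]
  }
  out
}

#' Combine technical replicates within individual and season
#'
#' @param table a [taxa_count_table()].
#' @return A [taxa_count_table()] with one row per individual-season
#'   (replicate label "combined") and counts summed over replicates.
#' @export
combine_replicates <- function(table) {
  stopifnot(inherits(table, "taxa_count_table"))
  key <- interaction(table$samples$individual, table$samples$season,
                     drop = TRUE, lex.order = TRUE)
  counts <- rowsum(table$counts, key)
  first <- !duplicated(key)
  samples <- data.frame(individual = table$samples$individual[first],
                        season = table$samples$season[first],
                        replicate = "combined")
  ord <- order(key[first])
  samples <- samples[ord, ]
  counts <- counts[match(levels(key), rownames(counts)), , drop = FALSE]
  rownames(counts) <- NULL
  taxa_count_table(counts, samples, table$taxonomy)
}

#' Relative abundance per sample
#'
#' Standardizes each row of counts by its total so rows sum to one.
#' Samples with zero total reads are excluded with a warning.
#'
#' @param table a [taxa_count_table()].
#' @return list with `proportions` (matrix rows summing to 1), `samples`,
#'   and `excluded` (character vector of dropped sample individuals).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxa_count_table"))
  tot <- rowSums(table$counts)
  zero <- tot == 0
  if (any(zero))
    warn_mg("excluding %d sample(s) with zero total reads", sum(zero))
  prop <- sweep(table$counts[!zero, , drop = FALSE], 1, tot[!zero], "/")
  list(proportions = prop, samples = table$samples[!zero, , drop = FALSE],
       excluded = table$samples$individual[zero])
}

#' Prevalence filter
#'
#' Keeps taxa observed (count >= 1) in at least `min_fraction` of the
#' individuals, boundary inclusive; column order of the survivors is
#' preserved.
#'
#' @param table a [taxa_count_table()].
#' @param min_fraction minimum fraction of individuals with at least one
#'   read (default 0.75).
#' @return A filtered [taxa_count_table()]; empty result triggers a warning.
#' @export
prevalence_filter <- function(table, min_fraction = 0.75) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop_mg("min_fraction must be in (0, 1]")
  prev <- colMeans(table$counts >= 1)
  keep <- prev >= min_fraction
  if (!any(keep)) warn_mg("no taxa pass the prevalence filter")
  table$counts <- table$counts[, keep, drop = FALSE]
  table$taxonomy <- table$taxonomy[keep, , drop = FALSE]
  table
}

#' Rank-based inverse normal transformation
#'
#' Maps values onto standard-normal quantiles:
#' `qnorm((rank - a) / (n + 1 - 2a))` with the offset `a = 3/8` for
#' `n <= 10` and `a = 1/2` otherwise (the classical normal-scores plotting
#' positions). Ties receive the average of their ranks, so tied inputs map
#' to identical outputs; the transform is monotone in the input.
#'
#' @param x numeric vector, length >= 3, not all values identical.
#' @return numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(x) {
  if (anyNA(x)) stop_mg("missing values are not allowed")
  n <- length(x)
  if (n < 3) stop_mg("need at least 3 observations")
  if (diff(range(x)) == 0)
    stop_mg("constant input cannot be normal-transformed; drop the taxon upstream")
  a <- if (n <= 10) 3 / 8 else 0.5
  r <- rank(x, ties.method = "average")
  qnorm((r - a) / (n + 1 - 2 * a))
}

TAXON_LEVEL_RANK <- c(phylum = 1, class = 2, order = 3, family = 4, genus = 5)

#' Prune highly correlated taxa
#'
#' Removes taxa until no remaining pair has Pearson correlation at or above
#' `r_threshold`. For a pair spanning two taxonomic levels the broader
#' (higher) level is removed; within a level the taxon listed first
#' alphabetically is removed. Violating pairs are processed in decreasing
#' correlation (ties broken lexicographically) and correlations are
#' re-checked after every removal, making the result deterministic.
#'
#' @param values numeric matrix, individuals x taxa (normalized abundances).
#' @param taxonomy data.frame with columns `taxon`, `level` covering every
#'   column of `values`.
#' @param r_threshold correlation at or above which a pair is pruned
#'   (default 0.9).
#' @return list with `values` (pruned matrix) and `removed` (data.frame
#'   kept, removed, r — one row per removal).
#' @export
correlation_prune <- function(values, taxonomy, r_threshold = 0.9) {
  stopifnot(is.matrix(values))
  taxa <- colnames(values)
  if (is.null(taxa)) stop_mg("values must have taxon column names")
  if (!all(taxa %in% taxonomy$taxon))
    stop_mg("taxonomy must cover all taxa in the matrix")
  lvl <- setNames(TAXON_LEVEL_RANK[as.character(taxonomy$level)],
                  taxonomy$taxon)
  removed <- data.frame(kept = character(), removed = character(),
                        r = numeric())
  repeat {
    if (ncol(values) < 2) break
    cm <- suppressWarnings(cor(values))
    cm[lower.tri(cm, diag = TRUE)] <- NA
    hits <- which(!is.na(cm) & cm >= r_threshold, arr.ind = TRUE)
    if (!nrow(hits)) break
    h <- data.frame(a = colnames(values)[hits[, 1]],
                    b = colnames(values)[hits[, 2]],
                    r = cm[hits])
    pair_min <- pmin(h$a, h$b); pair_max <- pmax(h$a, h$b)
    h <- h[order(-h$r, pair_min, pair_max), , drop = FALSE][1, ]
    la <- lvl[[h$a]]; lb <- lvl[[h$b]]
    if (la != lb) {
      drop <- if (la < lb) h$a else h$b   # broader rank has the lower number
    } else {
      drop <- min(h$a, h$b)               # alphabetically first goes
    }
    keep <- setdiff(c(h$a, h$b), drop)
    removed <- rbind(removed,
                     data.frame(kept = keep, removed = drop, r = h$r))
    values <- values[, colnames(values) != drop, drop = FALSE]
  }
  list(values = values, removed = removed)
}

#' Average within-season normalized abundances across two seasons
#'
#' Individuals sampled in both seasons get the mean of their two normalized
#' values; single-season individuals keep their value unchanged. Taxa are
#' restricted to those present in both inputs (the caller is expected to
#' have applied the prevalence filter within each season first).
#'
#' @param winter,summer numeric matrices (individuals x taxa) normalized
#'   within season, with individual row names and taxon column names.
#' @return numeric matrix over the union of individuals and the common
#'   taxa.
#' @export
combine_seasons <- function(winter, summer) {
  taxa <- intersect(colnames(winter), colnames(summer))
  if (!length(taxa)) stop_mg("seasons share no taxa")
  ids <- union(rownames(winter), rownames(summer))
  out <- matrix(NA_real_, length(ids), length(taxa),
                dimnames = list(ids, taxa))
  w <- rownames(winter); s <- rownames(summer)
  both <- intersect(w, s)
  only_w <- setdiff(w, s); only_s <- setdiff(s, w)
  if (length(both))
    out[both, ] <- (winter[both, taxa, drop = FALSE] +
                      summer[both, taxa, drop = FALSE]) / 2
  if (length(only_w)) out[only_w, ] <- winter[only_w, taxa, drop = FALSE]
  if (length(only_s)) out[only_s, ] <- summer[only_s, taxa, drop = FALSE]
  out
}

#' Alpha diversity at the genus level
#'
#' Richness S (genera with count > 0), Shannon diversity
#' H = -sum p log p (natural log, via vegan), and Pielou evenness
#' J = H / log S. Computed on raw counts, before any normalization or
#' rarity filtering. J is reported as NA when S = 1.
#'
#' @param genus_counts matrix of genus-level counts, individuals x genera.
#' @return data.frame with columns richness, shannon, evenness (one row per
#'   individual).
#' @export
alpha_diversity <- function(genus_counts) {
  stopifnot(is.matrix(genus_counts))
  if (any(genus_counts < 0)) stop_mg("counts must be non-negative")
  if (any(rowSums(genus_counts) == 0))
    stop_mg("individual with all-zero counts has undefined diversity")
  S <- as.integer(rowSums(genus_counts > 0))
  H <- vegan::diversity(genus_counts, index = "shannon")
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(richness = S, shannon = as.numeric(H), evenness = as.numeric(J),
             row.names = rownames(genus_counts))
}

#' Label-association QC on top principal components
#'
#' Computes the top-k principal components of the centered individuals x
#' taxa matrix and tests each component against a per-individual label by
#' Pearson (point-biserial for a two-level label) correlation. Used to
#' confirm that a nuisance label (e.g. season) is not correlated with the
#' leading axes of variation after normalization.
#'
#' @param values numeric matrix, individuals x taxa.
#' @param label per-individual label; numeric, or a factor/character with
#'   two levels.
#' @param k number of leading components to test (default 10).
#' @return data.frame with columns pc, correlation, p_value.
#' @export
pca_label_qc <- function(values, label, k = 10) {
  stopifnot(is.matrix(values))
  if (length(label) != nrow(values))
    stop_mg("label must have one entry per individual")
  if (is.character(label) || is.factor(label)) {
    label <- as.factor(as.character(label))
    if (nlevels(label) != 2)
      stop_mg("non-numeric labels must have exactly two levels")
    label <- as.numeric(label) - 1
  }
  if (sd(label) == 0) stop_mg("label is constant")
  k <- min(k, nrow(values) - 1L, ncol(values))
  if (nrow(values) <= k) stop_mg("need more individuals than components")
  pcs <- prcomp(values, center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  res <- lapply(seq_len(k), function(j) {
    ct <- cor.test(pcs[, j], label)
    data.frame(pc = j, correlation = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, res)
}

#' Run the full within-season preprocessing ladder
#'
#' Fixed order: subsample to `max_depth` -> combine technical replicates ->
#' relative abundance -> prevalence filter -> inverse normal transform per
#' taxon -> correlation pruning.
#'
#' @param table a [taxa_count_table()] holding one season's replicates.
#' @param max_depth subsampling depth (default 2e6 reads).
#' @param min_fraction prevalence threshold (default 0.75).
#' @param r_threshold pruning correlation threshold (default 0.9); `NULL`
#'   skips pruning (used before season averaging in the combined analysis).
#' @param seed subsampling seed.
#' @return list with `values` (normalized individuals x taxa matrix),
#'   `removed` (pruning report or NULL), `counts` (post-filter combined
#'   counts) and `samples`.
#' @export
preprocess_taxa <- function(table, max_depth = 2e6, min_fraction = 0.75,
                            r_threshold = 0.9, seed = NULL) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (length(unique(table$samples$season)) != 1)
    stop_mg("preprocess_taxa expects a single season; split the table first")
  sub <- subsample_counts(table, max_depth = max_depth, seed = seed)
  comb <- combine_replicates(sub)
  ra <- relative_abundance(comb)
  # proportions are relative to the total reads subsampled (all taxa),
  # computed before the rarity filter drops columns
  kept_rows <- match(ra$samples$individual, comb$samples$individual)
  kept <- taxa_count_table(comb$counts[kept_rows, , drop = FALSE],
                           ra$samples, comb$taxonomy)
  filt <- prevalence_filter(kept, min_fraction = min_fraction)
  prop <- ra$proportions[, colnames(filt$counts), drop = FALSE]
  vals <- apply(prop, 2, inverse_normal_transform)
  rownames(vals) <- filt$samples$individual
  removed <- NULL
  if (!is.null(r_threshold)) {
    pr <- correlation_prune(vals, filt$taxonomy, r_threshold = r_threshold)
    vals <- pr$values
    removed <- pr$removed
  }
  list(values = vals, removed = removed, counts = filt$counts,
       samples = filt$samples,
       taxonomy = filt$taxonomy[match(colnames(vals), filt$taxonomy$taxon), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
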