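# Genotype quality control (MAF, call rate, exact Hardy-Weinberg) and the
# genomic relationship matrix used as the random-effect covariance in the
# mixed models. Relatedness is estimated from the genotypes themselves via
# the centered GRM; a pedigree-based IBD matrix would fill the same role
# when a pedigree is available.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of probabilities of every heterozygote count (of the
#' correct parity) whose conditional probability does not exceed that of
#' the observed heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop_mg("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stop_mg("total genotype count is zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare allele count
  h <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | n, nA) up to a constant: multinomial weight * 2^h
  logw <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2)
  logw <- logw - max(logw)
  pr <- exp(logw) / sum(exp(logw))
  obs <- pr[match(n_Aa, h)]
  if (is.na(obs)) stop_mg("heterozygote count has impossible parity")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Genotype counts (dosage 0/1/2) per SNP, ignoring missing.
dosage_counts <- function(dosages) {
  n0 <- colSums(dosages == 0, na.rm = TRUE)
  n1 <- colSums(dosages == 1, na.rm = TRUE)
  n2 <- colSums(dosages == 2, na.rm = TRUE)
  cbind(n0 = n0, n1 = n1, n2 = n2)
}

#' SNP quality-control filter
#'
#' Removes SNPs failing any of: minor allele frequency >= `maf_min`
#' (computed on non-missing calls), call rate >= `call_rate_min`, exact
#' Hardy-Weinberg p-value >= `hwe_p_min`. All thresholds are inclusive.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,call_rate_min,hwe_p_min inclusive thresholds (defaults
#'   0.05, 0.95, 0.001).
#' @return list with `genotypes` (filtered) and `report` (data.frame of
#'   per-criterion failure counts; note the pedigree-based Mendelian-error
#'   filter is not applied, as it requires a pedigree).
#' @export
snp_qc <- function(g, maf_min = 0.05, call_rate_min = 0.95,
                   hwe_p_min = 0.001) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_prob(maf_min, "maf_min"); check_prob(call_rate_min, "call_rate_min")
  check_prob(hwe_p_min, "hwe_p_min")
  dos <- g$dosages
  maf <- snp_maf(dos)
  call_rate <- colMeans(!is.na(dos))
  cnt <- dosage_counts(dos)
  hwe_p <- vapply(seq_len(nrow(cnt)), function(s)
    if (sum(cnt[s, ]) == 0) 0 else hwe_exact_test(cnt[s, 1], cnt[s, 2], cnt[s, 3]),
    numeric(1))
  fail_maf <- !(maf >= maf_min) | is.na(maf)
  fail_call <- !(call_rate >= call_rate_min)
  fail_hwe <- !(hwe_p >= hwe_p_min)
  keep <- !(fail_maf | fail_call | fail_hwe)
  report <- data.frame(
    criterion = c("maf", "call_rate", "hwe", "any", "mendelian_errors"),
    n_failed = c(sum(fail_maf), sum(fail_call), sum(fail_hwe), sum(!keep), NA),
    note = c("", "", "", "",
             "not applied: requires pedigree information"))
  g$dosages <- dos[, keep, drop = FALSE]
  g$snp_meta <- g$snp_meta[keep, , drop = FALSE]
  list(genotypes = g, report = report)
}

#' Analysis-subset minor allele frequency filter
#'
#' Recomputes MAF on the individuals entering an analysis and removes SNPs
#' whose subset MAF is strictly below `maf_min` (a SNP at exactly the
#' threshold is kept).
#'
#' @param g a [genotype_matrix()].
#' @param individuals ids of the analysis subset.
#' @param maf_min threshold (default 0.10).
#' @return filtered [genotype_matrix()] restricted to `individuals`.
#' @export
analysis_maf_filter <- function(g, individuals, maf_min = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!length(individuals)) stop_mg("empty analysis subset")
  miss <- setdiff(individuals, rownames(g$dosages))
  if (length(miss))
    stop_mg("individuals absent from genotypes: %s",
            paste(head(miss, 5), collapse = ", "))
  dos <- g$dosages[individuals, , drop = FALSE]
  maf <- snp_maf(dos)
  keep <- !is.na(maf) & maf >= maf_min
  g$dosages <- dos[, keep, drop = FALSE]
  g$snp_meta <- g$snp_meta[keep, , drop = FALSE]
  g
}

#' Genomic relationship (kinship) matrix
#'
#' Centered method: `K = (1/p) * sum_s (g_s - 2 f_s)(g_s - 2 f_s)^T` over
#' the p SNPs, with `f_s` the allele frequency of SNP s; the standardized
#' method additionally divides each SNP term by `2 f_s (1 - f_s)`. Missing
#' dosages are mean-imputed per SNP; monomorphic SNPs are skipped with a
#' warning. The result is symmetric positive semi-definite and invariant
#' to SNP order and to allele-label flips.
#'
#' @param g a [genotype_matrix()] (post-QC).
#' @param method `"centered"` (default) or `"standardized"`.
#' @return numeric kinship matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(g, method = c("centered", "standardized")) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  dos <- g$dosages
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  f <- mu / 2
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    warn_mg("skipping %d monomorphic SNP(s) in kinship", sum(mono))
    dos <- dos[, !mono, drop = FALSE]
    f <- f[!mono]
  }
  if (!ncol(dos)) stop_mg("no polymorphic SNPs available for kinship")
  Z <- sweep(dos, 2, 2 * f, "-")
  if (method == "standardized")
    Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  K <- tcrossprod(Z) / ncol(dos)
  dimnames(K) <- list(rownames(g$dosages), rownames(g$dosages))
  (K + t(K)) / 2
}
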