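# Per-trait GWAS and covariate association. Traits are residualized on
# covariates by OLS, then scanned SNP-by-SNP with the kinship-aware LRT;
# multiple testing is controlled within each GWAS (Bonferroni on the SNP
# count, and Storey q-values at 0.1 / 0.2), never pooled across traits.

#' Build a covariate design matrix
#'
#' Intercept, numeric age, sex coded F = 0 / M = 1, and one-hot collection
#' group dropping the first level.
#'
#' @param covars a [covariate_table()].
#' @param drop character vector of covariates to leave out (e.g. the one
#'   being tested).
#' @return numeric design matrix with named columns.
#' @export
covariate_design <- function(covars, drop = character()) {
  n <- nrow(covars)
  X <- matrix(1, n, 1, dimnames = list(covars$individual, "intercept"))
  if (!"age" %in% drop) X <- cbind(X, age = covars$age)
  if (!"sex" %in% drop) X <- cbind(X, sex = as.numeric(covars$sex == "M"))
  if (!"collection_group" %in% drop) {
    grp <- factor(covars$collection_group)
    if (nlevels(grp) > 1) {
      dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE]
      colnames(dummies) <- paste0("group_", levels(grp)[-1])
      X <- cbind(X, dummies)
    }
  }
  X
}

#' Regress covariates out of a trait
#'
#' Ordinary least squares; the returned residuals are orthogonal to every
#' design column. A rank-deficient design is rejected with the offending
#' columns named.
#'
#' @param y numeric trait.
#' @param design numeric design matrix including the intercept.
#' @return numeric residual vector.
#' @export
residualize <- function(y, design) {
  design <- as.matrix(design)
  if (anyNA(y) || anyNA(design)) stop_mg("y and design must be complete")
  q <- qr(design)
  if (q$rank < ncol(design)) {
    bad <- colnames(design)[q$pivot[(q$rank + 1):ncol(design)]]
    stop_mg("rank-deficient design; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  as.vector(qr.resid(q, y))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 with the smoother method (pi0(l) =
#' mean(p > l) / (1 - l) on a ladder of l, smoothed by a cubic spline and
#' evaluated at the largest l), then q_i = min over p >= p_i of
#' pi0 * m * p / rank(p). With fewer than 100 p-values pi0 is fixed at 1,
#' which makes the q-values identical to Benjamini-Hochberg.
#'
#' @param p vector of p-values in [0, 1].
#' @return list with `q` (q-values, same order as `p`) and `pi0`.
#' @export
qvalues <- function(p) {
  if (!length(p)) stop_mg("empty p-value vector")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_mg("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (m >= 100) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- tryCatch(smooth.spline(lam, pi0_l, df = 3), error = function(e) NULL)
    if (!is.null(fit))
      pi0 <- predict(fit, x = max(lam))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  ord <- order(p)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[ord] <- pmin(q_ord, 1)
  list(q = q, pi0 = pi0)
}

#' Study-wise Bonferroni threshold
#'
#' `alpha` divided by the total number of trait x SNP tests summed over all
#' the component GWAS.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param tests_per_gwas list (or data.frame) of pairs `(n_traits, n_snps)`.
#' @return the study-wise p-value threshold.
#' @export
study_bonferroni <- function(alpha = 0.05, tests_per_gwas) {
  if (alpha <= 0 || alpha >= 1) stop_mg("alpha must be in (0, 1)")
  if (is.data.frame(tests_per_gwas))
    tests_per_gwas <- split(as.matrix(tests_per_gwas),
                            seq_len(nrow(tests_per_gwas)))
  if (!length(tests_per_gwas)) stop_mg("no GWAS supplied")
  total <- sum(vapply(tests_per_gwas, function(x) {
    if (length(x) != 2 || any(x < 1)) stop_mg("each GWAS needs (n_traits, n_snps)")
    as.double(x[1]) * as.double(x[2])
  }, numeric(1)))
  alpha / total
}

#' Genome-wide association scan for one trait
#'
#' Restricts the genotypes to the analysis individuals, applies the
#' analysis MAF filter (default 10%), mean-imputes residual missing calls,
#' and runs the kinship-aware likelihood-ratio test per SNP with an
#' intercept-only fixed design (covariates are residualized out of the
#' trait beforehand). Within-GWAS q-values are attached.
#'
#' @param y named trait residual vector (names = individual ids).
#' @param g a [genotype_matrix()].
#' @param K kinship matrix (or eigendecomposition aligned to `names(y)`).
#' @param maf_min analysis MAF threshold (default 0.10).
#' @param exact re-optimize lambda per SNP (default TRUE); FALSE reuses the
#'   null-model lambda, trading exactness for speed.
#' @param min_n refuse to run below this sample size (default 30).
#' @return data.frame of class `gwas_result`: id, chrom, pos, maf, beta,
#'   se, stat, p_lrt, q_value; attributes `n`, `trait`, `pi0`.
#' @param trait trait label carried in the result.
#' @export
run_gwas <- function(y, g, K, maf_min = 0.10, exact = TRUE, min_n = 30,
                     trait = "trait") {
  ids <- names(y)
  if (is.null(ids)) stop_mg("y must be named by individual id")
  if (length(ids) < min_n)
    stop_mg("refusing to run GWAS on %d individuals (< %d)", length(ids), min_n)
  if (sd(y) == 0) stop_mg("trait is constant")
  ga <- analysis_maf_filter(g, ids, maf_min = maf_min)
  if (!n_snps(ga)) stop_mg("no SNPs pass the analysis MAF filter")
  G <- ga$dosages
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  eig <- if (inherits(K, "kinship_eigen")) K else
    eigendecompose_kinship(K[ids, ids])
  scan <- lmm_scan(y, G, eig, exact = exact)
  qv <- qvalues(scan$p_lrt)
  res <- data.frame(id = ga$snp_meta$id, chrom = ga$snp_meta$chrom,
                    pos = ga$snp_meta$pos, maf = snp_maf(ga$dosages),
                    beta = scan$beta, se = scan$se, stat = scan$stat,
                    p_lrt = scan$p_lrt, q_value = qv$q,
                    row.names = NULL)
  attr(res, "n") <- length(ids)
  attr(res, "trait") <- trait
  attr(res, "pi0") <- qv$pi0
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Genomic-control inflation factor
#'
#' Median of the per-SNP chi-squared statistics divided by the null median
#' (0.4549 for one degree of freedom).
#'
#' @param p vector of GWAS p-values.
#' @return lambda_GC.
#' @export
genomic_control_lambda <- function(p) {
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Kinship-aware association of taxa with a single covariate
#'
#' For each taxon: residualize the normalized abundance on the *other*
#' covariates, then run the mixed-model LRT with the tested covariate as
#' the predictor and an intercept-only design. Q-values are computed across
#' taxa.
#'
#' @param values normalized taxa matrix (individuals x taxa, row names =
#'   ids).
#' @param predictor `"age"` or `"sex"`.
#' @param covars a [covariate_table()] aligned to the rows of `values`.
#' @param K kinship matrix aligned to the rows of `values`.
#' @return data.frame with columns taxon, beta, p_lrt, q_value.
#' @export
covariate_association_scan <- function(values, predictor = c("age", "sex"),
                                       covars, K) {
  predictor <- match.arg(predictor)
  ids <- rownames(values)
  stopifnot(!is.null(ids), all(covars$individual == ids))
  x <- if (predictor == "age") covars$age else as.numeric(covars$sex == "M")
  if (sd(x) == 0)
    stop_mg("covariate '%s' is constant in this sample", predictor)
  W_other <- covariate_design(covars, drop = predictor)
  eig <- eigendecompose_kinship(K[ids, ids])
  res <- lapply(colnames(values), function(tx) {
    y <- residualize(values[, tx], W_other)
    fit <- lrt_predictor(y, x, W = matrix(1, length(y), 1), K = eig)
    data.frame(taxon = tx, beta = fit$beta, se = fit$se, p_lrt = fit$p_lrt)
  })
  res <- do.call(rbind, res)
  res$q_value <- qvalues(res$p_lrt)$q
  res
}

#' Permutation test for heritability-GWAS overlap
#'
#' Observed statistic: the number of taxa flagged both heritable (non-zero
#' PVE) and carrying at least one genome-wide significant association. The
#' null permutes the heritability flags across taxa; the empirical p-value
#' is the fraction of permutations with overlap greater than or equal to
#' the observed count.
#'
#' @param nonzero_flags logical vector, per-taxon heritability flag.
#' @param hit_flags logical vector, per-taxon GWAS-hit flag.
#' @param n_perm number of permutations (default 10000).
#' @param seed permutation seed.
#' @param plus_one use the (count + 1) / (n_perm + 1) estimator instead of
#'   the literal count / n_perm (default FALSE).
#' @return list with `observed`, `p`, `null` (permutation overlaps).
#' @export
herit_gwas_overlap_test <- function(nonzero_flags, hit_flags, n_perm = 10000,
                                    seed = NULL, plus_one = FALSE) {
  if (length(nonzero_flags) != length(hit_flags))
    stop_mg("flag vectors must have equal length")
  if (!is_count(n_perm)) stop_mg("n_perm must be a positive integer")
  observed <- sum(nonzero_flags & hit_flags)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      sum(sample(nonzero_flags) & hit_flags), numeric(1))
  })
  p <- if (plus_one) (sum(null >= observed) + 1) / (n_perm + 1)
  else sum(null >= observed) / n_perm
  list(observed = observed, p = p, null = null)
}

#' Simple linear-model sex scan (no kinship)
#'
#' Per-taxon ordinary linear model of normalized abundance on sex, with the
#' usual t-test p-value and q-values across taxa. This is the
#' kinship-free analysis appropriate for unrelated-population replication
#' panels.
#'
#' @param values normalized taxa matrix (individuals x taxa).
#' @param sex character vector of F/M.
#' @return data.frame with columns taxon, beta, p, q_value.
#' @export
ols_sex_scan <- function(values, sex) {
  sexn <- as.numeric(as.character(sex) == "M")
  if (length(unique(sexn)) < 2) stop_mg("both sexes must be present")
  res <- lapply(colnames(values), function(tx) {
    fit <- summary(stats::lm(values[, tx] ~ sexn))$coefficients
    data.frame(taxon = tx, beta = fit["sexn", 1], p = fit["sexn", 4])
  })
  res <- do.call(rbind, res)
  res$q_value <- qvalues(res$p)$q
  res
}

#' Hypergeometric overlap test between two taxon sets
#'
#' Upper-tail probability of observing at least the actual overlap when
#' `|A|` draws are taken at random from the universe.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all tested taxa.
#' @return p-value `P(X >= |A intersect B|)`.
#' @export
overlap_hypergeom <- function(setA, setB, universe) {
  if (!length(universe)) stop_mg("empty universe")
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop_mg("sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  phyper(k - 1, length(setA), length(universe) - length(setA),
         length(setB), lower.tail = FALSE)
}

#' Significance summary for a set of GWAS results
#'
#' Per trait: does any SNP pass the within-GWAS Bonferroni threshold
#' (alpha / n_snps), q <= 0.1, q <= 0.2 — the three criteria reported side
#' by side in the study summary tables.
#'
#' @param results named list of `gwas_result` data.frames.
#' @param alpha within-GWAS Bonferroni alpha (default 0.05).
#' @return data.frame with one row per trait and logical hit columns.
#' @export
gwas_significance_summary <- function(results, alpha = 0.05) {
  rows <- lapply(names(results), function(tr) {
    r <- results[[tr]]
    thr <- alpha / nrow(r)
    data.frame(trait = tr, n_snps = nrow(r),
               bonferroni = any(r$p_lrt <= thr),
               q_le_0.1 = any(r$q_value <= 0.1),
               q_le_0.2 = any(r$q_value <= 0.2),
               min_p = min(r$p_lrt))
  })
  out <- do.call(rbind, rows)
  out$total_significant <- out$bonferroni | out$q_le_0.2
  out
}
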