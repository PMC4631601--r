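test_that("residualization matches the normal-equation oracle and is orthogonal", {
  set.seed(101)
  n <- 50
  X <- cbind(intercept = 1, age = rnorm(n), grp = rbinom(n, 1, 0.4))
  y <- rnorm(n)
  r <- residualize(y, X)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(r, as.vector(oracle), tolerance = 1e-10)
  expect_true(all(abs(crossprod(X, r)) < 1e-8))

  # covariate orthogonal to y: residuals equal centered y
  x_orth <- residualize(rnorm(n), cbind(1, y))
  r2 <- residualize(y, cbind(intercept = 1, x = x_orth))
  expect_equal(r2, y - mean(y), tolerance = 1e-8)

  # y exactly linear in a covariate: residuals vanish
  age <- runif(n, 20, 70)
  r3 <- residualize(2 + 0.3 * age, cbind(intercept = 1, age = age))
  expect_lt(max(abs(r3)), 1e-10)

  Xbad <- cbind(intercept = 1, a = X[, 2], a_copy = X[, 2])
  expect_error(residualize(y, Xbad), "a_copy")
})

test_that("q-values reduce to Benjamini-Hochberg for small m and behave at the edges", {
  out <- qvalues(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$pi0, 1)
  expect_equal(out$q, rep(0.04, 4))
  expect_equal(out$q, p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"))

  expect_equal(qvalues(rep(1, 10))$q, rep(1, 10))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  # q monotone in p
  set.seed(31)
  p <- runif(500)
  q <- qvalues(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("pi0 is estimated near 1 for uniform p-values", {
  set.seed(41)
  expect_gt(qvalues(runif(10000))$pi0, 0.9)
  expect_lte(qvalues(runif(10000))$pi0, 1)
})

test_that("study-wise Bonferroni threshold is alpha over total tests", {
  expect_equal(study_bonferroni(0.05, list(c(1, 1))), 0.05)
  one <- study_bonferroni(0.05, list(c(10, 1000)))
  expect_equal(study_bonferroni(0.05, list(c(10, 1000), c(10, 1000))), one / 2)
  expect_error(study_bonferroni(0.05, list()), "no GWAS")
})

test_that("a planted QTL is recovered as the top association with q <= 0.2", {
  hits <- 0; qpass <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_individuals = 150, n_snps = 300, n_families = 38,
                      family_size = 4, n_taxa = 2,
                      planted_effects = data.frame(taxon = "genus_001",
                                                   snp = "snp00123",
                                                   effect = 1.0),
                      maf_range = c(0.2, 0.5), seed = 9000 + s)
    st <- simulate_study(cfg)
    ids <- st$covariates$individual
    design <- covariate_design(st$covariates)
    y <- setNames(residualize(st$truth$latent[, "genus_001"], design), ids)
    K <- suppressWarnings(kinship_matrix(st$genotypes))
    res <- run_gwas(y, st$genotypes, K, exact = FALSE)
    top <- res$id[which.min(res$p_lrt)]
    if (top == "snp00123") hits <- hits + 1
    if (res$q_value[res$id == "snp00123"] <= 0.2) qpass <- qpass + 1
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
  expect_gte(qpass, ceiling(0.9 * n_seeds))
})

test_that("run_gwas guards its inputs", {
  fix <- make_sibship_fixture(n_ind = 40, n_snps = 60, seed = 11)
  ids <- rownames(fix$genotypes$dosages)
  y <- setNames(rnorm(40), ids)
  expect_error(run_gwas(y[1:10], fix$genotypes, fix$K), "refusing")
  expect_error(run_gwas(setNames(rep(1, 40), ids), fix$genotypes, fix$K),
               "constant")
  expect_error(run_gwas(unname(y), fix$genotypes, fix$K), "named")
})

test_that("null GWAS p-values are uniform (DKW band) with calibrated lambda_GC", {
  fix <- make_sibship_fixture(n_ind = 150, n_snps = 500, seed = 83)
  set.seed(83)
  lams <- numeric(4); pall <- NULL
  for (s in 1:4) {
    y <- setNames(rnorm(150), rownames(fix$genotypes$dosages))
    res <- run_gwas(y, fix$genotypes, fix$eig, exact = FALSE)
    lams[s] <- genomic_control_lambda(res$p_lrt)
    pall <- c(pall, res$p_lrt)
  }
  expect_gt(median(lams), 0.9)
  expect_lt(median(lams), 1.1)
  # DKW band at alpha = 0.01 for the pooled ECDF
  m <- length(pall)
  eps <- sqrt(log(2 / 0.01) / (2 * m))
  grid <- seq(0.01, 0.99, by = 0.01)
  ecdf_dev <- max(abs(vapply(grid, function(t) mean(pall <= t), numeric(1)) - grid))
  expect_lt(ecdf_dev, eps + 0.02)
})

test_that("covariate scans find a planted sex effect and report its direction", {
  found <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_individuals = 120, n_snps = 100, n_families = 30,
                      family_size = 4, n_taxa = 12,
                      sex_effects = c(genus_005 = 1.0), seed = 4000 + s)
    st <- simulate_study(cfg)
    vals <- st$truth$latent
    rownames(vals) <- st$covariates$individual
    res <- covariate_association_scan(vals, "sex", st$covariates, st$kinship)
    hit <- res$taxon[res$q_value <= 0.05]
    if ("genus_005" %in% hit) found <- found + 1
    expect_gt(res$beta[res$taxon == "genus_005"], 0)  # M coded 1, effect +1
  }
  expect_gte(found, 9)
})

test_that("age scan recovers the sign of an age-linear taxon", {
  cfg <- sim_config(n_individuals = 100, n_snps = 80, n_families = 25,
                    family_size = 4, n_taxa = 4, seed = 19)
  st <- simulate_study(cfg)
  vals <- st$truth$latent
  vals[, 1] <- vals[, 1] + 0.5 * scale(st$covariates$age)
  rownames(vals) <- st$covariates$individual
  res <- covariate_association_scan(vals, "age", st$covariates, st$kinship)
  expect_gt(res$beta[1], 0)
  expect_lt(res$p_lrt[1], 0.05)
})

test_that("overlap permutation p matches the hypergeometric tail", {
  # 10 taxa, 5 heritable, 5 hits, observed overlap 5:
  # P(X >= 5) = choose(5,5)*choose(5,0)/choose(10,5) = 1/252
  herit <- c(rep(TRUE, 5), rep(FALSE, 5))
  hits <- c(rep(TRUE, 5), rep(FALSE, 5))
  out <- herit_gwas_overlap_test(herit, hits, n_perm = 10000, seed = 2)
  expect_equal(out$observed, 5)
  p_exact <- 1 / choose(10, 5)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(out$p - p_exact), 4 * mc_se)

  # disjoint flags: observed 0 is always matched or beaten
  out0 <- herit_gwas_overlap_test(c(TRUE, TRUE, FALSE, FALSE),
                                  c(FALSE, FALSE, TRUE, TRUE),
                                  n_perm = 500, seed = 3)
  expect_equal(out0$observed, 0)
  expect_equal(out0$p, 1)
})

test_that("jointly permuting both flag vectors leaves the empirical p unbiased", {
  set.seed(71)
  ps <- replicate(60, {
    herit <- sample(c(rep(TRUE, 4), rep(FALSE, 8)))
    hits <- sample(c(rep(TRUE, 5), rep(FALSE, 7)))
    herit_gwas_overlap_test(herit, hits, n_perm = 400,
                            seed = sample.int(1e6, 1))$p
  })
  # under exchangeability the empirical p is valid (super-uniform: the
  # >= convention with a discrete statistic can only over-cover)
  for (a in c(0.1, 0.3, 0.5))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 60))
})

test_that("hypergeometric overlap test matches the closed form", {
  # universe 10, |A| = 5, |B| = 4, overlap 4 -> C(5,4) C(5,0) / C(10,4)
  u <- paste0("t", 1:10)
  A <- u[1:5]; B <- u[2:5]
  expect_equal(overlap_hypergeom(A, B, u),
               choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_gt(overlap_hypergeom(u[1], u[2], u), 0.89)  # tiny disjoint sets
  expect_error(overlap_hypergeom(A, B, character()), "empty")
})

test_that("the OLS sex scan equals the kinship scan with vanishing kinship", {
  cfg <- sim_config(n_individuals = 80, n_snps = 60, n_families = 20,
                    family_size = 4, n_taxa = 6,
                    sex_effects = c(genus_002 = 0.8), seed = 303)
  st <- simulate_study(cfg)
  vals <- st$truth$latent
  rownames(vals) <- st$covariates$individual
  ols <- ols_sex_scan(vals, st$covariates$sex)
  expect_equal(ols$q_value, qvalues(ols$p)$q)
  # with K ~ 0 the mixed model collapses to the linear model on the
  # covariate-residualized trait: betas agree, p-values to chi2-vs-t slack
  K0 <- diag(1e-12, 80)
  dimnames(K0) <- list(rownames(vals), rownames(vals))
  mm <- covariate_association_scan(vals, "sex", st$covariates, K0)
  W_other <- covariate_design(st$covariates, drop = "sex")
  vals_res <- apply(vals, 2, residualize, design = W_other)
  rownames(vals_res) <- rownames(vals)
  ols_res <- ols_sex_scan(vals_res, st$covariates$sex)
  expect_equal(mm$beta, ols_res$beta, tolerance = 1e-6)
  expect_equal(mm$p_lrt, ols_res$p, tolerance = 0.03)
})

test_that("significance summaries report all three criteria per trait", {
  fix <- make_sibship_fixture(n_ind = 60, n_snps = 150, seed = 121)
  ids <- rownames(fix$genotypes$dosages)
  set.seed(121)
  res <- list(
    null_trait = run_gwas(setNames(rnorm(60), ids), fix$genotypes, fix$eig,
                          exact = FALSE),
    qtl_trait = run_gwas(
      setNames(fix$genotypes$dosages[, 10] + rnorm(60, 0, 0.3), ids),
      fix$genotypes, fix$eig, exact = FALSE))
  summ <- gwas_significance_summary(res)
  expect_equal(summ$trait, c("null_trait", "qtl_trait"))
  expect_true(all(c("bonferroni", "q_le_0.1", "q_le_0.2") %in% names(summ)))
  expect_true(summ$total_significant[2])
})
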