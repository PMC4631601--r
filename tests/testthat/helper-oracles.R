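# Independent oracles used across the suite. Each is a deliberately naive
# implementation (per-base scans, full enumerations, closed forms) kept
# separate from the package's own code paths.

# Per-base-pair membership oracle for interval sets on one chromosome.
bp_members <- function(intervals, limit) {
  hit <- rep(FALSE, limit)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < limit) hit[(s + 1):min(e, limit)] <- TRUE
  }
  hit
}

# Exact two-sided HWE p-value by direct enumeration with factorials
# (small totals only).
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  na <- 2 * n2 + n1
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  w <- sapply(hs, function(h) {
    a <- (nA - h) / 2; b <- (na - h) / 2
    factorial(n) / (factorial(a) * factorial(h) * factorial(b)) * 2^h
  })
  pr <- w / sum(w)
  obs <- pr[match(n1, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Dense multivariate-normal ML log-likelihood for the mixed model,
# evaluated by direct solves (no rotation).
dense_ml_loglik <- function(y, X, K, sg2, se2) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  b <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r) + n * log(2 * pi)))
}

# Brute-force correlated-taxon pruning: enumerate all violating pairs,
# apply the removal rules one pair at a time (highest r first, ties by
# name), recompute after each removal.
prune_oracle <- function(values, taxonomy, r_threshold = 0.9) {
  rank_of <- c(phylum = 1, class = 2, order = 3, family = 4, genus = 5)
  repeat {
    if (ncol(values) < 2) break
    pairs <- NULL
    cn <- colnames(values)
    for (i in seq_len(ncol(values) - 1)) {
      for (j in (i + 1):ncol(values)) {
        r <- cor(values[, i], values[, j])
        if (!is.na(r) && r >= r_threshold)
          pairs <- rbind(pairs, data.frame(a = cn[i], b = cn[j], r = r))
      }
    }
    if (is.null(pairs)) break
    pairs <- pairs[order(-pairs$r, pmin(pairs$a, pairs$b),
                         pmax(pairs$a, pairs$b)), , drop = FALSE]
    a <- pairs$a[1]; b <- pairs$b[1]
    la <- rank_of[[taxonomy$level[taxonomy$taxon == a]]]
    lb <- rank_of[[taxonomy$level[taxonomy$taxon == b]]]
    drop <- if (la != lb) { if (la < lb) a else b } else min(a, b)
    values <- values[, colnames(values) != drop, drop = FALSE]
  }
  colnames(values)
}

# Small aligned genotype/kinship fixture used by several LMM tests.
make_sibship_fixture <- function(n_ind = 120, n_snps = 400, seed = 42,
                                 family_size = 4) {
  cfg <- sim_config(n_individuals = n_ind, n_snps = n_snps,
                    n_families = ceiling(n_ind / family_size),
                    family_size = family_size, seed = seed)
  g <- simulate_genotypes(cfg)
  # small fixtures can carry monomorphic draws; the skip is expected here
  K <- suppressWarnings(kinship_matrix(g$genotypes))
  list(config = cfg, genotypes = g$genotypes, true_kinship = g$kinship,
       family = g$family, K = K, eig = eigendecompose_kinship(K))
}
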