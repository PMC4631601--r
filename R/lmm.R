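# Univariate linear mixed model y ~ N(X beta, sigma_g^2 K + sigma_e^2 I),
# written from scratch. One eigendecomposition K = U D U' rotates the model
# into independent observations with variances sigma_e^2 (lambda d_i + 1),
# lambda = sigma_g^2 / sigma_e^2; beta and sigma_e^2 are profiled out and
# the 1-d likelihood in lambda is maximized by a log-spaced grid followed
# by Brent refinement (the profiled likelihood can be multimodal, so the
# grid guards against local maxima). ML fits feed likelihood-ratio tests;
# REML fits feed variance-component (PVE) estimation.

LOG10_LAMBDA_RANGE <- c(-5, 5)
LAMBDA_GRID_N <- 50

#' Eigendecompose a kinship matrix for mixed-model fitting
#'
#' @param K symmetric kinship matrix.
#' @return list of class `kinship_eigen` with `values` (eigenvalues,
#'   negatives clipped at zero with a warning) and `vectors` (rotation U).
#' @export
eigendecompose_kinship <- function(K) {
  if (!all(is.finite(K))) stop_mg("kinship contains non-finite entries")
  if (!isSymmetric(unname(K), tol = 1e-8)) stop_mg("kinship must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1)))
    warn_mg("clipping %d negative kinship eigenvalue(s) at zero",
            sum(e$values < 0))
  e$values <- pmax(e$values, 0)
  structure(list(values = e$values, vectors = e$vectors,
                 ids = rownames(K)), class = "kinship_eigen")
}

as_kinship_eigen <- function(K) {
  if (inherits(K, "kinship_eigen")) K else eigendecompose_kinship(K)
}

# Profiled log-likelihood pieces at a fixed lambda, in the rotated basis.
# Uty: rotated response; UtX: rotated design; d: eigenvalues.
profile_fit <- function(lambda, Uty, UtX, d, reml = FALSE) {
  n <- length(Uty); p <- ncol(UtX)
  w <- 1 / (lambda * d + 1)
  A <- crossprod(UtX, w * UtX)
  b <- crossprod(UtX, w * Uty)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  r <- Uty - UtX %*% beta
  rss <- sum(w * r^2)
  logdet_v <- sum(log(lambda * d + 1))
  if (reml) {
    df <- n - p
    s2 <- rss / df
    logdet_a <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * (df * (log(2 * pi) + 1 + log(s2)) + logdet_v + logdet_a)
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + 1 + log(s2)) + logdet_v)
  }
  list(loglik = ll, beta = as.vector(beta), sigma_e2 = s2, rss = rss,
       chol_A = ch, weights = w)
}

# Maximize the profiled likelihood over log10(lambda) in a fixed range:
# coarse grid then Brent on the bracketing interval.
optimize_lambda <- function(Uty, UtX, d, reml = FALSE,
                            grid_n = LAMBDA_GRID_N) {
  grid <- seq(LOG10_LAMBDA_RANGE[1], LOG10_LAMBDA_RANGE[2],
              length.out = grid_n)
  ll <- vapply(grid, function(lg)
    profile_fit(10^lg, Uty, UtX, d, reml)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  opt <- optimize(function(lg) profile_fit(10^lg, Uty, UtX, d, reml)$loglik,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  best_lg <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  boundary <- best_lg <= LOG10_LAMBDA_RANGE[1] + 1e-4 ||
    best_lg >= LOG10_LAMBDA_RANGE[2] - 1e-4
  list(lambda = 10^best_lg, loglik = max(opt$objective, ll[i]),
       boundary = boundary)
}

#' Fit the linear mixed model
#'
#' Fits `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)` by both maximum
#' likelihood and REML, profiling beta and sigma_e^2 and optimizing the
#' variance ratio lambda = sigma_g^2 / sigma_e^2 on a log10 grid over
#' \[-5, 5\] with Brent refinement.
#'
#' @param y numeric response (residualized upstream; no missing values).
#' @param X fixed-effect design matrix (include the intercept).
#' @param K kinship matrix or a [eigendecompose_kinship()] result.
#' @return list of class `lmm_fit` with elements `lambda`, `sigma_g2`,
#'   `sigma_e2`, `loglik` (ML), `beta`, `beta_se`, `reml` (REML
#'   counterparts) and `boundary` flags.
#' @export
fit_lmm <- function(y, X, K) {
  X <- as.matrix(X)
  n <- length(y)
  if (anyNA(y) || anyNA(X)) stop_mg("y and X must be complete")
  if (n < ncol(X) + 2) stop_mg("too few observations for the design")
  if (qr(X)$rank < ncol(X)) stop_mg("singular fixed-effect design")
  eig <- as_kinship_eigen(K)
  if (length(eig$values) != n) stop_mg("kinship dimension does not match y")
  U <- eig$vectors; d <- eig$values
  Uty <- crossprod(U, y)[, 1]
  UtX <- crossprod(U, X)
  ml <- optimize_lambda(Uty, UtX, d, reml = FALSE)
  ml_fit <- profile_fit(ml$lambda, Uty, UtX, d, reml = FALSE)
  reml <- optimize_lambda(Uty, UtX, d, reml = TRUE)
  reml_fit <- profile_fit(reml$lambda, Uty, UtX, d, reml = TRUE)
  cov_beta <- ml_fit$sigma_e2 * chol2inv(ml_fit$chol_A)
  structure(list(
    lambda = ml$lambda,
    sigma_g2 = ml$lambda * ml_fit$sigma_e2,
    sigma_e2 = ml_fit$sigma_e2,
    loglik = ml_fit$loglik,
    beta = ml_fit$beta,
    beta_se = sqrt(diag(cov_beta)),
    boundary = ml$boundary,
    reml = list(lambda = reml$lambda,
                sigma_g2 = reml$lambda * reml_fit$sigma_e2,
                sigma_e2 = reml_fit$sigma_e2,
                loglik = reml_fit$loglik,
                beta = reml_fit$beta,
                boundary = reml$boundary),
    n = n), class = "lmm_fit")
}

#' Likelihood-ratio test for one predictor in the mixed model
#'
#' Compares ML fits of `y ~ W` and `y ~ W + x` (lambda re-optimized in
#' each); the statistic `2 (l1 - l0)` is referred to chi-squared with one
#' degree of freedom, with negative statistics clipped to zero.
#'
#' @param y response vector.
#' @param x tested predictor.
#' @param W covariate design (default intercept only).
#' @param K kinship matrix or eigendecomposition.
#' @param null_fit optional pre-computed null [fit_lmm()] on `W` (saves the
#'   null optimization when scanning many predictors).
#' @return list with `beta`, `se`, `p_lrt`, `stat`.
#' @export
lrt_predictor <- function(y, x, W = NULL, K = NULL, null_fit = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (sd(x) == 0) stop_mg("tested predictor is constant")
  X1 <- cbind(W, x)
  if (qr(X1)$rank < ncol(X1))
    stop_mg("predictor is collinear with the covariate design")
  if (is.null(null_fit)) null_fit <- fit_lmm(y, W, K)
  alt <- fit_lmm(y, X1, K)
  stat <- max(0, 2 * (alt$loglik - null_fit$loglik))
  list(beta = alt$beta[ncol(X1)], se = alt$beta_se[ncol(X1)],
       stat = stat, p_lrt = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Chip heritability (proportion of variance explained)
#'
#' REML variance components with an intercept-only design give
#' `PVE = sigma_g^2 (tr K / n) / (sigma_g^2 (tr K / n) + sigma_e^2)`; the
#' trace normalization keeps the estimate invariant to the overall scale of
#' K. The standard error comes from the delta method on the inverse
#' observed information of (sigma_g^2, sigma_e^2) at the REML optimum, and
#' the estimate is flagged non-zero when `pve - se > 0` (the error bar does
#' not intersect zero).
#'
#' @param y trait values, already residualized of covariates.
#' @param K kinship matrix or eigendecomposition built from all analysis
#'   SNPs.
#' @return list of class `pve_estimate` with `pve`, `se`, `nonzero`,
#'   `sigma_g2`, `sigma_e2`.
#' @export
estimate_pve <- function(y, K) {
  if (sd(y) == 0) stop_mg("trait has zero variance")
  eig <- as_kinship_eigen(K)
  n <- length(y)
  if (length(eig$values) != n) stop_mg("kinship dimension does not match y")
  U <- eig$vectors; d <- eig$values
  Uty <- crossprod(U, y)[, 1]
  UtX <- crossprod(U, matrix(1, n, 1))
  fit <- optimize_lambda(Uty, UtX, d, reml = TRUE)
  pf <- profile_fit(fit$lambda, Uty, UtX, d, reml = TRUE)
  sg2 <- fit$lambda * pf$sigma_e2
  se2 <- pf$sigma_e2
  cbar <- mean(d)  # tr(K) / n survives the rotation
  pve <- sg2 * cbar / (sg2 * cbar + se2)
  # observed information of the REML log-likelihood in (sigma_g2, sigma_e2)
  ll_theta <- function(th) {
    if (any(th <= 0)) return(-Inf)
    v <- th[1] * d + th[2]
    w <- 1 / v
    A <- crossprod(UtX, w * UtX)
    beta <- solve(A, crossprod(UtX, w * Uty))
    r <- Uty - UtX %*% beta
    -0.5 * (sum(log(v)) + determinant(A, logarithm = TRUE)$modulus +
              sum(w * r^2) + (n - 1) * log(2 * pi))
  }
  theta <- c(max(sg2, 1e-10 * var(y)), max(se2, 1e-10 * var(y)))
  den <- (sg2 * cbar + se2)^2
  grad <- c(cbar * se2 / den, -sg2 * cbar / den)
  delta_se <- function(info) {
    cov_theta <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov_theta)) return(NA_real_)
    v <- drop(t(grad) %*% cov_theta %*% grad)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  H <- tryCatch(pracma::hessian(ll_theta, theta), error = function(e) NULL)
  se <- if (!is.null(H) && all(is.finite(H))) delta_se(-H) else NA_real_
  if (is.na(se)) {
    # expected (Fisher) information: finite even at the sigma_g2 boundary,
    # where the observed-information surface is one-sided
    v <- theta[1] * d + theta[2]
    w <- 1 / v
    x0 <- UtX[, 1]
    Pm <- diag(w) - (w * x0) %*% t(w * x0) / sum(w * x0^2)
    PA <- Pm * rep(d, each = n)  # P %*% diag(d)
    info <- 0.5 * matrix(c(sum(PA * t(PA)), sum(PA * t(Pm)),
                           sum(PA * t(Pm)), sum(Pm * t(Pm))), 2)
    se <- delta_se(info)
    if (is.na(se)) se <- Inf
  }
  structure(list(pve = pve, se = se, nonzero = (pve - se) > 0,
                 sigma_g2 = sg2, sigma_e2 = se2,
                 boundary = fit$boundary), class = "pve_estimate")
}

#' @export
print.pve_estimate <- function(x, ...) {
  cat(sprintf("PVE = %.3f +/- %.3f (%szero)\n", x$pve, x$se,
              if (x$nonzero) "non-" else ""))
  invisible(x)
}

# Vectorized per-SNP mixed-model scan in the rotated basis.
#
# exact = TRUE re-optimizes lambda per SNP (two full ML fits per test);
# exact = FALSE ("fast" mode) reuses the null-model lambda and computes
# every per-SNP weighted regression in closed form, which is what makes
# 10^4 phenotype permutations tractable. W is intercept-only: covariates
# are residualized out of y upstream, mirroring the two-stage design.
lmm_scan <- function(y, G, eig, exact = TRUE, grid_n = LAMBDA_GRID_N,
                     UtG = NULL) {
  n <- length(y)
  U <- eig$vectors; d <- eig$values
  Uty <- crossprod(U, y)[, 1]
  Utx0 <- crossprod(U, matrix(1, n, 1))
  null <- optimize_lambda(Uty, Utx0, d, reml = FALSE, grid_n = grid_n)
  null_ll <- null$loglik
  # the rotated genotypes do not depend on y, so permutation scans pass
  # them in precomputed
  if (is.null(UtG)) UtG <- crossprod(U, G)
  m <- ncol(G)
  if (exact) {
    beta <- se <- stat <- numeric(m)
    for (j in seq_len(m)) {
      X1 <- cbind(Utx0, UtG[, j])
      alt <- optimize_lambda(Uty, X1, d, reml = FALSE, grid_n = grid_n)
      pf <- profile_fit(alt$lambda, Uty, X1, d, reml = FALSE)
      stat[j] <- max(0, 2 * (alt$loglik - null_ll))
      beta[j] <- pf$beta[2]
      se[j] <- sqrt(pf$sigma_e2 * chol2inv(pf$chol_A)[2, 2])
    }
  } else {
    w <- 1 / (null$lambda * d + 1)
    x0 <- Utx0[, 1]
    S00 <- sum(w * x0 * x0)
    S0y <- sum(w * x0 * Uty)
    Syy <- sum(w * Uty * Uty)
    rss0 <- Syy - S0y^2 / S00
    Sgy <- crossprod(UtG, w * Uty)[, 1]
    Sg0 <- crossprod(UtG, w * x0)[, 1]
    Sgg <- crossprod(UtG^2, w)[, 1]
    g_perp <- pmax(Sgg - Sg0^2 / S00, .Machine$double.eps)
    g_r0 <- Sgy - Sg0 * S0y / S00
    drss <- g_r0^2 / g_perp
    rss1 <- pmax(rss0 - drss, .Machine$double.eps)
    stat <- pmax(0, n * log(rss0 / rss1))
    beta <- g_r0 / g_perp
    se <- sqrt((rss1 / n) / g_perp)
  }
  data.frame(beta = beta, se = se, stat = stat,
             p_lrt = pchisq(stat, df = 1, lower.tail = FALSE),
             row.names = colnames(G))
}
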