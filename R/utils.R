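#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test cutree dist hclust lm.fit median optimize
#'   pchisq phyper prcomp qchisq qnorm rbinom rhyper rmultinom rnorm runif
#'   sd setNames smooth.spline predict var complete.cases p.adjust rchisq
#' @importFrom utils head read.table write.table modifyList
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All exported stochastic operations funnel
# through this so a single root seed makes whole runs reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a root seed and a stream offset; keeps every
# generator on its own stream while remaining a function of the root alone.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset * 1000003) %% 2147483647L)
}

stop_mg <- function(...) stop(sprintf(...), call. = FALSE)

warn_mg <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_mg("'%s' must be a single value in [0, 1]", name)
  invisible(x)
}
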