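#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' All randomness in isoTP flows from a single user-supplied integer seed.
#' Independent stochastic stages (cohort generation, each MCMC chain, TEF and
#' beta draws, each scenario in a batch) receive their own sub-seed via this
#' splitting rule, so that stages are mutually independent and insensitive to
#' the order in which sibling stages run.
#'
#' The rule is a polynomial string hash of `key` (base 31, modulo 2^31 - 1)
#' added to the base seed, reduced modulo 2^31 - 1. It is deterministic,
#' platform-independent, and keeps seeds within R's integer range.
#'
#' @param seed integer base seed.
#' @param key character scalar naming the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(42, "cohort")
#' split_seed(42, "chain1")
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% m
  s <- (abs(as.numeric(seed)) + h) %% m
  as.integer(if (s < 1) 1 else s)
}

# Truncated-normal draws on (lower, Inf) by inverse-CDF so that a shared
# uniform stream gives monotone coupling across sd values. sd = 0 degenerates
# to the constant mean.
rtnorm_lower <- function(n, mean, sd, lower = 0, u = NULL) {
  if (sd == 0) {
    if (mean <= lower) stop("degenerate truncated normal: mean below truncation bound")
    return(rep(mean, n))
  }
  if (is.null(u)) u <- stats::runif(n)
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, the standard guard against within-chain trends that the classic
#' diagnostic misses.
#'
#' @param draws a numeric matrix, iterations x chains.
#' @return a single R-hat value (>= 1 in expectation; ~1 at convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  pieces <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(pieces)
  if (stats::var(as.vector(pieces)) == 0) return(1)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

# Effective sample size summed over chains (coda's spectral estimator).
ess_chains <- function(draws) {
  draws <- as.matrix(draws)
  if (stats::var(as.vector(draws)) == 0) return(Inf)
  mcl <- coda::as.mcmc.list(lapply(seq_len(ncol(draws)),
                                   function(j) coda::mcmc(draws[, j])))
  as.numeric(coda::effectiveSize(mcl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
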