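#' Trophic enrichment factor (TEF) prior
#'
#' Normal prior on the per-trophic-step delta15N enrichment, in per-mil.
#' `sd = 0` means a fixed constant. During estimation one TEF value is drawn
#' per retained posterior draw (truncated at zero), propagating TEF
#' uncertainty into the trophic-position posterior.
#'
#' @param mean prior mean (> 0), per-mil.
#' @param sd prior SD (>= 0), per-mil.
#' @return object of class `"tef_prior"`.
#' @export
#' @examples
#' tef_prior(3.4, 0.51)  # bulk delta15N
#' tef_prior(7.6, 1.2)   # Glx-Phe
tef_prior <- function(mean, sd = 0) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1, length(sd) == 1)
  if (!(mean > 0)) stop("TEF mean must be > 0")
  if (sd < 0) stop("TEF sd must be >= 0")
  structure(list(mean = mean, sd = sd), class = "tef_prior")
}

#' beta prior (producer-level trophic-minus-source offset)
#'
#' Normal prior on beta, the delta15N difference between a trophic amino
#' acid and phenylalanine in marine phytoplankton, subtracted in the CSI-AA
#' trophic position formula. Literature values are point estimates (3.4
#' per-mil for Glx, 3.1 for Pro), so `sd` defaults to 0; any SD can be
#' supplied to propagate beta uncertainty as well.
#'
#' @param mean prior mean, per-mil.
#' @param sd prior SD (>= 0), per-mil.
#' @return object of class `"beta_prior"`.
#' @export
beta_prior <- function(mean, sd = 0) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1, length(sd) == 1)
  if (sd < 0) stop("beta sd must be >= 0")
  structure(list(mean = mean, sd = sd), class = "beta_prior")
}

#' Commonly used TEF priors
#'
#' @return named list of [tef_prior()] objects: `bulk` (3.4 +/- 0.51),
#'   `glx_phe` (7.6 +/- 1.2), `pro_phe` (4.5 +/- 0.9), `bulk_fish_temp`
#'   (5.2 +/- 0.68, a temperature-adjusted bulk TEF proposed for fishes) and
#'   `glx_phe_fish` (5.5, fixed, proposed for middle/upper-trophic fishes).
#' @export
tef_defaults <- function() {
  list(bulk = tef_prior(3.4, 0.51),
       glx_phe = tef_prior(7.6, 1.2),
       pro_phe = tef_prior(4.5, 0.9),
       bulk_fish_temp = tef_prior(5.2, 0.68),
       glx_phe_fish = tef_prior(5.5, 0))
}

#' Commonly used beta priors
#'
#' @return named list of [beta_prior()] objects: `glx_phe` (3.4) and
#'   `pro_phe` (3.1), the phytoplankton offsets for the two standard pairs.
#' @export
beta_defaults <- function() {
  list(glx_phe = beta_prior(3.4, 0), pro_phe = beta_prior(3.1, 0))
}

#' Specify one trophic-position estimation scenario
#'
#' @param method `"bulk"` (one-baseline model on bulk delta15N) or `"csia"`
#'   (trophic-minus-source amino-acid model; baseline trophic position is
#'   implicitly 1, the primary producers).
#' @param consumer species whose trophic position is estimated.
#' @param tef a [tef_prior()].
#' @param baseline baseline species name (bulk only), e.g. `"POM"`.
#' @param lambda trophic position assigned to the baseline organism
#'   (bulk only, >= 1; 1 for POM, 2 when a known herbivore prey is used).
#' @param pair `(trophic, source)` analyte pair (csia only).
#' @param beta a [beta_prior()] (csia only).
#' @param chains,iterations,warmup MCMC layout; defaults 4 chains of 2000
#'   iterations with the first 1000 discarded, i.e. 4000 retained draws.
#' @param seed integer seed; chain RNG states and TEF/beta draws are derived
#'   from it via [split_seed()].
#' @param label optional label for report tables (defaults to a
#'   method-derived one such as `"bulk"` or `"Glx-Phe"`).
#' @return object of class `"tp_model_spec"`.
#' @export
#' @examples
#' tp_model_spec("bulk", "Champsocephalus gunnari", tef_defaults()$bulk,
#'               baseline = "POM", lambda = 1, seed = 7)
#' tp_model_spec("csia", "Euphausia superba", tef_defaults()$glx_phe,
#'               pair = c("Glx", "Phe"), beta = beta_defaults()$glx_phe, seed = 7)
tp_model_spec <- function(method = c("bulk", "csia"), consumer, tef,
                          baseline = NULL, lambda = 1,
                          pair = NULL, beta = NULL,
                          chains = 4, iterations = 2000, warmup = 1000,
                          seed = 1, label = NULL) {
  method <- match.arg(method)
  stopifnot(is.character(consumer), length(consumer) == 1)
  if (!inherits(tef, "tef_prior")) stop("tef must be a tef_prior()")
  if (method == "bulk") {
    if (is.null(baseline)) stop("bulk method needs a baseline species")
    if (!(lambda >= 1)) stop("lambda must be >= 1")
  } else {
    if (is.null(pair) || length(pair) != 2)
      stop("csia method needs a (trophic, source) analyte pair")
    if (is.null(beta)) stop("csia method needs a beta_prior()")
    if (!inherits(beta, "beta_prior")) stop("beta must be a beta_prior()")
    lambda <- 1
  }
  if (!(warmup < iterations)) stop("warmup must be smaller than iterations")
  if (chains < 1) stop("need at least one chain")
  if (is.null(label))
    label <- if (method == "bulk") "bulk" else paste(pair, collapse = "-")
  structure(list(method = method, consumer = consumer, tef = tef,
                 baseline = baseline, lambda = lambda,
                 pair = pair, beta = beta,
                 mcmc = list(chains = as.integer(chains),
                             iterations = as.integer(iterations),
                             warmup = as.integer(warmup),
                             seed = as.integer(seed)),
                 label = label),
            class = "tp_model_spec")
}

#' Deterministic plug-in trophic position, bulk one-baseline formula
#'
#' `TP = lambda + (delta15N_consumer - delta15N_baseline) / TEF`. Serves as
#' the closed-form oracle the Bayesian posterior must concentrate on when
#' group means are well determined.
#'
#' @param mean_consumer,mean_baseline group mean delta15N, per-mil.
#' @param lambda trophic position of the baseline organism.
#' @param tef_mean TEF, per-mil (> 0).
#' @return trophic position (dimensionless).
#' @export
#' @examples
#' plugin_tp_bulk(8.5, -0.5, 1, 3.4)  # 3.647
plugin_tp_bulk <- function(mean_consumer, mean_baseline, lambda = 1, tef_mean = 3.4) {
  if (!(tef_mean > 0)) stop("tef_mean must be > 0")
  lambda + (mean_consumer - mean_baseline) / tef_mean
}

#' Deterministic plug-in trophic position, CSI-AA trophic-minus-source formula
#'
#' `TP = 1 + (delta15N_trophic - delta15N_source - beta) / TEF`, with beta
#' the producer-level offset for the pair.
#'
#' @param mean_trophic,mean_source group mean delta15N of the trophic and
#'   source amino acid, per-mil.
#' @param beta producer offset, per-mil.
#' @param tef_mean pair-specific TEF, per-mil (> 0).
#' @return trophic position (dimensionless).
#' @export
#' @examples
#' plugin_tp_csia(23.1, 1.3, 3.4, 7.6)  # 3.421
plugin_tp_csia <- function(mean_trophic, mean_source, beta = 3.4, tef_mean = 7.6) {
  if (!(tef_mean > 0)) stop("tef_mean must be > 0")
  1 + (mean_trophic - mean_source - beta) / tef_mean
}

#' @export
print.tp_model_spec <- function(x, ...) {
  cat("tp_model_spec [", x$label, "] for ", x$consumer, "\n", sep = "")
  if (x$method == "bulk")
    cat("  bulk one-baseline: baseline ", x$baseline, ", lambda ", x$lambda, "\n", sep = "")
  else
    cat("  csia pair: ", paste(x$pair, collapse = " - "),
        ", beta ", x$beta$mean, " +/- ", x$beta$sd, "\n", sep = "")
  cat("  TEF ~ Normal(", x$tef$mean, ", ", x$tef$sd, ") truncated > 0\n", sep = "")
  cat("  mcmc: ", x$mcmc$chains, " chains x ", x$mcmc$iterations, " (",
      x$mcmc$warmup, " warmup), seed ", x$mcmc$seed, "\n", sep = "")
  invisible(x)
}
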