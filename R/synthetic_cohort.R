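#' Specify a synthetic isotope cohort
#'
#' A cohort spec lists, per species x analyte, the Gaussian moments
#' (mean, SD in per-mil) and group size to emulate, plus the haul structure:
#' samples are assigned uniformly at random to `n_hauls` hauls, and a
#' fraction of each analyte's total SD is moved to a shared between-haul
#' effect so that within-haul correlation matches the survey design.
#' Variances partition exactly: between-haul sd = `haul_sd_fraction * sd`,
#' residual sd = `sqrt(1 - haul_sd_fraction^2) * sd`, so the marginal SD is
#' the specified total and the intra-class correlation is
#' `haul_sd_fraction^2`.
#'
#' @param moments data.frame with columns `species, analyte, mean, sd, n`.
#' @param kinds named character vector, species -> sample kind
#'   (`individual`/`pooled`/`pom`); species not named default to
#'   `"individual"` (`"pom"` for species `"POM"`).
#' @param n_hauls number of hauls (net deployments) to spread samples over.
#' @param haul_sd_fraction fraction of total SD assigned to the between-haul
#'   effect, in `[0, 1)`.
#' @param seed integer seed making [generate_cohort()] deterministic.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(moments, kinds = NULL, n_hauls = 10,
                        haul_sd_fraction = 0.3, seed = 1) {
  stopifnot(is.data.frame(moments),
            all(c("species", "analyte", "mean", "sd", "n") %in% names(moments)))
  if (!all(moments$analyte %in% ANALYTES))
    stop("unknown analyte(s) in moments: ",
         paste(setdiff(moments$analyte, ANALYTES), collapse = ", "))
  if (any(moments$sd < 0)) stop("sd must be >= 0")
  if (any(moments$n < 1)) stop("n must be >= 1")
  if (anyDuplicated(moments[, c("species", "analyte")]))
    stop("duplicated species x analyte rows in moments")
  if (!(n_hauls >= 1)) stop("n_hauls must be a positive integer")
  if (haul_sd_fraction < 0 || haul_sd_fraction >= 1)
    stop("haul_sd_fraction must lie in [0, 1)")
  structure(list(moments = as.data.frame(moments, stringsAsFactors = FALSE),
                 kinds = kinds,
                 n_hauls = as.integer(n_hauls),
                 haul_sd_fraction = haul_sd_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort spec emulating the South Orkney pelagic food-web survey
#'
#' Bundled per-species delta15N moments (bulk and 14 amino acids) for the
#' six-species pelagic assemblage around the mackerel icefish
#' (*Champsocephalus gunnari*), its main prey Antarctic krill
#' (*Euphausia superba*), secondary prey, and the POM baseline, with the
#' survey group sizes: 284 individual *C. gunnari*, 75 krill pools, 30
#' *Electrona antarctica*, 50 invertebrate pools split 17/17/16 across
#' *T. gaudichaudii*/*E. frigida*/*A. maxima*, 23 POM filters; CSI-AA subsets
#' of 10/10/3/3/3/3. POM carries bulk values only (no amino-acid delta15N).
#'
#' @param n_hauls,haul_sd_fraction,seed see [cohort_spec()]; defaults 10
#'   hauls and 0.3 (ICC 0.09), exercising the haul random effect while
#'   keeping the marginal SDs at their specified totals.
#' @return object of class `"cohort_spec"`.
#' @export
#' @examples
#' spec <- default_study_spec(seed = 1)
#' subset(spec$moments, analyte == "bulk")
default_study_spec <- function(n_hauls = 10, haul_sd_fraction = 0.3, seed = 1) {
  path <- system.file("extdata", "study_species_moments.csv", package = "isoTP",
                      mustWork = TRUE)
  moments <- utils::read.csv(path, stringsAsFactors = FALSE)
  kinds <- c("POM" = "pom",
             "Euphausia superba" = "pooled",
             "Themisto gaudichaudii" = "pooled",
             "Euphausia frigida" = "pooled",
             "Antarctomysis maxima" = "pooled",
             "Electrona antarctica" = "individual",
             "Champsocephalus gunnari" = "individual")
  cohort_spec(moments, kinds = kinds, n_hauls = n_hauls,
              haul_sd_fraction = haul_sd_fraction, seed = seed)
}

#' Generate a synthetic isotope cohort
#'
#' Draws one `isotope_samples` table from a [cohort_spec()]. For each
#' species, `max(n)` samples are created and assigned hauls uniformly at
#' random; analyte `a` (with group size `n_a`) is measured on the first
#' `n_a` samples, mirroring surveys where compound-specific analysis covers
#' a subset of the bulk samples. Each value is
#' `mean + haul effect + residual`, the haul effect being shared by all
#' samples of that species in the same haul (drawn independently per
#' analyte, SD `haul_sd_fraction * sd`), the residual independent with SD
#' `sqrt(1 - haul_sd_fraction^2) * sd`. Deterministic given `spec$seed`.
#'
#' @param spec a `cohort_spec`.
#' @return an `isotope_samples` data.frame.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_spec(seed = 1))
#' table(cohort$species)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  frac <- spec$haul_sd_fraction
  resid_scale <- sqrt(1 - frac^2)
  species_order <- unique(spec$moments$species)
  blocks <- list()
  for (si in seq_along(species_order)) {
    sp <- species_order[si]
    rows <- spec$moments[spec$moments$species == sp, , drop = FALSE]
    n_max <- max(rows$n)
    haul <- sample.int(spec$n_hauls, n_max, replace = TRUE)
    block <- data.frame(
      sample_id = sprintf("SP%02d-%04d", si, seq_len(n_max)),
      species = sp,
      haul_id = sprintf("H%02d", haul),
      stringsAsFactors = FALSE)
    kind <- (spec$kinds %||% character(0))[sp]
    if (is.na(kind) || is.null(kind)) kind <- if (sp == "POM") "pom" else "individual"
    block$sample_kind <- unname(kind)
    for (a in ANALYTES) block[[a]] <- rep(NA_real_, n_max)
    for (ri in seq_len(nrow(rows))) {
      a <- rows$analyte[ri]
      n_a <- rows$n[ri]
      haul_eff <- stats::rnorm(spec$n_hauls, 0, frac * rows$sd[ri])
      resid <- stats::rnorm(n_a, 0, resid_scale * rows$sd[ri])
      block[[a]][seq_len(n_a)] <- rows$mean[ri] + haul_eff[haul[seq_len(n_a)]] + resid
    }
    blocks[[si]] <- block
  }
  out <- do.call(rbind, blocks)
  keep_analytes <- ANALYTES[colSums(!is.na(out[, ANALYTES, drop = FALSE])) > 0]
  out <- out[, c("sample_id", "species", "haul_id", "sample_kind", keep_analytes)]
  isotope_samples(out)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec: ", length(unique(x$moments$species)), " species, ",
      nrow(x$moments), " species x analyte entries\n", sep = "")
  cat("n_hauls = ", x$n_hauls, ", haul_sd_fraction = ", x$haul_sd_fraction,
      " (ICC ", round(x$haul_sd_fraction^2, 3), "), seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
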