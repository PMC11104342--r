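#' @keywords internal
#' @importFrom stats rnorm runif quantile median sd var setNames update
#' @importFrom utils read.csv write.csv head packageVersion
"_PACKAGE"

# Canonical analyte set: bulk tissue delta15N plus the amino acids measured
# by GC-C-IRMS after acid hydrolysis (Glx = glutamic acid + glutamine pool).
ANALYTES <- c("bulk", "Ala", "Asp", "Glx", "Gly", "Ile", "Leu", "Pro", "Val",
              "Lys", "Met", "Phe", "Tyr", "Ser", "Thr")

SAMPLE_KINDS <- c("individual", "pooled", "pom")

DELTA15N_WINDOW <- c(-50, 50) # per-mil sanity window for validation

#' Canonical analyte names
#'
#' @return character vector: `"bulk"` followed by the 14 amino acids.
#' @export
analyte_names <- function() ANALYTES

#' Default amino-acid classification
#'
#' Classifies each analyte as `"trophic"` (delta15N enriches with each
#' trophic transfer: Ala, Asp, Glx, Gly, Ile, Leu, Pro, Val), `"source"`
#' (little trophic enrichment, preserving the baseline signal: Lys, Met,
#' Phe, Tyr), `"other"` (Ser, Thr) or `"bulk"`.
#'
#' @return named character vector mapping analyte name to class.
#' @export
#' @examples
#' aa_classification()[["Glx"]]  # "trophic"
#' aa_classification()[["Phe"]]  # "source"
aa_classification <- function() {
  c(bulk = "bulk",
    Ala = "trophic", Asp = "trophic", Glx = "trophic", Gly = "trophic",
    Ile = "trophic", Leu = "trophic", Pro = "trophic", Val = "trophic",
    Lys = "source", Met = "source", Phe = "source", Tyr = "source",
    Ser = "other", Thr = "other")
}

#' Construct an isotope sample table
#'
#' The central data container: one row per measured sample (an individual,
#' a pooled sample of 3-5 similarly sized individuals, or a particulate
#' organic matter filter), with columns `sample_id`, `species`, `haul_id`,
#' `sample_kind`, and one numeric column per analyte holding delta15N in
#' per-mil vs atmospheric N2. A missing measurement is `NA`, never zero;
#' downstream models use complete cases per analyte (pair).
#'
#' @param df data.frame with at least `species` and one analyte column.
#'   `sample_id`, `haul_id` and `sample_kind` are filled with defaults when
#'   absent (`sample_kind` defaults to `"pom"` for species `"POM"`, else
#'   `"individual"`).
#' @param validate check invariants (finite values inside the +/- 50 per-mil
#'   sanity window, at least one analyte present per row)?
#' @return a data.frame of class `"isotope_samples"`.
#' @export
isotope_samples <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("isotope samples need a 'species' column")
  present <- intersect(ANALYTES, names(df))
  if (length(present) == 0L)
    stop("no recognizable analyte column among: ", paste(ANALYTES, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- sprintf("S%04d", seq_len(nrow(df)))
  if (!"haul_id" %in% names(df)) df$haul_id <- "H01"
  if (!"sample_kind" %in% names(df))
    df$sample_kind <- ifelse(df$species == "POM", "pom", "individual")
  df <- df[, c("sample_id", "species", "haul_id", "sample_kind",
               intersect(ANALYTES, names(df)))]
  for (a in present) df[[a]] <- as.numeric(df[[a]])
  class(df) <- c("isotope_samples", "data.frame")
  if (validate) validate_samples(df)
  df
}

#' Validate an isotope sample table
#'
#' @param samples an `isotope_samples` data.frame.
#' @return `samples`, invisibly; stops with an informative message on the
#'   first violated invariant.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  present <- intersect(ANALYTES, names(samples))
  if (length(present) == 0L) stop("no analyte columns present")
  if (!all(samples$sample_kind %in% SAMPLE_KINDS))
    stop("sample_kind must be one of: ", paste(SAMPLE_KINDS, collapse = ", "))
  vals <- as.matrix(samples[, present, drop = FALSE])
  if (any(is.nan(vals) | is.infinite(vals)))
    stop("non-finite delta15N values present")
  bad <- which(!is.na(vals) & (vals < DELTA15N_WINDOW[1] | vals > DELTA15N_WINDOW[2]))
  if (length(bad))
    stop("delta15N values outside the [-50, 50] per-mil sanity window")
  if (any(rowSums(!is.na(vals)) == 0L))
    stop("every sample must carry at least one analyte value; rows with none: ",
         paste(utils::head(which(rowSums(!is.na(vals)) == 0L), 5), collapse = ", "))
  invisible(samples)
}

#' Read isotope samples from CSV
#'
#' Expects a header row; column matching is case-insensitive, with `haul`
#' accepted for `haul_id` and `kind` for `sample_kind`. Empty cells become
#' absent (`NA`) analytes. Rows with malformed (non-numeric, non-empty)
#' analyte cells are rejected with a warning naming the offending rows; a
#' file with no recognizable analyte column is a fatal format error.
#'
#' @param path CSV file path.
#' @return an `isotope_samples` data.frame.
#' @export
read_isotope_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", comment.char = "#")
  lower <- tolower(trimws(names(raw)))
  canon <- c(sample_id = "sample_id", id = "sample_id",
             species = "species",
             haul = "haul_id", haul_id = "haul_id", tow = "haul_id",
             sample_kind = "sample_kind", kind = "sample_kind")
  analyte_lookup <- stats::setNames(ANALYTES, tolower(ANALYTES))
  out_names <- names(raw)
  for (i in seq_along(lower)) {
    if (lower[i] %in% names(canon)) out_names[i] <- canon[[lower[i]]]
    else if (lower[i] %in% names(analyte_lookup)) out_names[i] <- analyte_lookup[[lower[i]]]
  }
  names(raw) <- out_names
  if (!"species" %in% names(raw)) stop("format error: no 'species' column in ", path)
  present <- intersect(ANALYTES, names(raw))
  if (length(present) == 0L)
    stop("format error: no recognizable analyte column in ", path)
  bad_rows <- integer(0)
  for (a in present) {
    x <- trimws(raw[[a]])
    x[x == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad_rows <- union(bad_rows, which(!is.na(x) & is.na(num)))
    raw[[a]] <- num
  }
  if (length(bad_rows)) {
    warning("rejecting ", length(bad_rows), " row(s) with malformed numeric cells: rows ",
            paste(sort(bad_rows), collapse = ", "))
    raw <- raw[-sort(bad_rows), , drop = FALSE]
  }
  isotope_samples(raw)
}

#' Write isotope samples to CSV
#'
#' Canonical header (`sample_id, species, haul_id, sample_kind`, then the
#' analyte columns present); absent analytes are written as empty cells.
#' `read_isotope_samples()` round-trips the output exactly to printed
#' precision.
#'
#' @param samples an `isotope_samples` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_samples <- function(samples, path) {
  validate_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-species, per-analyte summary (mean, SD, n)
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' species x analyte group over the samples where that analyte was measured.
#' Groups with a single observation report `sd = 0` and are flagged in the
#' `single_obs` column. Permutation-invariant over input order.
#'
#' @param samples an `isotope_samples` data.frame.
#' @return data.frame with columns `species, analyte, mean, sd, n, single_obs`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_spec(seed = 1))
#' head(summarize_species(cohort))
summarize_species <- function(samples) {
  validate_samples(samples)
  if (nrow(samples) == 0L) stop("need at least one sample")
  present <- intersect(ANALYTES, names(samples))
  out <- list()
  for (sp in unique(samples$species)) {
    sub <- samples[samples$species == sp, , drop = FALSE]
    for (a in present) {
      v <- sub[[a]][!is.na(sub[[a]])]
      n <- length(v)
      if (n == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        species = sp, analyte = a,
        mean = mean(v),
        sd = if (n == 1L) 0 else stats::sd(v),
        n = n,
        single_obs = n == 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Within-sample trophic-minus-source delta15N differences
#'
#' Computes `delta = delta15N[pair1] - delta15N[pair2]` per sample, e.g. the
#' Glx-Phe or Pro-Phe difference that feeds the CSI-AA trophic position
#' model. The first analyte must be classified trophic and the second source
#' under `classification`, unless `allow_any = TRUE` (exploratory pairs).
#' Samples lacking either analyte are skipped; the skip count is attached as
#' attribute `n_skipped`.
#'
#' @param samples an `isotope_samples` data.frame.
#' @param pair length-2 character vector `(trophic, source)`.
#' @param classification named vector as from [aa_classification()].
#' @param allow_any bypass the trophic/source check.
#' @return data.frame `sample_id, species, haul_id, trophic, source, delta`
#'   with attribute `n_skipped`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_spec(seed = 1))
#' d <- compute_deltas(cohort, c("Glx", "Phe"))
#' mean(d$delta[d$species == "Euphausia superba"])
compute_deltas <- function(samples, pair = c("Glx", "Phe"),
                           classification = aa_classification(),
                           allow_any = FALSE) {
  validate_samples(samples)
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% ANALYTES)) stop("unknown analyte(s): ", paste(pair, collapse = ", "))
  if (!allow_any) {
    cl1 <- classification[[pair[1]]] %||% "unknown"
    cl2 <- classification[[pair[2]]] %||% "unknown"
    if (cl1 != "trophic" || cl2 != "source")
      stop("pair (", pair[1], ", ", pair[2], ") is not (trophic, source) under the ",
           "active classification (", cl1, ", ", cl2, "); use allow_any = TRUE ",
           "for exploratory pairs")
  }
  for (a in pair) if (!a %in% names(samples))
    samples[[a]] <- rep(NA_real_, nrow(samples))
  keep <- !is.na(samples[[pair[1]]]) & !is.na(samples[[pair[2]]])
  out <- data.frame(sample_id = samples$sample_id[keep],
                    species = samples$species[keep],
                    haul_id = samples$haul_id[keep],
                    trophic = pair[1], source = pair[2],
                    delta = samples[[pair[1]]][keep] - samples[[pair[2]]][keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' @export
print.isotope_samples <- function(x, ...) {
  present <- intersect(ANALYTES, names(x))
  cat("isotope_samples: ", nrow(x), " samples, ",
      length(unique(x$species)), " species, ",
      length(unique(x$haul_id)), " hauls\n", sep = "")
  cat("analytes: ", paste(present, collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
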