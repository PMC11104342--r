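RUN_CONFIG_KEYS <- c("version", "seed", "data", "simulate", "models",
                     "comparisons", "outdir", "verbose")
MODEL_KEYS <- c("method", "consumer", "label", "tef", "baseline", "lambda",
                "pair", "beta", "chains", "iterations", "warmup")
COMPARISON_KEYS <- c("a", "b", "expected_dtp")

#' Build a run configuration
#'
#' A run configuration drives one reproducible end-to-end analysis: one data
#' source (a CSV file *or* a simulation spec, never both), a list of
#' estimation scenarios, optional posterior comparisons, an output
#' directory, and a mandatory seed from which every stochastic stage derives
#' its own sub-seed.
#'
#' @param models named list of [tp_model_spec()] objects; names become the
#'   scenario labels used by `comparisons`.
#' @param outdir output directory (created on demand).
#' @param seed integer master seed.
#' @param data path to an isotope CSV (exclusive with `simulate`).
#' @param simulate a [cohort_spec()] (exclusive with `data`); its seed is
#'   re-derived from `seed` so the whole run is governed by one seed.
#' @param comparisons list of `list(a = <label>, b = <label>,
#'   expected_dtp = <number or NULL>)`; entries with `expected_dtp` produce
#'   accuracy rows, the rest plain difference probabilities.
#' @param verbose echo log lines to the console?
#' @return object of class `"run_config"`.
#' @export
run_config <- function(models, outdir, seed, data = NULL, simulate = NULL,
                       comparisons = list(), verbose = FALSE) {
  if (is.null(data) == is.null(simulate))
    stop("exactly one data source: give either 'data' (CSV path) or 'simulate' (cohort_spec)")
  if (!is.null(simulate) && !inherits(simulate, "cohort_spec"))
    stop("'simulate' must be a cohort_spec")
  stopifnot(is.list(models), length(models) >= 1)
  for (m in models) if (!inherits(m, "tp_model_spec"))
    stop("every element of 'models' must be a tp_model_spec")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, function(s) paste(s$consumer, s$label), character(1))
  if (anyDuplicated(names(models))) stop("duplicated scenario labels in 'models'")
  for (cmp in comparisons) {
    if (!all(names(cmp) %in% COMPARISON_KEYS))
      stop("unknown comparison keys: ",
           paste(setdiff(names(cmp), COMPARISON_KEYS), collapse = ", "))
    if (!all(c(cmp$a, cmp$b) %in% names(models)))
      stop("comparison refers to unknown scenario label(s): ", cmp$a, ", ", cmp$b)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), data = data, simulate = simulate,
                 models = models, comparisons = comparisons,
                 outdir = outdir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Strict, versioned schema (`version: 1`); unknown keys at any level are
#' errors rather than warnings, so a misspelt field cannot silently corrupt
#' a scenario comparison. See the packaged example in
#' `system.file("extdata", "example_config.yaml", package = "isoTP")`.
#'
#' @param path YAML file path.
#' @return object of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), RUN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(y$version) || y$version != 1) stop("config 'version' must be 1")
  if (is.null(y$seed)) stop("config needs a 'seed'")
  simulate <- NULL
  if (!is.null(y$simulate)) {
    sim_keys <- setdiff(names(y$simulate), c("n_hauls", "haul_sd_fraction"))
    if (length(sim_keys)) stop("unknown simulate key(s): ", paste(sim_keys, collapse = ", "))
    simulate <- default_study_spec(
      n_hauls = y$simulate$n_hauls %||% 10,
      haul_sd_fraction = y$simulate$haul_sd_fraction %||% 0.3,
      seed = 1)
  }
  models <- lapply(y$models, function(m) {
    unknown <- setdiff(names(m), MODEL_KEYS)
    if (length(unknown)) stop("unknown model key(s): ", paste(unknown, collapse = ", "))
    tp_model_spec(method = m$method, consumer = m$consumer,
                  tef = tef_prior(m$tef$mean, m$tef$sd %||% 0),
                  baseline = m$baseline, lambda = m$lambda %||% 1,
                  pair = unlist(m$pair),
                  beta = if (!is.null(m$beta)) beta_prior(m$beta$mean, m$beta$sd %||% 0),
                  chains = m$chains %||% 4, iterations = m$iterations %||% 2000,
                  warmup = m$warmup %||% 1000, seed = y$seed, label = m$label)
  })
  names(models) <- vapply(y$models, function(m)
    m$label %||% paste(m$consumer, m$method), character(1))
  run_config(models = models, outdir = y$outdir %||% ".", seed = y$seed,
             data = y$data, simulate = simulate,
             comparisons = y$comparisons %||% list(),
             verbose = isTRUE(y$verbose))
}

#' Default full-study run configuration
#'
#' All three estimation methods (bulk vs POM baseline, Glx-Phe, Pro-Phe with
#' their standard TEF/beta priors) for the six consumer species of the
#' default synthetic cohort, plus the predator-vs-main-prey accuracy
#' comparisons for each method (expected delta-TP of 1).
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return object of class `"run_config"`.
#' @export
default_run_config <- function(outdir, seed = 1) {
  consumers <- c("Euphausia superba", "Themisto gaudichaudii", "Euphausia frigida",
                 "Antarctomysis maxima", "Electrona antarctica",
                 "Champsocephalus gunnari")
  tefs <- tef_defaults(); betas <- beta_defaults()
  models <- list()
  for (sp in consumers) {
    models[[paste(sp, "bulk")]] <-
      tp_model_spec("bulk", sp, tefs$bulk, baseline = "POM", lambda = 1, seed = seed)
    models[[paste(sp, "Glx-Phe")]] <-
      tp_model_spec("csia", sp, tefs$glx_phe, pair = c("Glx", "Phe"),
                    beta = betas$glx_phe, seed = seed)
    models[[paste(sp, "Pro-Phe")]] <-
      tp_model_spec("csia", sp, tefs$pro_phe, pair = c("Pro", "Phe"),
                    beta = betas$pro_phe, seed = seed)
  }
  comparisons <- lapply(c("bulk", "Glx-Phe", "Pro-Phe"), function(meth)
    list(a = paste("Champsocephalus gunnari", meth),
         b = paste("Euphausia superba", meth),
         expected_dtp = 1))
  run_config(models = models, outdir = outdir, seed = seed,
             simulate = default_study_spec(seed = seed),
             comparisons = comparisons)
}

write_csv_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run a full, reproducible trophic-position analysis
#'
#' Executes the configured pipeline end to end: load or simulate the cohort,
#' write the species x analyte summary, fit every scenario, write full-
#' precision estimates plus a 1-decimal display table, run the requested
#' posterior comparisons, and keep a plain-text log. Every output carries a
#' metadata header (package version, master seed, data source), and rerunning
#' the same configuration reproduces the numbers exactly.
#'
#' Scenario failures are isolated (an `NA` row with the error message in
#' `note`, logged with the stage name); a missing input file aborts before
#' any output is written.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `samples`, `estimates`, `comparisons`, and
#'   the output `paths`.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$data) && !file.exists(config$data))
    stop("input data file not found: ", config$data)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    writeLines(line, log_con)
    if (config$verbose) message(line)
  }
  meta <- c(paste0("isoTP ", as.character(utils::packageVersion("isoTP"))),
            paste0("seed: ", config$seed),
            paste0("data: ", if (is.null(config$data)) "simulated cohort" else config$data))
  log_line("config", paste0("seed ", config$seed, ", ", length(config$models),
                            " scenario(s), ", length(config$comparisons),
                            " comparison(s)"))

  if (is.null(config$data)) {
    sim <- config$simulate
    sim$seed <- split_seed(config$seed, "cohort")
    samples <- generate_cohort(sim)
    log_line("data", paste0("simulated ", nrow(samples), " samples (cohort seed ",
                            sim$seed, ")"))
  } else {
    samples <- read_isotope_samples(config$data)
    log_line("data", paste0("read ", nrow(samples), " samples from ", config$data))
  }

  summary_df <- summarize_species(samples)
  summary_path <- file.path(config$outdir, "summary.csv")
  write_csv_with_meta(summary_df, summary_path, meta)
  log_line("summary", paste0(nrow(summary_df), " species x analyte rows -> ", summary_path))

  fits <- list()
  est_rows <- vector("list", length(config$models))
  for (i in seq_along(config$models)) {
    lab <- names(config$models)[i]
    sc <- config$models[[i]]
    sc$mcmc$seed <- split_seed(config$seed, lab)
    est_rows[[i]] <- tryCatch({
      fit <- fit_tp(samples, sc)
      fits[[lab]] <- fit
      est <- suppressWarnings(summarize_posterior(fit))
      log_line("estimate", sprintf("%s: median %.3f (%.3f-%.3f)%s", lab,
                                   est$median, est$ci_low, est$ci_high,
                                   if (nzchar(est$note)) paste0(" [", est$note, "]") else ""))
      cbind(data.frame(scenario = lab, stringsAsFactors = FALSE), as.data.frame(est))
    }, error = function(e) {
      log_line("estimate", paste0("FAILED ", lab, ": ", conditionMessage(e)))
      data.frame(scenario = lab, species = sc$consumer, method = sc$label,
                 median = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 rhat_max = NA_real_, ess_min = NA_real_, converged = FALSE,
                 note = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL
  est_path <- file.path(config$outdir, "estimates.csv")
  write_csv_with_meta(estimates, est_path,
                      c(meta, if (any(!estimates$converged))
                        "WARNING: partial results, see 'note' column"))
  display <- data.frame(species = estimates$species, method = estimates$method,
                        median = round(estimates$median, 1),
                        ci_low = round(estimates$ci_low, 1),
                        ci_high = round(estimates$ci_high, 1))
  write_csv_with_meta(display, file.path(config$outdir, "tp_table.csv"), meta)
  log_line("estimates", paste0(nrow(estimates), " rows -> ", est_path))

  comparisons <- list()
  for (cmp in config$comparisons) {
    key <- paste0(cmp$a, " vs ", cmp$b)
    comparisons[[key]] <- tryCatch({
      if (is.null(fits[[cmp$a]]) || is.null(fits[[cmp$b]]))
        stop("one of the fits failed or is missing")
      res <- compare_draws(fits[[cmp$a]], fits[[cmp$b]], subsample = TRUE,
                           seed = config$seed)
      out <- list(label_a = res$label_a, label_b = res$label_b,
                  p_a_ge_b = res$p_a_ge_b, diff_median = res$diff_median,
                  diff_ci95 = c(res$diff_ci_low, res$diff_ci_high))
      if (!is.null(cmp$expected_dtp)) {
        acc <- diet_accuracy(fits[[cmp$a]], fits[[cmp$b]],
                             expected_dtp = cmp$expected_dtp,
                             subsample = TRUE, seed = config$seed)
        out$expected_dtp <- acc$expected_dtp
        out$bias_median <- acc$bias_median
        out$bias_ci95 <- c(acc$bias_ci_low, acc$bias_ci_high)
      }
      log_line("compare", sprintf("%s: p = %.3f, diff median %.3f", key,
                                  out$p_a_ge_b, out$diff_median))
      out
    }, error = function(e) {
      log_line("compare", paste0("FAILED ", key, ": ", conditionMessage(e)))
      list(error = conditionMessage(e))
    })
  }
  cmp_path <- file.path(config$outdir, "comparisons.json")
  jsonlite::write_json(list(meta = as.list(meta), comparisons = comparisons),
                       cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done", paste0("outputs in ", config$outdir))
  invisible(list(samples = samples, estimates = estimates,
                 comparisons = comparisons,
                 paths = list(summary = summary_path, estimates = est_path,
                              comparisons = cmp_path, log = log_path)))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: seed ", x$seed, ", ", length(x$models), " scenario(s), ",
      length(x$comparisons), " comparison(s)\n", sep = "")
  cat("data source: ", if (is.null(x$data)) "simulated cohort" else x$data,
      "; outdir: ", x$outdir, "\n", sep = "")
  invisible(x)
}
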