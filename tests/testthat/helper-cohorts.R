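# Shared fixtures, built in code at test time.

# Small two-species cohort spec (consumer + POM-like baseline) with known
# moments; used where the full study cohort would be overkill.
toy_spec <- function(seed = 1, n_hauls = 6, frac = 0.3,
                     n_cons = 40, n_base = 25) {
  moments <- data.frame(
    species = c("consumer", "consumer", "consumer", "base"),
    analyte = c("bulk", "Glx", "Phe", "bulk"),
    mean = c(8.5, 23.1, 1.3, -0.5),
    sd = c(0.6, 0.8, 0.8, 1.2),
    n = c(n_cons, n_cons, n_cons, n_base))
  cohort_spec(moments, kinds = c(base = "pom"), n_hauls = n_hauls,
              haul_sd_fraction = frac, seed = seed)
}

# Large balanced cohort at the study's Table-1-style moments, for
# oracle-equivalence checks where group means must concentrate.
big_study_spec <- function(seed = 1, n = 400) {
  spec <- default_study_spec(n_hauls = 20, seed = seed)
  spec$moments$n <- n
  spec
}

quick_mcmc <- list(chains = 2, iterations = 800, warmup = 400)

quick_bulk_spec <- function(consumer, baseline = "POM", lambda = 1,
                            tef = tef_defaults()$bulk, seed = 1) {
  tp_model_spec("bulk", consumer, tef, baseline = baseline, lambda = lambda,
                chains = quick_mcmc$chains, iterations = quick_mcmc$iterations,
                warmup = quick_mcmc$warmup, seed = seed)
}

quick_csia_spec <- function(consumer, pair = c("Glx", "Phe"),
                            tef = tef_defaults()$glx_phe,
                            beta = beta_defaults()$glx_phe, seed = 1) {
  tp_model_spec("csia", consumer, tef, pair = pair, beta = beta,
                chains = quick_mcmc$chains, iterations = quick_mcmc$iterations,
                warmup = quick_mcmc$warmup, seed = seed)
}
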