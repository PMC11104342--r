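# isoTP

Bayesian estimation of trophic position (TP) from nitrogen stable isotopes,
for food-web ecologists comparing bulk-tissue and compound-specific
amino-acid (CSI-AA) approaches.

Knowing where a consumer sits in a food web is central to understanding its
ecosystem role, but TP estimates depend heavily on the analytical route and
on uncertain biochemical constants. isoTP implements both standard routes in
one hierarchical Bayesian framework:

- **Bulk one-baseline model**

  TP_bulk = λ + (δ¹⁵N_consumer − δ¹⁵N_baseline) / TEF_bulk

  where λ is the trophic position of the baseline organism (e.g. 1 for
  particulate organic matter, POM) and TEF is the per-trophic-step
  enrichment of δ¹⁵N (commonly 3.4 ‰ ± 0.51).

- **CSI-AA trophic-minus-source model**

  TP_Trc−Phe = 1 + (δ¹⁵N_Trc − δ¹⁵N_Phe − β_Trc−Phe) / TEF_Trc−Phe

  using the within-sample difference between a "trophic" amino acid (Glx,
  Pro, ...) that enriches with each transfer and the "source" amino acid
  phenylalanine that preserves the baseline signal; β is the offset between
  the two in marine phytoplankton (3.4 ‰ for Glx, 3.1 ‰ for Pro), with
  pair-specific TEFs (Glx−Phe: 7.6 ‰ ± 1.2; Pro−Phe: 4.5 ‰ ± 0.9).

Group means are estimated by a Gaussian multilevel model with haul (net
deployment) random effects, and TEF/β uncertainty is propagated by drawing
those constants per retained MCMC iteration, so credible intervals reflect
all three sources of variation: sampling noise, haul structure, and
enrichment-factor uncertainty. Posteriors from different methods or species
can be compared via difference probabilities, and a known-diet accuracy
check tests the predator-minus-prey difference against the ΔTP = 1 expected
for a monospecific diet. A synthetic cohort generator reproduces the
sampling structure of a pelagic survey (species-level Gaussian analyte
distributions, between-haul variance, realistic group sizes), so the whole
pipeline runs and is tested entirely offline.

MCMC is performed with JAGS via `rjags`.

## Worked example

```r
library(isoTP)

# synthetic cohort emulating a Southern Ocean pelagic survey:
# an icefish predator, krill and other prey, and a POM baseline
cohort <- generate_cohort(default_study_spec(seed = 1))
cohort
#> isotope_samples: 462 samples, 7 species, 10 hauls
#> analytes: bulk, Ala, Asp, Glx, Gly, Ile, Leu, Pro, Val, Lys, Met, Phe, Tyr, Ser, Thr

# CSI-AA (Glx-Phe) trophic position of the icefish predator
glx <- tp_model_spec("csia", "Champsocephalus gunnari", tef_defaults()$glx_phe,
                     pair = c("Glx", "Phe"), beta = beta_defaults()$glx_phe,
                     seed = 1)
fit_fish <- fit_tp(cohort, glx)
summarize_posterior(fit_fish)
#> Champsocephalus gunnari [Glx-Phe]: TP = 3.4 (95% CI 2.8-4.6)

# bulk route, POM baseline at lambda = 1
bulk <- tp_model_spec("bulk", "Champsocephalus gunnari", tef_defaults()$bulk,
                      baseline = "POM", lambda = 1, seed = 1)
summarize_posterior(fit_tp(cohort, bulk))
#> Champsocephalus gunnari [bulk]: TP = 3.6 (95% CI 3.0-4.7)

# known-diet accuracy: the predator eats krill almost exclusively,
# so the TP difference should be ~1
krill <- tp_model_spec("csia", "Euphausia superba", tef_defaults()$glx_phe,
                       pair = c("Glx", "Phe"), beta = beta_defaults()$glx_phe,
                       seed = 1)
fit_krill <- fit_tp(cohort, krill)
diet_accuracy(fit_fish, fit_krill, expected_dtp = 1)
#> dTP(Champsocephalus gunnari Glx-Phe - Euphausia superba Glx-Phe) = 1.25;
#>   bias vs expected 1.0: 0.25 (95% CI -0.19 to 0.97)
```

The predator sits between TP 3.4 and 3.6 depending on the route; the bulk
interval is wider because the POM baseline is more variable than the
internal amino-acid baseline. The predator-minus-prey difference is
compatible with the expected single trophic step (the 95% interval of the
bias covers 0); the point bias here reflects the sampling noise of a cohort
with only ten CSI-AA samples per species.

Full study-shaped runs (6 species × 3 methods, summary tables, comparison
JSON, log) are driven by `run_report(default_run_config(outdir, seed))` or a
YAML configuration (see
`system.file("extdata", "example_config.yaml", package = "isoTP")`).

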