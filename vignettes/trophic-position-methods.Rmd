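---
title: "Models and design choices in isoTP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in isoTP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

isoTP estimates the trophic position (TP) of consumers from nitrogen stable
isotope data, by either of the two standard analytical routes, inside one
Bayesian hierarchical framework. This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology is genuinely open.

## The two estimation routes

**Bulk one-baseline.** With a baseline organism of known trophic position
$\lambda$ (POM at $\lambda = 1$ for a pelagic web, or a known herbivorous
prey at $\lambda = 2$),

$$TP_{bulk} = \lambda + \frac{\delta^{15}N_{consumer} -
\delta^{15}N_{baseline}}{TEF_{bulk}},$$

where the trophic enrichment factor (TEF, per-mil) is the average
per-trophic-step increase in bulk-tissue $\delta^{15}N$. Its default prior,
Normal(3.4, 0.51), is the widely used meta-analytic value; a
temperature-adjusted alternative for fishes, Normal(5.2, 0.68), and other
choices are available through `tef_defaults()` or any `tef_prior()`.

**CSI-AA trophic-minus-source.** Compound-specific analysis contrasts a
"trophic" amino acid (Glx, Pro, Ala, ...) whose $\delta^{15}N$ enriches with
each transfer against the "source" amino acid phenylalanine, which tracks
the base of the web:

$$TP_{Trc-Phe} = 1 + \frac{\delta^{15}N_{Trc} - \delta^{15}N_{Phe} -
\beta_{Trc-Phe}}{TEF_{Trc-Phe}},$$

with $\beta$ the producer-level offset between the pair (3.4 per-mil for
Glx, 3.1 for Pro in marine phytoplankton) and pair-specific TEFs (defaults
Normal(7.6, 1.2) for Glx−Phe and Normal(4.5, 0.9) for Pro−Phe). The
response entering the model is the *within-sample* difference
$\delta^{15}N_{Trc} - \delta^{15}N_{Phe}$: the two measurements come from
the same chromatogram and are correlated, and their difference is exactly
the quantity the formula needs, so collapsing them into one Gaussian
response avoids modelling that correlation.

## The hierarchical model

Samples from the same haul (net deployment) are correlated, so for each
group (consumer response, and for the bulk route also the baseline) we fit

$$y_{ij} \sim \mathcal{N}(\mu + u_j,\ \sigma), \qquad
u_j \sim \mathcal{N}(0,\ \sigma_h),$$

with flat (precision $10^{-6}$) priors on group means and half-Normal(0, 5
per-mil) priors on $\sigma$ and $\sigma_h$ — weakly informative relative to
the 0.2–2.7 per-mil spread of real $\delta^{15}N$ groups. For the bulk route
the consumer and baseline groups are fitted jointly, each with its own mean,
residual SD and haul effects, so baseline uncertainty propagates into TP
instead of being plugged in as a fixed summary.

TEF and $\beta$ are not informed by the data; they are *propagated*: per
retained MCMC draw one TEF value is drawn from its prior truncated at zero
(preventing sign flips in the denominator) and, for CSI-AA, one $\beta$
value from its (untruncated) Normal prior, and the TP draw is computed from
the defining formula. The stored draws always satisfy that algebra exactly,
which the tests verify at machine precision. $\beta$ defaults to a point
value (sd 0) because the literature reports point estimates; any sd can be
supplied.

Sampling uses JAGS (4 chains × 2000 iterations, first 1000 discarded as
adaptation + burn-in, i.e. 4000 retained draws, overridable). Haul effects
are parameterised non-centred ($u_j = \sigma_h z_j$, $z_j \sim
\mathcal{N}(0,1)$): with few hauls the centred form mixes an order of
magnitude worse. Convergence is monitored by split-$\hat R$ (threshold
1.05) and effective sample size (threshold 400) on every structural
parameter; a violating fit is *flagged* in the returned estimate (and a
warning raised), never silently discarded or truncated. Estimates are the
posterior median with an equal-tailed 95% credible interval (2.5%/97.5%
quantiles) — equal-tailed rather than HPD because it is the common default
and reproducible without density estimation. TP draws below 1 or above 6
are retained; only the reported median is sanity-flagged.

All randomness flows from one user seed through a documented splitting rule
(`split_seed()`: a string-keyed hash offset), so chains, TEF/β streams,
scenario batches and subsampling are reproducible and order-independent.
Because the TEF stream uses inverse-CDF draws on a shared uniform stream,
re-propagating the same fit under a wider TEF prior (`propagate_tef()`)
is coupled draw-for-draw; credible intervals can only widen, a property the
test suite checks.

## The synthetic cohort generator

`default_study_spec()` encodes the species × analyte means, SDs and group
sizes of a Southern Ocean pelagic assemblage: the icefish predator
*Champsocephalus gunnari* (284 bulk samples, 10 CSI-AA), its main prey
*Euphausia superba* (75 pooled samples, 10 CSI-AA), *Electrona antarctica*
(30), three invertebrate prey taxa (50 pooled samples in total), a POM
baseline (23, bulk only), and 14 amino acids per species. Where the survey
design leaves details open the generator makes explicit choices:

- the 50 invertebrate pools are split 17/17/16 across *T. gaudichaudii*,
  *E. frigida* and *A. maxima* (an even split; only the total is known);
- the number of hauls is a free parameter (default 10, a realistic survey
  size that leaves several samples per haul for the abundant species);
- `haul_sd_fraction` (default 0.3) routes that fraction of each analyte's
  total SD into a shared between-haul effect, giving an intra-class
  correlation of 0.09 while keeping the marginal SD at its specified total
  (between² + within² = total²);
- CSI-AA analytes are measured on the first $n_{CSIA}$ samples of each
  species, mirroring surveys where compound-specific analysis covers a
  subset of the bulk samples;
- pooled samples are treated as single observations (the survey's unit of
  analysis), with no pseudo-replication correction.

What the generator does *not* emulate: cross-amino-acid correlation within
a sample (only univariate moments are available, so analytes are drawn
independently), size-class structure, sex effects, and measurement-replicate
noise of the GC-C-IRMS procedure. Passing tests therefore demonstrate
correct inference *under the stated Gaussian hierarchical structure*, not
robustness to those unmodelled features of real data.

## Numerical and testing choices

- Missing analytes are absent (`NA`), never imputed or zero-filled; models
  use complete cases per analyte (pair).
- $\delta^{15}N$ values are validated against a [−50, 50] per-mil sanity
  window — a data-entry guard, not a physical law.
- Species are fitted independently, one model per species × method; a joint
  multivariate fit across species is out of scope.
- Draws from independently fitted posteriors are compared by index pairing,
  the Monte-Carlo estimator of $P(A \ge B)$ for independent posteriors;
  ties count toward $\ge$.
- The test suite runs the full 4 × 2000/1000 layout for the study-scale
  checks and reduced layouts (2 × 800/400) for structural and
  parameter-recovery checks; the recovery study uses 50 replicate cohorts
  of 40 samples over 8 hauls. Oracle-equivalence checks use enlarged
  balanced cohorts (n = 400 per group, 20 hauls) so that group-mean
  posteriors concentrate on the generating means and the posterior median
  can be compared against the closed-form plug-in TP.

## Known limitations

- The Pro−Phe route is exposed with the standard parameterisation
  ($\beta$ = 3.1, TEF = 4.5 ± 0.9), but published TP tables based on it are
  not mutually consistent with those constants (back-solving implies a
  substantially larger TEF); both parameters are user-settable, and the
  package treats Pro−Phe outputs as exploratory.
- With typical CSI-AA group sizes (3–10 samples) the posterior median
  inherits a cohort-sampling SE of order 0.1 TP; single-cohort comparisons
  at that precision are noise-limited, which is visible in the test suite.
- TEF uncertainty dominates the credible intervals for high-TP consumers;
  the intervals are honest about this rather than narrow.
- Alternative pairs (Ala−Phe, Ile−Phe) are supported mechanically via
  user-supplied `tef_prior()`/`beta_prior()` values, but no defaults are
  shipped because no standard constants are established.
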