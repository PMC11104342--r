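test_that("plug-in formulas reproduce closed-form trophic positions", {
  # bulk one-baseline arithmetic at the study group means
  expect_equal(plugin_tp_bulk(8.5, -0.5, 1, 3.4), 1 + 9 / 3.4)
  expect_equal(round(plugin_tp_bulk(8.5, -0.5, 1, 3.4), 1), 3.6)
  expect_equal(round(plugin_tp_bulk(3.5, -0.5, 1, 3.4), 1), 2.2)
  # zero-difference identity: consumer == baseline -> lambda
  expect_equal(plugin_tp_bulk(4.2, 4.2, 2.5, 1.7), 2.5)
  # CSI-AA arithmetic
  expect_equal(plugin_tp_csia(23.1, 1.3, 3.4, 7.6), 1 + 18.4 / 7.6)
  expect_equal(round(plugin_tp_csia(23.1, 1.3, 3.4, 7.6), 1), 3.4)
  expect_equal(round(plugin_tp_csia(14.9, 1.7, 3.4, 7.6), 1), 2.3)
  # base-of-food-web identity
  expect_equal(plugin_tp_csia(1.7 + 3.4, 1.7, 3.4, 7.6), 1)
  expect_error(plugin_tp_bulk(8.5, -0.5, 1, 0), "tef_mean")
  expect_error(plugin_tp_csia(23.1, 1.3, 3.4, -1), "tef_mean")
})

test_that("model spec construction enforces its contract", {
  tef <- tef_defaults()$bulk
  expect_error(tp_model_spec("bulk", "x", tef), "baseline")
  expect_error(tp_model_spec("bulk", "x", tef, baseline = "POM", lambda = 0.5),
               "lambda")
  expect_error(tp_model_spec("csia", "x", tef, pair = c("Glx", "Phe")), "beta")
  expect_error(tp_model_spec("bulk", "x", tef, baseline = "POM",
                             iterations = 100, warmup = 100), "warmup")
  expect_error(tef_prior(-1, 0.5), "mean")
  expect_error(tef_prior(3.4, -0.1), "sd")
  spec <- tp_model_spec("bulk", "x", tef, baseline = "POM")
  expect_equal(spec$mcmc$chains, 4L)
  expect_equal(spec$mcmc$iterations, 2000L)
  expect_equal(spec$mcmc$warmup, 1000L)
})

test_that("fits are deterministic under a fixed seed and carry the right draw count", {
  cohort <- generate_cohort(toy_spec(seed = 2))
  spec <- quick_bulk_spec("consumer", baseline = "base", seed = 42)
  f1 <- fit_tp(cohort, spec)
  f2 <- fit_tp(cohort, spec)
  expect_identical(f1$tp, f2$tp)
  expect_equal(dim(f1$tp), c(400L, 2L))  # chains x (iterations - warmup)
  spec2 <- quick_bulk_spec("consumer", baseline = "base", seed = 43)
  f3 <- fit_tp(cohort, spec2)
  expect_false(identical(f1$tp, f3$tp))
})

test_that("TP draws satisfy the defining algebra from stored per-draw parameters", {
  cohort <- generate_cohort(toy_spec(seed = 2))
  fb <- fit_tp(cohort, quick_bulk_spec("consumer", baseline = "base", seed = 1))
  expect_equal(fb$tp, fb$spec$lambda + (fb$params$mu_c - fb$params$mu_b) / fb$params$tef,
               tolerance = 1e-12)
  expect_true(all(fb$params$tef > 0))
  fc <- fit_tp(cohort, quick_csia_spec("consumer", seed = 1))
  expect_equal(fc$tp, 1 + (fc$params$mu_delta - fc$params$beta) / fc$params$tef,
               tolerance = 1e-12)
})

test_that("posterior medians agree with the plug-in oracle on large balanced data", {
  # group-mean posteriors concentrate on the generating means, so the TP
  # posterior median must land on the closed-form plug-in value
  spec <- big_study_spec(seed = 3, n = 400)
  cohort <- generate_cohort(spec)
  m <- spec$moments
  mu <- function(sp, a) m$mean[m$species == sp & m$analyte == a]
  consumers <- setdiff(unique(m$species), "POM")
  for (sp in consumers) {
    est_b <- suppressWarnings(summarize_posterior(fit_tp(cohort, quick_bulk_spec(sp, seed = 5))))
    expect_lt(abs(est_b$median - plugin_tp_bulk(mu(sp, "bulk"), mu("POM", "bulk"), 1, 3.4)),
              0.1, label = paste(sp, "bulk median vs oracle"))
    est_g <- suppressWarnings(summarize_posterior(fit_tp(cohort, quick_csia_spec(sp, seed = 5))))
    expect_lt(abs(est_g$median - plugin_tp_csia(mu(sp, "Glx"), mu(sp, "Phe"), 3.4, 7.6)),
              0.1, label = paste(sp, "Glx-Phe median vs oracle"))
    est_p <- suppressWarnings(summarize_posterior(fit_tp(cohort, quick_csia_spec(
      sp, pair = c("Pro", "Phe"), tef = tef_defaults()$pro_phe,
      beta = beta_defaults()$pro_phe, seed = 5))))
    expect_lt(abs(est_p$median - plugin_tp_csia(mu(sp, "Pro"), mu(sp, "Phe"), 3.1, 4.5)),
              0.1, label = paste(sp, "Pro-Phe median vs oracle"))
  }
})

test_that("fixed TEF and beta reduce the CSI-AA posterior to an affine transform", {
  moments <- data.frame(species = "k", analyte = c("Glx", "Phe"),
                        mean = c(14.9, 1.7), sd = c(1.8, 1.0), n = 30)
  spec <- cohort_spec(moments, n_hauls = 1, haul_sd_fraction = 0, seed = 8)
  cohort <- generate_cohort(spec)
  fit <- fit_tp(cohort, quick_csia_spec("k", tef = tef_prior(7.6, 0),
                                        beta = beta_prior(3.4, 0), seed = 2))
  expect_equal(fit$tp, 1 + (fit$params$mu_delta - 3.4) / 7.6, tolerance = 1e-12)
  d <- compute_deltas(cohort, c("Glx", "Phe"))
  expect_lt(abs(median(tp_values(fit)) - plugin_tp_csia(mean(d$delta) + 1.7, 1.7, 3.4, 7.6)),
            0.05)
})

test_that("consumer identical to baseline yields TP = lambda", {
  moments <- data.frame(species = c("a", "b"), analyte = "bulk",
                        mean = 5, sd = 0.8, n = 60)
  cohort <- generate_cohort(cohort_spec(moments, n_hauls = 5, seed = 12))
  est <- suppressWarnings(summarize_posterior(fit_tp(
    cohort, quick_bulk_spec("a", baseline = "b", lambda = 2, seed = 3))))
  expect_lt(abs(est$median - 2), 0.1)
})

test_that("adding a constant to consumer and baseline leaves bulk TP unchanged", {
  cohort <- generate_cohort(toy_spec(seed = 6))
  spec <- tp_model_spec("bulk", "consumer", tef_defaults()$bulk,
                        baseline = "base", lambda = 1, seed = 4)
  f1 <- fit_tp(cohort, spec)
  shifted <- cohort
  shifted$bulk <- shifted$bulk + 7
  f2 <- fit_tp(shifted, spec)
  # the posterior is shift-invariant; sampled draws agree to MC precision
  q1 <- quantile(tp_values(f1), c(0.025, 0.5, 0.975))
  q2 <- quantile(tp_values(f2), c(0.025, 0.5, 0.975))
  expect_equal(q1, q2, tolerance = 0.05)
})

test_that("widening the TEF prior never narrows the credible interval", {
  cohort <- generate_cohort(toy_spec(seed = 2))
  fit <- fit_tp(cohort, quick_bulk_spec("consumer", baseline = "base", seed = 9))
  widths <- sapply(c(0, 0.25, 0.51, 1.0), function(s) {
    tp <- tp_values(propagate_tef(fit, tef_prior(3.4, s), seed = 9))
    diff(quantile(tp, c(0.025, 0.975)))
  })
  expect_true(all(diff(widths) > -1e-8))
})

test_that("insufficient samples raise explicit errors", {
  cohort <- generate_cohort(toy_spec(seed = 2))
  expect_error(fit_tp(cohort, quick_bulk_spec("missing", baseline = "base")),
               ">= 2 consumer samples")
  expect_error(fit_tp(cohort, quick_bulk_spec("consumer", baseline = "missing")),
               ">= 2 baseline samples")
  one <- cohort[cohort$species == "consumer", ][1, ]
  expect_error(fit_tp(one, quick_csia_spec("consumer")), ">= 2 consumer samples")
})

test_that("posterior summaries report equal-tailed intervals and diagnostics", {
  # closed-form check on a synthetic standard-normal draw matrix
  fit <- structure(list(species = "x", method = "csia", label = "test",
                        spec = list(mcmc = list(seed = 1)),
                        params = list(mu_delta = matrix(0, 2, 2)),
                        tp = NULL, n_obs = c(consumer = 4, baseline = NA),
                        diagnostics = data.frame(param = "mu_delta",
                                                 rhat = 1.0, ess = 1e6)),
                   class = "tp_draws")
  set.seed(1)
  fit$tp <- matrix(rnorm(1e6), ncol = 4)
  est <- summarize_posterior(fit)
  expect_lt(abs(est$median), 0.01)
  expect_lt(abs(est$ci_low + 1.96), 0.02)
  expect_lt(abs(est$ci_high - 1.96), 0.02)
  expect_true(est$note %in% c("tp_outside_1_6"))
  # constant draws give a degenerate interval
  fit$tp <- matrix(2, 100, 4)
  est2 <- summarize_posterior(fit)
  expect_equal(unlist(est2[c("median", "ci_low", "ci_high")]),
               c(median = 2, ci_low = 2, ci_high = 2))
})

test_that("split-Rhat flags diverged chains and passes well-mixed ones", {
  set.seed(3)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- good + matrix(rep(c(0, 0, 0, 5), each = 1000), 1000, 4)
  expect_gt(split_rhat(bad), 1.5)
  trending <- matrix(seq(0, 1, length.out = 1000), 1000, 2)
  expect_gt(split_rhat(trending), 1.5)  # within-chain trend caught by splitting
})
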