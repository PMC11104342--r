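test_that("CSV reading handles minimal files, missing cells and malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,haul,bulk",
               "krill,H1,3.5",
               "krill,H2,4.1"), path)
  s <- read_isotope_samples(path)
  expect_s3_class(s, "isotope_samples")
  expect_equal(nrow(s), 2L)
  expect_equal(s$bulk, c(3.5, 4.1))
  expect_equal(s$haul_id, c("H1", "H2"))

  # empty Phe cell -> absent analyte, never zero
  writeLines(c("species,haul,Glx,Phe",
               "fish,H1,23.9,0.8",
               "fish,H1,23.1,"), path)
  s <- read_isotope_samples(path)
  expect_true(is.na(s$Phe[2]))
  expect_equal(s$Glx[2], 23.1)

  # header matching is case-insensitive
  writeLines(c("SPECIES,HAUL,BULK,phe", "krill,H1,3.5,1.7"), path)
  s <- read_isotope_samples(path)
  expect_equal(s$bulk, 3.5)
  expect_equal(s$Phe, 1.7)

  # malformed numeric cell -> that row rejected, with a row-indexed message
  writeLines(c("species,haul,bulk", "krill,H1,3.5", "krill,H2,oops"), path)
  expect_warning(s <- read_isotope_samples(path), "rows 2")
  expect_equal(nrow(s), 1L)

  # no recognizable analyte column is fatal
  writeLines(c("species,haul,weight", "krill,H1,12"), path)
  expect_error(read_isotope_samples(path), "format error")
})

test_that("write/read round-trip preserves random samples exactly", {
  cohort <- generate_cohort(toy_spec(seed = 7))
  cohort <- cohort[sample(seq_len(nrow(cohort)), 50), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotope_samples(cohort, path)
  back <- read_isotope_samples(path)
  for (col in names(cohort))
    expect_equal(back[[col]], cohort[[col]], tolerance = 1e-12, label = col)
})

test_that("validation enforces the sanity window and analyte presence", {
  expect_error(isotope_samples(data.frame(species = "x", bulk = 99)),
               "sanity window")
  expect_error(isotope_samples(data.frame(species = "x", bulk = NA_real_)),
               "at least one analyte")
  expect_error(isotope_samples(data.frame(species = "x", weight = 1)),
               "no recognizable analyte")
})

test_that("summaries use mean, n-1 SD, and flag singletons", {
  s <- isotope_samples(data.frame(
    species = c("a", "a", "a", "b"),
    bulk = c(1, 2, 3, 5)))
  out <- summarize_species(s)
  a <- out[out$species == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)  # n-1 denominator
  expect_equal(a$n, 3L)
  b <- out[out$species == "b", ]
  expect_equal(b$sd, 0)
  expect_true(b$single_obs)
})

test_that("summarize is permutation-invariant and matches generating moments", {
  cohort <- generate_cohort(toy_spec(seed = 3))
  s1 <- summarize_species(cohort)
  perm <- cohort[rev(seq_len(nrow(cohort))), ]
  s2 <- summarize_species(perm)
  key <- function(d) d[order(d$species, d$analyte), c("mean", "sd", "n")]
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)

  # Monte-Carlo: 1000 draws at mean 14.9, sd 1.8 -> mean within 3 SE
  spec <- cohort_spec(data.frame(species = "krill", analyte = "Glx",
                                 mean = 14.9, sd = 1.8, n = 1000),
                      n_hauls = 10, haul_sd_fraction = 0.3, seed = 11)
  big <- generate_cohort(spec)
  m <- summarize_species(big)
  se <- sqrt(0.3^2 * 1.8^2 / 10 + (1 - 0.3^2) * 1.8^2 / 1000)
  expect_lt(abs(m$mean[m$analyte == "Glx"] - 14.9), 3 * se)
})

test_that("trophic-minus-source deltas follow the classification contract", {
  s <- isotope_samples(data.frame(
    species = c("fish", "fish", "fish"),
    Glx = c(23.9, 20, NA),
    Pro = c(19.8, 19.8, 21),
    Phe = c(0.8, 19.8, 1.0)))
  d <- compute_deltas(s, c("Glx", "Phe"))
  expect_equal(d$delta[1], 23.1)
  expect_equal(attr(d, "n_skipped"), 1L)
  # equal values give delta 0
  d2 <- compute_deltas(s, c("Pro", "Phe"))
  expect_equal(d2$delta[2], 0)
  # classification guard with override
  expect_error(compute_deltas(s, c("Phe", "Glx")), "not \\(trophic, source\\)")
  expect_silent(compute_deltas(s, c("Phe", "Glx"), allow_any = TRUE))
  # mean of deltas equals difference of means on a fixed complete sample set
  cc <- s[!is.na(s$Glx) & !is.na(s$Phe), ]
  expect_equal(mean(compute_deltas(cc, c("Glx", "Phe"))$delta),
               mean(cc$Glx) - mean(cc$Phe))
})

test_that("default amino-acid classification matches the field grouping", {
  cls <- aa_classification()
  expect_setequal(names(cls)[cls == "trophic"],
                  c("Ala", "Asp", "Glx", "Gly", "Ile", "Leu", "Pro", "Val"))
  expect_setequal(names(cls)[cls == "source"], c("Lys", "Met", "Phe", "Tyr"))
  expect_setequal(names(cls)[cls == "other"], c("Ser", "Thr"))
})
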