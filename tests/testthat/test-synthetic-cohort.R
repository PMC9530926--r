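test_that("subject generation is seeded-deterministic and respects the config", {
  cfg <- cohort_config(seed = 1)
  s1 <- generate_subjects(cfg)
  s2 <- generate_subjects(cfg)
  expect_identical(s1, s2)

  expect_equal(sum(s1$group != "control"), 17L)
  expect_equal(sum(s1$group == "roller"), 11L)
  expect_equal(sum(s1$group == "spray"), 6L)
  expect_true(all(s1$age >= 21 & s1$age <= 54))

  # controls: cotinine present, zero solvent dose, zero exposure years
  ctl <- s1[s1$group == "control", ]
  expect_true(all(ctl$cotinine > 0))
  expect_true(all(ctl$dose_MA == 0 & ctl$dose_SBMA == 0))

  # dose = concentration x years, per metabolite
  expect_equal(s1$dose_MHIPP, s1$MHIPP * s1$exposure_years)

  # degenerate Hardy-Weinberg: zero minor-allele frequency => all wild type
  s0 <- generate_subjects(cohort_config(seed = 3, allele_freq_hOGG1 = 0,
                                        allele_freq_XRCC1 = 0))
  expect_true(all(s0$hOGG1 == "wt"))
  expect_true(all(s0$XRCC1 == "wt"))

  expect_error(cohort_config(n_roller = 0), "positive")
  expect_error(cohort_config(allele_freq_hOGG1 = 1.2), "\\[0, 1\\]")
})

test_that("spray painters receive higher noise and solvent exposure than rollers", {
  s <- generate_subjects(cohort_config(seed = 5, n_roller = 300,
                                       n_spray = 300, n_controls = 2))
  expect_gt(mean(s$L_ex8h[s$group == "spray"]),
            mean(s$L_ex8h[s$group == "roller"]))
  expect_gt(median(s$MA[s$group == "spray"]),
            median(s$MA[s$group == "roller"]))
})

test_that("audiology couples HL and DPOAE negatively through latent damage", {
  cfg <- cohort_config(seed = 11, n_roller = 400, n_spray = 300,
                       n_controls = 300)
  s <- generate_subjects(cfg)
  aud <- generate_audiology(s, planted_effects(), seed = 12)
  hl_mean <- rowMeans(as.matrix(aud$hl[-1]))
  dp_mean <- rowMeans(as.matrix(aud$dpoae[-1]))
  expect_lt(cor(hl_mean, dp_mean), 0)
  # damage raises HL and lowers DPOAE
  expect_gt(cor(hl_mean, s$damage), 0.5)
  expect_lt(cor(dp_mean, s$damage), -0.5)
})

test_that("per-ear 5 dB quantization and ear averaging behave as stated", {
  s <- generate_subjects(cohort_config(seed = 2))
  eff0 <- planted_effects(hl_noise_sd = 0, dp_noise_sd = 0)
  s0 <- s
  s0$damage <- 0
  # zero damage, zero ear noise: HL equals the 5 dB-quantized age baseline
  one <- generate_audiology(s0, eff0, seed = 9, ears = 1)
  baseline <- outer(s0$age - 20, planted_effects()$hl_baseline_age / 10) + 2
  expect_equal(as.matrix(one$hl[-1]), round(baseline / 5) * 5,
               ignore_attr = TRUE)
  # single-ear levels sit on the 5 dB grid
  noisy <- generate_audiology(s, planted_effects(), seed = 10, ears = 1)
  expect_true(all(as.matrix(noisy$hl[-1]) %% 5 == 0))
  # two-ear mode averages two quantized draws: half-steps appear
  two <- generate_audiology(s, planted_effects(), seed = 10, ears = 2)
  expect_true(all(round(as.matrix(two$hl[-1]) * 2 / 5) ==
                    as.matrix(two$hl[-1]) * 2 / 5))
  expect_error(generate_audiology(s[0, ], planted_effects()), "empty")
})

test_that("HL regression on latent damage recovers the frequency profile", {
  cfg <- cohort_config(seed = 21, n_roller = 4000, n_spray = 3000,
                       n_controls = 3000)
  s <- generate_subjects(cfg)
  eff <- planted_effects()
  aud <- generate_audiology(s, eff, seed = 22)
  freqs <- hl_frequencies()
  for (k in c(1, 5, 9, 11)) {
    fit <- lm(aud$hl[[paste0("F", freqs[k])]] ~ s$damage + s$age)
    est <- coef(summary(fit))["s$damage", ]
    expect_lt(abs(est["Estimate"] - eff$hl_profile[k]), 3 * est["Std. Error"])
  }
})

test_that("genotype multiplier ordering makes mut hearing worse at equal exposure", {
  cfg <- cohort_config(
    seed = 31, n_roller = 2000, n_spray = 1, n_controls = 1,
    noise_sd = 0, metabolite_sdlog = 0,
    exposure_years_range = c(10, 10),
    allele_freq_hOGG1 = 0.5
  )
  s <- generate_subjects(cfg)
  aud <- generate_audiology(s, planted_effects(), seed = 32)
  hl_mean <- rowMeans(as.matrix(aud$hl[-1]))
  keep <- s$group == "roller"
  w <- stats::wilcox.test(hl_mean[keep & s$hOGG1 == "mut"],
                          hl_mean[keep & s$hOGG1 == "wt"],
                          alternative = "greater")
  expect_lt(w$p.value, 0.001)
})

test_that("count generation is NB with planted fold changes and couplings", {
  s <- generate_subjects(cohort_config(seed = 41))
  eff <- planted_effects(n_genes = 60)
  cm1 <- generate_counts(s, eff, seed = 42)
  cm2 <- generate_counts(s, eff, seed = 42)
  expect_identical(cm1$counts, cm2$counts)

  # dispersion -> 0 with no planted effects: Poisson limit, variance ~ mean
  eff0 <- planted_effects(
    de_table = default_de_table()[0, ], coupling_slope = 0,
    dispersion = 0, n_genes = 200
  )
  big <- generate_subjects(cohort_config(seed = 43, n_roller = 400,
                                         n_spray = 200, n_controls = 2))
  cm0 <- generate_counts(big, eff0, mean_depth = 5e4, seed = 44,
                         libsize_sdlog = 0)
  m <- rowMeans(cm0$counts)
  v <- apply(cm0$counts, 1, var)
  keep <- m > 20
  expect_lt(median(abs(v[keep] / m[keep] - 1)), 0.15)
  # equal library-size factors: column sums approximately equal
  cs <- colSums(cm0$counts)
  expect_lt(max(abs(cs / mean(cs) - 1)), 0.05)

  expect_error(generate_counts(s[0, ], eff), "empty")
  expect_error(generate_counts(s, eff, mean_depth = -1), "positive")
  expect_error(planted_effects(dispersion = -0.5), "non-negative")
})

test_that("cohort tables round-trip through the tab-separated form", {
  co <- tiny_cohort(seed = 51, n_genes = 30)
  dir <- withr::local_tempdir()
  write_cohort(co[c("subjects", "hl", "dpoae", "counts")], dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$subjects), as.data.frame(co$subjects),
               tolerance = 1e-8)
  expect_equal(as.data.frame(back$hl), as.data.frame(co$hl), tolerance = 1e-8)
  expect_equal(as.data.frame(back$dpoae), as.data.frame(co$dpoae),
               tolerance = 1e-8)
  expect_identical(back$counts$counts, co$counts$counts)
  expect_equal(as.character(back$counts$condition),
               as.character(co$counts$condition))

  # schema violation: a dropped genotype column is named in the error
  subj2 <- co$subjects
  subj2$hOGG1 <- NULL
  dir2 <- withr::local_tempdir()
  write_cohort(list(subjects = subj2), dir2)
  expect_error(read_cohort(dir2), "hOGG1")

  # empty cohort is refused, not written as empty files
  expect_error(write_cohort(list(subjects = co$subjects[0, ]), dir2),
               "empty")
})
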