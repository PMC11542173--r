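test_that("cohort_spec validates its inputs", {
  expect_error(cohort_spec(n_ctl = 1), "at least 2")
  expect_error(cohort_spec(freqs = c(2, 1, 3)), "strictly increasing")
  expect_error(cohort_spec(freqs = c(-1, 1, 2)), "strictly increasing")
  expect_error(cohort_spec(spectral_noise_sd = -0.1), "non-negative")
  expect_error(
    cohort_spec(channels = c("Cz", "Oz"),
                topography_weights = list(alpha = c(1, 1, 1),
                                          beta = c(1, 1))),
    "one non-negative weight per channel")
  spec <- cohort_spec(n_ctl = 3, n_pd = 4, channels = c("Cz", "Oz"))
  expect_s3_class(spec, "cohort_spec")
  expect_length(spec$topography_weights$alpha, 2)
})

test_that("zero-variance draws hit the distribution means exactly", {
  spec <- cohort_spec(
    n_ctl = 2, n_pd = 2, channels = c("Oz", "Cz"),
    group_params = list(
      CTL = list(offset = c(mean = 0.5, sd = 0),
                 exponent = c(mean = 1.0, sd = 0)),
      PD = list(offset = c(mean = 0.7, sd = 0),
                exponent = c(mean = 1.15, sd = 0))),
    peaks = list(alpha = list(cf = c(mean = 10, sd = 0),
                              pw = c(mean = 0.6, sd = 0),
                              width = c(mean = 1.2, sd = 0),
                              topography = "uniform")),
    within_subject_sd = c(offset = 0, exponent = 0, alpha_pw = 0),
    spectral_noise_sd = 0)
  set.seed(1)
  p <- sample_subject_params(spec, "CTL", NA, "EC")
  # EC adds the condition shift on top of the CTL means
  expect_equal(p$offset, rep(0.5 + 0.05, 2))
  expect_equal(p$exponent, rep(1.0 + 0.05, 2))
  expect_equal(p$peaks[[1]]$pw, 0.6 + 0.10)
  p_eo <- sample_subject_params(spec, "PD", "ON", "EO")
  expect_equal(p_eo$offset, rep(0.7, 2))
  expect_equal(p_eo$exponent, rep(1.15, 2))
})

test_that("unknown labels are configuration errors", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz")
  expect_error(sample_subject_params(spec, "PATIENT", NA, "EC"),
               "Unknown group")
  expect_error(sample_subject_params(spec, "CTL", NA, "resting"),
               "Unknown condition")
  expect_error(sample_subject_params(spec, "PD", "SOMETIMES", "EC"),
               "Unknown session")
})

test_that("group offset gap of 0.2 with SD 0.1 yields pooled d near 2", {
  # brute-force simulation oracle for the pooled-SD Cohen's d
  spec <- cohort_spec(
    n_ctl = 2, n_pd = 2, channels = "Cz",
    group_params = list(
      CTL = list(offset = c(mean = 0.5, sd = 0.1),
                 exponent = c(mean = 1, sd = 0)),
      PD = list(offset = c(mean = 0.7, sd = 0.1),
                exponent = c(mean = 1, sd = 0))),
    within_subject_sd = c(offset = 0, exponent = 0, alpha_pw = 0))
  set.seed(42)
  b_ctl <- replicate(1000,
                     eegspectra:::draw_subject_base(spec, "CTL")$offset)
  b_pd <- replicate(1000,
                    eegspectra:::draw_subject_base(spec, "PD")$offset)
  d <- (mean(b_pd) - mean(b_ctl)) / sqrt((var(b_pd) + var(b_ctl)) / 2)
  expect_equal(d, 2.0, tolerance = 0.1)
})

test_that("identical RNG state reproduces identical parameter draws", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = c("Cz", "Oz"))
  set.seed(99); p1 <- sample_subject_params(spec, "PD", "OFF", "EC")
  set.seed(99); p2 <- sample_subject_params(spec, "PD", "OFF", "EC")
  expect_identical(p1, p2)
})

test_that("synthesize_psd matches the closed-form generative model", {
  spec <- cohort_spec(
    n_ctl = 2, n_pd = 2, channels = "Cz", freqs = c(1, 10, 13),
    peaks = list(alpha = list(cf = c(mean = 10, sd = 0.5),
                              pw = c(mean = 0.6, sd = 0.1),
                              width = c(mean = 1.2, sd = 0.1),
                              topography = "uniform")))
  p <- tibble::tibble(
    subject = "s", group = "CTL", session = NA_character_,
    condition = "EC", channel = "Cz", offset = 1, exponent = 1,
    peaks = list(tibble::tibble(cf = numeric(0), pw = numeric(0),
                                sd = numeric(0))))
  psd <- synthesize_psd(p, spec, noise_sd = 0)
  expect_equal(psd$power[psd$freq == 1], 10)
  expect_equal(psd$power[psd$freq == 10], 1)

  # single Gaussian: log10 P(10) = 0.5, log10 P(13) = 0.5 exp(-2)
  p$offset <- 0; p$exponent <- 0
  p$peaks <- list(tibble::tibble(cf = 10, pw = 0.5, sd = 1.5))
  psd2 <- synthesize_psd(p, spec, noise_sd = 0)
  expect_equal(log10(psd2$power[psd2$freq == 10]), 0.5)
  expect_equal(log10(psd2$power[psd2$freq == 13]), 0.5 * exp(-9 / 4.5),
               tolerance = 1e-12)
  expect_equal(0.5 * exp(-9 / 4.5), 0.0677, tolerance = 1e-3)
})

test_that("an offset shift of log10(2) doubles every linear power", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz")
  p <- tibble::tibble(
    subject = "s", group = "CTL", session = NA_character_,
    condition = "EC", channel = "Cz", offset = 1, exponent = 1.3,
    peaks = list(tibble::tibble(cf = 10, pw = 0.4, sd = 1.5)))
  p2 <- p; p2$offset <- p$offset + log10(2)
  a <- synthesize_psd(p, spec, noise_sd = 0)
  b <- synthesize_psd(p2, spec, noise_sd = 0)
  expect_equal(b$power, 2 * a$power, tolerance = 1e-12)
})

test_that("cohort layout: paired PD sessions, CTL without session", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = c("Cz", "Oz"),
                      seed = 7)
  coh <- generate_cohort(spec)
  recs <- dplyr::distinct(coh$manifest, subject, group, session, condition)
  # 2 CTL x 2 conditions + 2 PD x 2 sessions x 2 conditions
  expect_equal(nrow(recs), 12)
  pd <- dplyr::filter(recs, group == "PD")
  expect_setequal(unique(pd$session), c("ON", "OFF"))
  counts <- dplyr::count(pd, subject)
  expect_true(all(counts$n == 4))
  ctl <- dplyr::filter(recs, group == "CTL")
  expect_true(all(is.na(ctl$session)))
  expect_setequal(unique(ctl$condition), c("EC", "EO"))
})

test_that("default cohort spec reproduces the study group sizes", {
  spec <- cohort_spec()
  expect_equal(spec$n_ctl, 26L)
  expect_equal(spec$n_pd, 26L)
  expect_length(spec$channels, 64)
})

test_that("same seed gives byte-identical cohorts", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz", seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$spectra, c2$spectra)
})

test_that("paired sessions share subject-level parameters (null ON/OFF)", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz",
                      within_subject_sd = c(offset = 0, exponent = 0,
                                            alpha_pw = 0), seed = 5)
  coh <- generate_cohort(spec)
  pd <- dplyr::filter(coh$manifest, group == "PD", condition == "EC")
  on <- dplyr::filter(pd, session == "ON")
  off <- dplyr::filter(pd, session == "OFF")
  expect_equal(on$true_offset, off$true_offset)
  expect_equal(on$true_exponent, off$true_exponent)
})

test_that("time-domain synthesis respects scale and Nyquist", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz")
  set.seed(3)
  p <- sample_subject_params(spec, "CTL", NA, "EO")
  expect_error(synthesize_recording(p, duration_s = 2, fs = 30),
               "Nyquist")
  rec0 <- synthesize_recording(p, duration_s = 2, fs = 200, scale = 0)
  expect_true(all(rec0$Cz == 0))
})

test_that("written cohorts round-trip through the TSV interface", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = c("Cz", "Oz"),
                      seed = 11)
  coh <- generate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$manifest), nrow(coh$manifest))
  re <- dplyr::arrange(back$spectra, subject, session, condition, channel,
                       freq)
  or <- dplyr::arrange(coh$spectra, subject, session, condition, channel,
                       freq)
  expect_equal(re$power, or$power, tolerance = 1e-9)
  expect_equal(re$group, or$group)
})
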