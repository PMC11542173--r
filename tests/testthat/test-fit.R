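test_that("fit_settings validates and carries the published defaults", {
  s <- fit_settings()
  expect_equal(s$peak_width_limits, c(1, 8))
  expect_equal(s$max_n_peaks, 8L)
  expect_equal(s$min_peak_height, 0.1)
  expect_equal(s$peak_threshold, 2)
  expect_equal(s$aperiodic_mode, "fixed")
  expect_equal(s$fit_range, c(2, 40))
  expect_error(fit_settings(peak_width_limits = c(8, 1)), "min < max")
  expect_error(fit_settings(peak_threshold = -1), ">= 0")
  expect_error(fit_settings(aperiodic_mode = "knee"), "fixed")
})

test_that("aperiodic fit is exact on noiseless peak-free spectra", {
  f <- grid_2_40
  ap <- fit_aperiodic(f, model_spectrum(f, 1.5, 1.2))
  expect_equal(unname(ap), c(1.5, 1.2), tolerance = 1e-6)
  # flat spectrum: zero exponent
  ap0 <- fit_aperiodic(f, rep(2, length(f)))
  expect_equal(ap0[["exponent"]], 0, tolerance = 1e-9)
  expect_error(fit_aperiodic(f, c(-1, rep(1, length(f) - 1))), "positive")
})

test_that("robust first pass resists peak-induced slope bias", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.6, sd = 1.5)
  p <- model_spectrum(f, 1, 1, pk)
  rob <- fit_aperiodic(f, p, robust = TRUE)
  plain <- fit_aperiodic(f, p, robust = FALSE)
  expect_lt(abs(rob[["exponent"]] - 1), 0.05)
  # oracle: the peak-free spectrum gives the unbiased slope; the
  # non-robust fit deviates from it more than the robust one does
  truth <- fit_aperiodic(f, model_spectrum(f, 1, 1), robust = FALSE)
  expect_gt(abs(plain[["exponent"]] - truth[["exponent"]]),
            abs(rob[["exponent"]] - truth[["exponent"]]))
})

test_that("flattening is the exact inverse of adding the aperiodic model", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.4, sd = 2)
  p <- model_spectrum(f, 0.8, 1.1, pk)
  ap <- c(offset = 0.8, exponent = 1.1)
  flat <- flatten_spectrum(f, p, ap)
  expect_equal(flat, 0.4 * exp(-(f - 10)^2 / 8), tolerance = 1e-9)
  # spectrum equal to its own model flattens to zero
  p0 <- model_spectrum(f, 0.8, 1.1)
  expect_equal(flatten_spectrum(f, p0, ap), rep(0, length(f)),
               tolerance = 1e-12)
  # add the model back: original log10 spectrum exactly
  back <- flat + eegspectra:::aperiodic_model(f, 0.8, 1.1)
  expect_equal(back, log10(p), tolerance = 1e-12)
})

test_that("peak detection finds height and location of a clean Gaussian", {
  f <- grid_2_40
  flat <- 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2))
  g <- detect_peaks(f, flat)
  expect_equal(nrow(g), 1)
  expect_lt(abs(g$cf[1] - 10), 0.25)
  expect_lt(abs(g$pw[1] - 0.5), 0.05)
})

test_that("detection respects the absolute height floor", {
  f <- grid_2_40
  flat <- 0.05 * exp(-(f - 10)^2 / (2 * 1.5^2))
  expect_equal(nrow(detect_peaks(f, flat)), 0)
})

test_that("detection stops at the configured peak budget", {
  f <- seq(2, 40, 0.25)
  cfs <- seq(5, 36, length.out = 10)
  flat <- rowSums(vapply(cfs, function(cf)
    0.5 * exp(-(f - cf)^2 / (2 * 0.8^2)), numeric(length(f))))
  g <- detect_peaks(f, flat)
  expect_equal(nrow(g), 8)
})

test_that("joint peak refit recovers multiple clean peaks", {
  f <- grid_2_40
  flat <- 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2)) +
    0.3 * exp(-(f - 20)^2 / (2 * 2^2))
  g <- detect_peaks(f, flat)
  pk <- fit_peaks_joint(f, flat, g)
  expect_equal(nrow(pk), 2)
  expect_lt(max(abs(pk$cf - c(10, 20))), 0.1)
  expect_true(all(pk$bw >= 1 & pk$bw <= 8))
  # empty guesses stay empty
  empty <- fit_peaks_joint(f, flat, detect_peaks(f, rep(0, length(f))))
  expect_equal(nrow(empty), 0)
})

test_that("peak height is recovered without material bias under noise", {
  f <- grid_2_40
  set.seed(31)
  errs <- replicate(100, {
    flat <- 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2)) +
      rnorm(length(f), 0, 0.02)
    pk <- fit_peaks_joint(f, flat, detect_peaks(f, flat))
    pk$pw[which.max(pk$pw)] - 0.5
  })
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(max(abs(errs)), 0.06)
})

test_that("aperiodic refit on the peak-removed spectrum is exact", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.5, sd = 1.5)
  p <- model_spectrum(f, 1.3, 0.9, pk)
  ap <- refit_aperiodic(f, p, pk)
  expect_equal(unname(ap), c(1.3, 0.9), tolerance = 1e-6)
  # with no peaks it coincides with the plain least-squares fit
  p0 <- model_spectrum(f, 1.3, 0.9)
  ap0 <- refit_aperiodic(f, p0, pk[0, ])
  expect_equal(ap0, fit_aperiodic(f, p0, robust = FALSE),
               tolerance = 1e-12)
})

test_that("full decomposition is near-exact on a noiseless model spectrum", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.5, sd = 1.5)
  fit <- fit_spectrum(tibble::tibble(freq = f,
                                     power = model_spectrum(f, 0.8, 1.1, pk)))
  expect_lt(abs(fit$offset - 0.8), 1e-3)
  expect_lt(abs(fit$exponent - 1.1), 1e-3)
  expect_equal(nrow(fit$peaks), 1)
  expect_lt(abs(fit$peaks$cf - 10), 1e-3)
  expect_lt(abs(fit$peaks$pw - 0.5), 1e-3)
  expect_lt(abs(fit$peaks$sd - 1.5), 1e-3)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("scaling power by 10 shifts only the offset", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.5, sd = 1.5)
  p <- model_spectrum(f, 0.8, 1.1, pk, noise_sd = 0)
  f1 <- fit_spectrum(tibble::tibble(freq = f, power = p))
  f2 <- fit_spectrum(tibble::tibble(freq = f, power = p * 10))
  expect_equal(f2$offset - f1$offset, 1.0, tolerance = 1e-9)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-9)
  expect_equal(f2$peaks$cf, f1$peaks$cf, tolerance = 1e-9)
  expect_equal(f2$peaks$pw, f1$peaks$pw, tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("fitted peaks always respect the bounds", {
  f <- grid_2_40
  set.seed(32)
  for (i in 1:20) {
    n_pk <- sample(0:3, 1)
    pk <- if (n_pk > 0) {
      data.frame(cf = runif(n_pk, 5, 35), pw = runif(n_pk, 0.2, 0.8),
                 sd = runif(n_pk, 0.6, 3))
    } else NULL
    fit <- fit_spectrum(tibble::tibble(
      freq = f, power = model_spectrum(f, runif(1, -1, 2),
                                       runif(1, 0.5, 2), pk,
                                       noise_sd = 0.03)))
    expect_lte(nrow(fit$peaks), 8)
    if (nrow(fit$peaks) > 0) {
      expect_true(all(fit$peaks$bw >= 1 - 1e-9 & fit$peaks$bw <= 8 + 1e-9))
      expect_true(all(fit$peaks$cf >= 2 & fit$peaks$cf <= 40))
      expect_true(all(fit$peaks$pw > 0))
    }
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("fit_cohort produces one tidy row per spectrum", {
  spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = c("Cz", "Oz"),
                      seed = 17)
  coh <- generate_cohort(spec)
  params <- fit_cohort(coh$spectra)
  expect_equal(nrow(params), 24)   # 12 recordings x 2 channels
  expect_setequal(
    names(params),
    c("subject", "group", "session", "condition", "channel", "offset",
      "exponent", "r_squared", "mean_abs_error", "n_peaks", "peaks"))
  # fitted truth tracks the manifest
  j <- dplyr::inner_join(
    params, coh$manifest,
    by = c("subject", "session", "condition", "channel"))
  expect_gt(cor(j$offset, j$true_offset), 0.9)
})

test_that("fit QC flags a participant-condition mean 3 SD below the rest", {
  params <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                               condition = c("EC", "EO"),
                               channel = c("Cz", "Oz"))
  set.seed(33)
  params$r_squared <- 0.98 + rnorm(nrow(params), 0, 0.001)
  bad <- params$subject == "s03" & params$condition == "EO"
  params$r_squared[bad] <- 0.90
  qc <- qc_fits(params)
  flagged <- dplyr::filter(qc, flagged)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$subject, "s03")
  expect_equal(flagged$condition, "EO")
  # threshold arithmetic: flag iff mean < grand mean - 3 SD
  expect_true(flagged$mean_r_squared < unique(qc$threshold))
})

test_that("QC with identical fits flags nobody", {
  params <- tidyr::expand_grid(subject = c("a", "b", "c"),
                               condition = "EC", channel = c("Cz", "Oz"))
  params$r_squared <- 0.99
  expect_false(any(qc_fits(params)$flagged))
})

test_that("tidy and glance summarize a spectral fit", {
  f <- grid_2_40
  pk <- data.frame(cf = 10, pw = 0.5, sd = 1.5)
  fit <- fit_spectrum(tibble::tibble(freq = f,
                                     power = model_spectrum(f, 1, 1, pk)))
  td <- tidy(fit)
  expect_equal(td$term[1:2], c("offset", "exponent"))
  expect_equal(td$estimate[td$term == "peak1_cf"], 10, tolerance = 1e-3)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$r_squared, 0.999)
  expect_s3_class(ggplot2::ggplot_build(autoplot(fit))$plot, "ggplot")
})
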