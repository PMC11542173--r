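#' Settings for spectral parameterization
#'
#' Collects the tunable settings of the iterative periodic/aperiodic
#' decomposition. Defaults are the standard published settings for resting
#' EEG: peak bandwidth limits 1-8 Hz, at most 8 peaks, minimum peak height
#' 0.1 log10 units, peak detection threshold 2 SD of the flattened
#' spectrum, fixed (knee-free) aperiodic mode, fit range 2-40 Hz.
#'
#' @param peak_width_limits Numeric length-2: allowed peak bandwidth range
#'   in Hz. Bandwidth is reported as `bw = 2 * sd` of the Gaussian, and the
#'   limits apply to `bw`.
#' @param max_n_peaks Maximum number of peaks fitted.
#' @param min_peak_height Absolute detection floor in log10 power units.
#' @param peak_threshold Relative detection threshold, in multiples of the
#'   SD of the current flattened spectrum.
#' @param aperiodic_mode Only `"fixed"` is supported:
#'   \eqn{\log_{10} P(f) = b - \chi \log_{10} f}.
#' @param fit_range Numeric length-2 frequency range fitted, Hz.
#' @param robust_percentile Quantile of the zero-clipped first-pass
#'   residuals used as the masking threshold in the robust aperiodic fit;
#'   the default 0.025 in practice excludes every point lying above the
#'   initial fit (oscillatory bumps) from the second pass.
#' @param edge_sd_limit Guessed peaks closer than `edge_sd_limit * sd` to a
#'   fit-range edge are dropped.
#' @param overlap_sd_limit Of two guesses whose centers differ by less than
#'   `overlap_sd_limit` times the larger SD, only the taller is kept.
#' @param refine_iter Number of alternating peak/aperiodic refinement
#'   passes after the first refit (improves exactness on noiseless
#'   spectra; stops early on convergence).
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(peak_width_limits = c(1, 8),
                         max_n_peaks = 8,
                         min_peak_height = 0.1,
                         peak_threshold = 2,
                         aperiodic_mode = "fixed",
                         fit_range = c(2, 40),
                         robust_percentile = 0.025,
                         edge_sd_limit = 1.0,
                         overlap_sd_limit = 0.75,
                         refine_iter = 2) {
  if (peak_width_limits[1] <= 0 ||
      peak_width_limits[1] >= peak_width_limits[2]) {
    abort("`peak_width_limits` must satisfy 0 < min < max.")
  }
  if (max_n_peaks < 0) abort("`max_n_peaks` must be >= 0.")
  if (min_peak_height < 0 || peak_threshold < 0) {
    abort("Peak thresholds must be >= 0.")
  }
  if (!identical(aperiodic_mode, "fixed")) {
    abort("Only the fixed aperiodic mode is supported.")
  }
  if (fit_range[1] <= 0 || fit_range[1] >= fit_range[2]) {
    abort("`fit_range` must satisfy 0 < fmin < fmax.")
  }
  structure(
    list(peak_width_limits = as.numeric(peak_width_limits),
         max_n_peaks = as.integer(max_n_peaks),
         min_peak_height = min_peak_height,
         peak_threshold = peak_threshold,
         aperiodic_mode = aperiodic_mode,
         fit_range = as.numeric(fit_range),
         robust_percentile = robust_percentile,
         edge_sd_limit = edge_sd_limit,
         overlap_sd_limit = overlap_sd_limit,
         refine_iter = as.integer(refine_iter)),
    class = "fit_settings"
  )
}

#' @export
print.fit_settings <- function(x, ...) {
  cat(sprintf("<fit_settings> width %g-%g Hz, max %d peaks, min height %g, threshold %g SD, %s mode, %g-%g Hz\n",
              x$peak_width_limits[1], x$peak_width_limits[2], x$max_n_peaks,
              x$min_peak_height, x$peak_threshold, x$aperiodic_mode,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Fit the aperiodic component of a power spectrum
#'
#' Least-squares fit of the fixed-mode aperiodic model
#' \eqn{\log_{10} P(f) = b - \chi \log_{10} f}. With `robust = TRUE` a
#' second pass refits after masking out the points that sit above the
#' first-pass fit (residuals above the `robust_percentile` quantile of the
#' zero-clipped residuals), which stops oscillatory bumps from tilting the
#' aperiodic estimate.
#'
#' @param freqs Frequencies, Hz (positive).
#' @param power Linear power (positive).
#' @param settings A [fit_settings()].
#' @param robust Use the residual-masked second pass?
#' @return Named numeric vector `c(offset, exponent)`.
#' @export
fit_aperiodic <- function(freqs, power, settings = fit_settings(),
                          robust = TRUE) {
  if (any(power <= 0)) abort("Power must be positive to fit in log space.")
  if (any(freqs <= 0)) abort("Frequencies must be positive.")
  y <- log10(power)
  lx <- log10(freqs)
  if (length(unique(lx)) < 2) abort("Cannot fit aperiodic: degenerate frequency grid.")
  co <- aperiodic_ols(lx, y)
  if (robust) {
    co <- fit_aperiodic_impl(lx, y, settings, robust = TRUE)
  }
  c(offset = co[1], exponent = co[2])
}

# OLS of y = b - chi * lx, returning c(b, chi).
aperiodic_ols <- function(lx, y) {
  fit <- stats::.lm.fit(cbind(1, -lx), y)
  co <- fit$coefficients
  c(co[1], co[2])
}

#' Remove the aperiodic component from a spectrum
#'
#' @param freqs Frequencies, Hz.
#' @param power Linear power.
#' @param ap Named vector `c(offset, exponent)` from [fit_aperiodic()].
#' @return The flattened spectrum: log10 power minus the aperiodic model.
#' @export
flatten_spectrum <- function(freqs, power, ap) {
  log10(power) - aperiodic_model(freqs, ap[["offset"]], ap[["exponent"]])
}

#' Iteratively detect peak guesses in a flattened spectrum
#'
#' Repeatedly takes the global maximum of the current flattened residual,
#' accepts it if its height clears both the absolute floor
#' (`min_peak_height`) and the relative threshold (`peak_threshold` times
#' the SD of the current residual), estimates its width from the
#' half-height crossing, subtracts the guessed Gaussian, and repeats until
#' `max_n_peaks` have been accepted or no candidate passes. The SD used in
#' the relative threshold is recomputed at each iteration.
#'
#' @param freqs Frequencies, Hz.
#' @param flattened Flattened log10 spectrum from [flatten_spectrum()].
#' @param settings A [fit_settings()].
#' @return Tibble of guesses (`cf`, `pw`, `sd`) in detection order
#'   (descending height); zero rows when nothing passes.
#' @export
detect_peaks <- function(freqs, flattened, settings = fit_settings()) {
  as_tibble(as.data.frame(detect_peaks_impl(freqs, flattened, settings)))
}

#' Jointly refit peak guesses by bounded nonlinear least squares
#'
#' Simultaneous Levenberg-Marquardt fit of the multi-Gaussian model to the
#' flattened spectrum, with analytic Jacobian and box bounds: center
#' frequencies inside the fit range, heights non-negative, Gaussian SDs
#' within half the bandwidth limits. Guesses violating the edge or overlap
#' rules are dropped before the fit. If the optimizer fails, the pruned
#' guesses are returned unchanged and flagged.
#'
#' @param freqs Frequencies, Hz.
#' @param flattened Flattened log10 spectrum.
#' @param guesses Guess tibble from [detect_peaks()].
#' @param settings A [fit_settings()].
#' @return Tibble of peak parameters (`cf`, `pw`, `sd`, `bw = 2 * sd`),
#'   sorted by `cf`, with attribute `converged`.
#' @export
fit_peaks_joint <- function(freqs, flattened, guesses,
                            settings = fit_settings()) {
  g <- if (is.data.frame(guesses)) {
    cbind(cf = guesses$cf, pw = guesses$pw, sd = guesses$sd)
  } else {
    guesses
  }
  pf <- fit_peaks_impl(freqs, flattened, g, settings)
  out <- as_tibble(as.data.frame(pf$peaks))
  out$bw <- 2 * out$sd
  if (isTRUE(pf$fellback)) {
    warn("Joint peak fit failed; returning initial guesses.")
  }
  attr(out, "converged") <- pf$converged
  out
}

#' Refit the aperiodic component after peak removal
#'
#' Subtracts the fitted multi-Gaussian model from the log10 spectrum and
#' refits the aperiodic line by ordinary (non-robust) least squares; once
#' peaks are removed the residual is linear in log-log space and no
#' masking is needed.
#'
#' @param freqs Frequencies, Hz.
#' @param power Linear power.
#' @param peaks Peak tibble from [fit_peaks_joint()].
#' @param settings A [fit_settings()].
#' @return Named numeric vector `c(offset, exponent)`.
#' @export
refit_aperiodic <- function(freqs, power, peaks,
                            settings = fit_settings()) {
  if (any(power <= 0)) abort("Power must be positive to fit in log space.")
  y <- log10(power) - gaussian_sum(freqs, peaks)
  co <- aperiodic_ols(log10(freqs), y)
  c(offset = co[1], exponent = co[2])
}

as_peak_tibble <- function(pk) {
  out <- as_tibble(as.data.frame(pk))
  out$bw <- 2 * out$sd
  out
}

#' Parameterize one power spectrum
#'
#' Full iterative decomposition of a power spectrum into aperiodic and
#' periodic components: robust aperiodic fit, flattening, iterative peak
#' detection, joint bounded peak refit, aperiodic refit on the
#' peak-removed spectrum, then (when `refine_iter > 0`) a
#' variable-projection polish that refits the peaks against the raw log10
#' spectrum with the aperiodic line profiled out by least squares, so the
#' combined model reaches the joint least-squares optimum. The final model
#' is the sum of the aperiodic line and the fitted Gaussians; goodness of
#' fit is the squared Pearson correlation between model and data in log10
#' space.
#'
#' @param data A data frame with columns `freq` (Hz) and `power` (linear),
#'   or a numeric vector of frequencies (with `power` supplied separately).
#' @param settings A [fit_settings()].
#' @param power Linear power vector when `data` is a frequency vector.
#' @return An object of class `spectral_fit`: offset, exponent, peak table,
#'   `r_squared`, `mean_abs_error` (log10 units), the fitted grid, data and
#'   model, and a convergence flag.
#' @examples
#' f <- seq(2, 40, 0.25)
#' p <- 10^(1 - 1.2 * log10(f) + 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2)))
#' fit <- fit_spectrum(data.frame(freq = f, power = p))
#' fit
#' @export
fit_spectrum <- function(data, settings = fit_settings(), power = NULL) {
  if (is.data.frame(data)) {
    freqs <- data$freq; pw <- data$power
  } else {
    freqs <- data; pw <- power
  }
  keep <- freqs >= settings$fit_range[1] & freqs <= settings$fit_range[2]
  freqs <- freqs[keep]; pw <- pw[keep]
  if (length(freqs) < 3) abort("Too few frequencies inside the fit range.")
  if (any(pw <= 0)) abort("Power must be positive on the fit range.")
  res <- fit_spectrum_impl(freqs, pw, settings)
  structure(
    list(offset = res$offset, exponent = res$exponent,
         peaks = as_peak_tibble(res$peaks), r_squared = res$r_squared,
         mean_abs_error = res$mean_abs_error,
         freqs = freqs, log_power = res$y, model = res$model,
         settings = settings, converged = isTRUE(res$converged)),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> offset %.4f, exponent %.4f, %d peak(s), R^2 %.5f, MAE %.5f\n",
              x$offset, x$exponent, nrow(x$peaks), x$r_squared,
              x$mean_abs_error))
  if (nrow(x$peaks) > 0) {
    for (k in seq_len(nrow(x$peaks))) {
      cat(sprintf("  peak %d: cf %.2f Hz, height %.3f, bw %.2f Hz\n",
                  k, x$peaks$cf[k], x$peaks$pw[k], x$peaks$bw[k]))
    }
  }
  invisible(x)
}

#' Parameterize every spectrum of a tidy cohort table
#'
#' Fits [fit_spectrum()] to each subject-session-condition-channel spectrum
#' and returns the tidy parameter table used by the band-power and
#' statistics stages.
#'
#' @param spectra Tidy tibble with columns `subject`, `session`,
#'   `condition`, `channel`, `freq`, `power` (and optionally `group`).
#' @param settings A [fit_settings()].
#' @return A tibble, one row per spectrum: identifiers, `offset`,
#'   `exponent`, `r_squared`, `mean_abs_error`, `n_peaks`, and `peaks`
#'   (semicolon-joined `cf:pw:sd` triples).
#' @export
fit_cohort <- function(spectra, settings = fit_settings()) {
  has_group <- "group" %in% names(spectra)
  id <- paste(spectra$subject, spectra$session, spectra$condition,
              spectra$channel, sep = "\r")
  idx <- split(seq_len(nrow(spectra)), factor(id, levels = unique(id)))
  n <- length(idx)
  first <- vapply(idx, `[`, 0L, 1)
  offset <- exponent <- r2 <- mae <- numeric(n)
  n_peaks <- integer(n)
  pk_str <- character(n)
  fr <- settings$fit_range
  for (j in seq_len(n)) {
    i <- idx[[j]]
    keep <- spectra$freq[i] >= fr[1] & spectra$freq[i] <= fr[2]
    fit <- fit_spectrum_impl(spectra$freq[i][keep],
                             spectra$power[i][keep], settings)
    offset[j] <- fit$offset; exponent[j] <- fit$exponent
    r2[j] <- fit$r_squared; mae[j] <- fit$mean_abs_error
    n_peaks[j] <- nrow(fit$peaks)
    pk_str[j] <- serialize_peaks(as.data.frame(fit$peaks))
  }
  tibble(
    subject = spectra$subject[first],
    group = if (has_group) spectra$group[first] else NA_character_,
    session = spectra$session[first],
    condition = spectra$condition[first],
    channel = spectra$channel[first],
    offset = offset, exponent = exponent, r_squared = r2,
    mean_abs_error = mae, n_peaks = n_peaks, peaks = pk_str
  )
}

#' Goodness-of-fit quality control across a cohort
#'
#' Computes each participant's mean R^2 per condition (across channels and
#' sessions) and flags participant-condition means more than 3 SD below
#' the grand mean of those means. Flagged participants are reported, not
#' removed: inclusion is the caller's decision.
#'
#' @param params Parameter table from [fit_cohort()].
#' @return A tibble: `subject`, `condition`, `mean_r_squared`, `threshold`,
#'   `flagged`.
#' @export
qc_fits <- function(params) {
  if (length(unique(params$subject)) < 2) {
    abort("QC requires at least two participants.")
  }
  means <- dplyr::summarise(
    dplyr::group_by(params, .data$subject, .data$condition),
    mean_r_squared = mean(.data$r_squared), .groups = "drop")
  gm <- mean(means$mean_r_squared)
  gsd <- sd(means$mean_r_squared)
  thr <- gm - 3 * gsd
  means$threshold <- thr
  means$flagged <- if (gsd == 0) FALSE else means$mean_r_squared < thr
  means
}
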