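#' Canonical frequency band definitions
#'
#' Alpha (8-13 Hz) and beta (13-30 Hz) by default. Band membership is
#' lower-inclusive and upper-exclusive, except that the last band also
#' includes its upper edge; the shared 13 Hz grid point therefore belongs
#' to beta only, and no point is counted twice.
#'
#' @param bands Named list of `c(fmin, fmax)` pairs, in band order.
#' @return A tibble `band`, `fmin`, `fmax`, `upper_inclusive`.
#' @export
band_definitions <- function(bands = list(alpha = c(8, 13),
                                          beta = c(13, 30))) {
  for (b in bands) if (b[1] >= b[2]) abort("Each band needs fmin < fmax.")
  tibble(
    band = names(bands),
    fmin = vapply(bands, `[`, 0, 1),
    fmax = vapply(bands, `[`, 0, 2),
    upper_inclusive = seq_along(bands) == length(bands)
  )
}

band_mask <- function(freqs, fmin, fmax, upper_inclusive) {
  if (upper_inclusive) freqs >= fmin & freqs <= fmax
  else freqs >= fmin & freqs < fmax
}

#' Total band power of a spectrum
#'
#' Arithmetic mean of the *linear* power over the grid points inside the
#' band (the traditional pre-parameterization measure; it still contains
#' the aperiodic component).
#'
#' @param freqs Frequencies, Hz.
#' @param power Linear power.
#' @param band One row of [band_definitions()] (or a list with `fmin`,
#'   `fmax`, `upper_inclusive`).
#' @return Mean linear power in the band.
#' @export
total_band_power <- function(freqs, power, band) {
  m <- band_mask(freqs, band$fmin, band$fmax, band$upper_inclusive)
  if (!any(m)) {
    abort(sprintf("Band [%g, %g) contains no grid points.",
                  band$fmin, band$fmax))
  }
  mean(power[m])
}

#' Parameterized band power of a fitted model
#'
#' Mean over the band's grid points of the fitted Gaussian peak component
#' in log10 units — the oscillatory power left after the aperiodic
#' component has been removed. Zero when no fitted peak reaches into the
#' band, which gives paired statistics a defined value even for subjects
#' without a discrete peak.
#'
#' @param fit A `spectral_fit`, or a peak tibble (`cf`, `pw`, `sd`).
#' @param band One row of [band_definitions()].
#' @param freqs Grid on which to average; defaults to the fit's own grid.
#' @return Mean peak-model log10 power in the band (>= 0).
#' @export
parameterized_band_power <- function(fit, band, freqs = NULL) {
  peaks <- if (inherits(fit, "spectral_fit")) fit$peaks else fit
  if (is.null(freqs)) {
    if (!inherits(fit, "spectral_fit")) {
      abort("Supply `freqs` when passing a bare peak table.")
    }
    freqs <- fit$freqs
  }
  if (band$fmin < min(freqs) || band$fmax > max(freqs)) {
    abort("Band lies outside the fitted frequency range.")
  }
  m <- band_mask(freqs, band$fmin, band$fmax, band$upper_inclusive)
  mean(gaussian_sum(freqs[m], peaks))
}

deserialize_peaks <- function(s) {
  if (is.na(s) || s == "") {
    return(tibble(cf = numeric(0), pw = numeric(0), sd = numeric(0)))
  }
  trip <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  mat <- do.call(rbind, lapply(trip, as.numeric))
  tibble(cf = mat[, 1], pw = mat[, 2], sd = mat[, 3])
}

#' Band-power table for a cohort
#'
#' Joins total band power (from the restricted spectra) and parameterized
#' band power (from the fitted peak models) for every
#' subject-session-condition-channel and band.
#'
#' @param spectra Tidy spectra tibble (`subject`, `session`, `condition`,
#'   `channel`, `freq`, `power`), already restricted to the fit range.
#' @param params Parameter table from [fit_cohort()].
#' @param bands A [band_definitions()] tibble.
#' @return A tibble with one row per key combination and band: identifiers,
#'   `band`, `total_power` (linear), `parameterized_power` (log10 units).
#' @export
band_power_table <- function(spectra, params,
                             bands = band_definitions()) {
  freqs <- sort(unique(spectra$freq))
  masks <- lapply(seq_len(nrow(bands)), function(i) {
    band_mask(freqs, bands$fmin[i], bands$fmax[i], bands$upper_inclusive[i])
  })
  id <- paste(spectra$subject, spectra$session, spectra$condition,
              spectra$channel, sep = "\r")
  idx <- split(seq_len(nrow(spectra)), factor(id, levels = unique(id)))
  n_key <- length(idx)
  first <- vapply(idx, `[`, 0L, 1)
  pid <- paste(params$subject, params$session, params$condition,
               params$channel, sep = "\r")
  pk_lookup <- match(names(idx), pid)
  n_band <- nrow(bands)
  total <- matrix(NA_real_, nrow = n_key, ncol = n_band)
  parm <- matrix(NA_real_, nrow = n_key, ncol = n_band)
  for (j in seq_len(n_key)) {
    i <- idx[[j]]
    pw <- spectra$power[i][order(spectra$freq[i])]
    pk <- if (is.na(pk_lookup[j])) NULL else
      deserialize_peaks(params$peaks[pk_lookup[j]])
    for (bi in seq_len(n_band)) {
      m <- masks[[bi]]
      total[j, bi] <- mean(pw[m])
      parm[j, bi] <- if (is.null(pk)) NA_real_ else
        mean(gaussian_sum(freqs[m], pk))
    }
  }
  out <- tibble(
    subject = rep(spectra$subject[first], each = n_band),
    session = rep(spectra$session[first], each = n_band),
    condition = rep(spectra$condition[first], each = n_band),
    channel = rep(spectra$channel[first], each = n_band),
    band = rep(bands$band, n_key),
    total_power = as.vector(t(total)),
    parameterized_power = as.vector(t(parm))
  )
  if ("group" %in% names(params)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(params, .data$subject, .data$group),
      by = "subject")
    out <- dplyr::select(out, "subject", "group", dplyr::everything())
  }
  out
}

#' Long measure table for statistics
#'
#' Stacks the six per-electrode measures — aperiodic `offset` and
#' `exponent`, `total_alpha`, `total_beta`, `param_alpha`, `param_beta` —
#' into one long tibble keyed by subject, group, session, condition and
#' channel, ready for [permutation_cluster_test()].
#'
#' @param params Parameter table from [fit_cohort()].
#' @param band_powers Table from [band_power_table()].
#' @return A tibble: identifiers, `measure`, `value`.
#' @export
measure_table <- function(params, band_powers) {
  ap <- tidyr::pivot_longer(
    dplyr::select(params, "subject", "group", "session", "condition",
                  "channel", "offset", "exponent"),
    cols = c("offset", "exponent"),
    names_to = "measure", values_to = "value")
  bp <- dplyr::mutate(band_powers,
                      total = .data$total_power,
                      param = .data$parameterized_power)
  bp <- tidyr::pivot_longer(
    dplyr::select(bp, "subject", "group", "session", "condition",
                  "channel", "band", "total", "param"),
    cols = c("total", "param"),
    names_to = "kind", values_to = "value")
  bp$measure <- paste(bp$kind, bp$band, sep = "_")
  bp <- dplyr::select(bp, "subject", "group", "session", "condition",
                      "channel", "measure", "value")
  dplyr::bind_rows(ap, bp)
}
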