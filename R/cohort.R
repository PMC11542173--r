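#' Specify a synthetic resting-EEG cohort
#'
#' Describes the generative model for a synthetic cohort of resting-state EEG
#' power spectra: a control group (CTL) and a patient group (PD) with paired
#' medication sessions (ON/OFF), each subject recorded eyes-closed (EC) and
#' eyes-open (EO). Every spectrum follows the fixed-mode aperiodic model plus
#' Gaussian oscillatory peaks in log10 power,
#' \deqn{\log_{10} P(f) = b - \chi \log_{10} f + \sum_k pw_k
#'   e^{-(f - cf_k)^2 / (2 sd_k^2)} + \varepsilon,}
#' with subject-level variability on all parameters, additive condition
#' (EC/EO) and medication (ON/OFF) shifts, per-channel topographic weighting
#' of peak heights, and i.i.d. Gaussian observation noise
#' \eqn{\varepsilon} on log10 power.
#'
#' Between-subject offset and exponent are drawn jointly with correlation
#' `ap_correlation`; in real resting EEG the two parameters are strongly
#' positively correlated across subjects, and the correlation is what keeps
#' broadband band-power variability realistic. Defaults reproduce the
#' magnitudes of group differences reported for Parkinson's disease resting
#' EEG: offset +0.2 log10 units and exponent +0.15 in PD versus CTL
#' (between-group Cohen's d roughly 1.05 and 0.7), EC minus EO shifts of
#' +0.05 on both aperiodic parameters and +0.10 on alpha peak height, and a
#' null ON/OFF medication effect.
#'
#' @param n_ctl,n_pd Number of control and patient subjects (each >= 2).
#' @param channels Character vector of montage labels; defaults to the
#'   64-channel cap of [montage_64()].
#' @param freqs Strictly increasing positive frequency grid in Hz.
#' @param group_params Named list with elements `CTL` and `PD`, each a list
#'   with numeric `offset = c(mean, sd)` and `exponent = c(mean, sd)`
#'   (between-subject mean and SD).
#' @param ap_correlation Between-subject correlation of offset and exponent,
#'   in \[-1, 1\].
#' @param peaks Named list of peak templates. Each template is a list with
#'   `cf = c(mean, sd)` (Hz), `pw = c(mean, sd)` (log10 power), `width =
#'   c(mean, sd)` (Gaussian SD, Hz), and `topography` (one of `"posterior"`,
#'   `"central"`, `"uniform"`).
#' @param condition_effects Named list with numeric vectors `EC` and `EO`,
#'   each with elements `offset`, `exponent`, `alpha_pw` added to the
#'   subject's parameters in that condition.
#' @param medication_effects As `condition_effects`, with elements `ON` and
#'   `OFF` (applied to PD sessions only).
#' @param within_subject_sd Named numeric vector (`offset`, `exponent`,
#'   `alpha_pw`): SD of the session/condition-level parameter jitter that
#'   makes paired contrasts realistically noisy.
#' @param topography_weights Optional named list of per-channel multiplier
#'   vectors (one per peak template, each of length `length(channels)`,
#'   non-negative). When `NULL`, weights are computed from the montage
#'   geometry according to each template's `topography`.
#' @param spectral_noise_sd SD of the additive observation noise on log10
#'   power (log10 units, >= 0).
#' @param seed Integer seed controlling all cohort randomness.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [sample_subject_params()], [synthesize_psd()]
#' @examples
#' spec <- cohort_spec(n_ctl = 3, n_pd = 3, channels = montage_16()$channel)
#' spec
#' @export
cohort_spec <- function(n_ctl = 26,
                        n_pd = 26,
                        channels = montage_64()$channel,
                        freqs = seq(2, 40, by = 0.25),
                        group_params = list(
                          CTL = list(offset = c(mean = 0.5, sd = 0.175),
                                     exponent = c(mean = 1.0, sd = 0.20)),
                          PD  = list(offset = c(mean = 0.7, sd = 0.175),
                                     exponent = c(mean = 1.15, sd = 0.20))
                        ),
                        ap_correlation = 0.9,
                        peaks = list(
                          alpha = list(cf = c(mean = 10, sd = 0.5),
                                       pw = c(mean = 0.6, sd = 0.10),
                                       width = c(mean = 1.2, sd = 0.10),
                                       topography = "posterior"),
                          beta = list(cf = c(mean = 20, sd = 1.0),
                                      pw = c(mean = 0.25, sd = 0.05),
                                      width = c(mean = 1.5, sd = 0.15),
                                      topography = "central")
                        ),
                        condition_effects = list(
                          EC = c(offset = 0.05, exponent = 0.05,
                                 alpha_pw = 0.10),
                          EO = c(offset = 0, exponent = 0, alpha_pw = 0)
                        ),
                        medication_effects = list(
                          ON = c(offset = 0, exponent = 0, alpha_pw = 0),
                          OFF = c(offset = 0, exponent = 0, alpha_pw = 0)
                        ),
                        within_subject_sd = c(offset = 0.05,
                                              exponent = 0.07,
                                              alpha_pw = 0.15),
                        topography_weights = NULL,
                        spectral_noise_sd = 0.05,
                        seed = 1L) {
  if (!is.numeric(n_ctl) || n_ctl < 2 || !is.numeric(n_pd) || n_pd < 2) {
    abort("`n_ctl` and `n_pd` must both be at least 2.")
  }
  if (!is.numeric(freqs) || any(freqs <= 0) || any(diff(freqs) <= 0)) {
    abort("`freqs` must be strictly increasing and positive.")
  }
  if (!is.character(channels) || length(channels) < 1 ||
      anyDuplicated(channels) > 0) {
    abort("`channels` must be a character vector of unique labels.")
  }
  for (g in c("CTL", "PD")) {
    gp <- group_params[[g]]
    if (is.null(gp)) abort(paste0("`group_params` must contain `", g, "`."))
    for (p in c("offset", "exponent")) {
      v <- gp[[p]]
      if (!is.numeric(v) || length(v) != 2 || v[2] < 0) {
        abort(paste0("`group_params$", g, "$", p,
                     "` must be c(mean, sd) with sd >= 0."))
      }
    }
  }
  if (abs(ap_correlation) > 1) {
    abort("`ap_correlation` must lie in [-1, 1].")
  }
  for (nm in names(peaks)) {
    pk <- peaks[[nm]]
    if (pk$width[1] <= 0) abort("Peak template widths must be positive.")
    if (pk$cf[1] < min(freqs) || pk$cf[1] > max(freqs)) {
      abort("Peak template center frequencies must lie inside `freqs`.")
    }
  }
  if (any(within_subject_sd < 0) || spectral_noise_sd < 0) {
    abort("All SDs must be non-negative.")
  }
  if (!is.null(topography_weights)) {
    for (nm in names(peaks)) {
      w <- topography_weights[[nm]]
      if (is.null(w) || length(w) != length(channels) || any(w < 0)) {
        abort("`topography_weights` must give one non-negative weight per channel per peak template.")
      }
    }
  } else {
    topography_weights <- default_topography_weights(channels, peaks)
  }
  structure(
    list(n_ctl = as.integer(n_ctl), n_pd = as.integer(n_pd),
         channels = channels, freqs = freqs, group_params = group_params,
         ap_correlation = ap_correlation, peaks = peaks,
         condition_effects = condition_effects,
         medication_effects = medication_effects,
         within_subject_sd = within_subject_sd,
         topography_weights = topography_weights,
         spectral_noise_sd = spectral_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Per-channel peak-height multipliers from montage geometry. Posterior
# templates ramp up toward the back of the head, central ones peak at the
# vertex; both stay within [0.45, 1.05] so no channel loses its peak.
default_topography_weights <- function(channels, peaks) {
  coords <- tryCatch(montage_64(channels),
                     error = function(e) tibble(channel = channels,
                                                x = 0, y = 0))
  out <- list()
  for (nm in names(peaks)) {
    topo <- peaks[[nm]]$topography %||% "uniform"
    w <- switch(topo,
      posterior = 0.45 + 0.6 * (1 - coords$y) / 2,
      central = 0.45 + 0.6 * (1 - pmin(sqrt(coords$x^2 + coords$y^2), 1)),
      uniform = rep(1, length(channels)),
      abort(paste0("Unknown topography `", topo, "`."))
    )
    out[[nm]] <- setNames(w, channels)
  }
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d CTL, %d PD (paired ON/OFF), conditions EC/EO\n",
              x$n_ctl, x$n_pd))
  cat(sprintf("  channels: %d; frequency grid %.2f-%.2f Hz (%d points)\n",
              length(x$channels), min(x$freqs), max(x$freqs),
              length(x$freqs)))
  cat(sprintf("  CTL offset %.2f (SD %.3f), exponent %.2f (SD %.2f); PD offset %.2f, exponent %.2f\n",
              x$group_params$CTL$offset[1], x$group_params$CTL$offset[2],
              x$group_params$CTL$exponent[1], x$group_params$CTL$exponent[2],
              x$group_params$PD$offset[1], x$group_params$PD$exponent[1]))
  cat(sprintf("  spectral noise SD %.3f log10 units; seed %d\n",
              x$spectral_noise_sd, x$seed))
  invisible(x)
}

#' Draw ground-truth spectral parameters for one synthetic recording
#'
#' Samples one subject's aperiodic and peak parameters for a given group,
#' session and condition, from the distributions in a [cohort_spec()].
#' Subject-level draws use the current RNG state, so the caller controls
#' reproducibility with `set.seed()` (or by using [generate_cohort()], which
#' seeds from the spec).
#'
#' @param spec A [cohort_spec()].
#' @param group `"CTL"` or `"PD"`.
#' @param session `"ON"`, `"OFF"`, or `NA` (controls carry no session).
#' @param condition `"EC"` or `"EO"`.
#' @param subject_id Identifier recorded in the output.
#' @param subject_base Optional list of subject-level base draws as returned
#'   by `draw_subject_base()`; supply the same base across sessions and
#'   conditions to obtain paired recordings from one underlying subject.
#' @return A tibble with one row per channel: `subject`, `group`, `session`,
#'   `condition`, `channel`, `offset`, `exponent`, and a `peaks` list-column
#'   of per-channel peak tables (`cf`, `pw`, `sd`).
#' @examples
#' spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = c("Oz", "Cz"))
#' set.seed(7)
#' sample_subject_params(spec, "CTL", NA, "EC")
#' @export
sample_subject_params <- function(spec, group, session = NA_character_,
                                  condition = "EC", subject_id = "S01",
                                  subject_base = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  if (!group %in% c("CTL", "PD")) {
    abort(paste0("Unknown group label `", group, "`."))
  }
  if (!condition %in% names(spec$condition_effects)) {
    abort(paste0("Unknown condition `", condition, "`."))
  }
  if (!is.na(session) && !session %in% names(spec$medication_effects)) {
    abort(paste0("Unknown session `", session, "`."))
  }
  base <- subject_base %||% draw_subject_base(spec, group)

  ce <- spec$condition_effects[[condition]]
  me <- if (is.na(session)) c(offset = 0, exponent = 0, alpha_pw = 0) else
    spec$medication_effects[[session]]
  wsd <- spec$within_subject_sd

  offset <- base$offset + ce[["offset"]] + me[["offset"]] +
    rnorm(1, 0, wsd[["offset"]])
  exponent <- max(base$exponent + ce[["exponent"]] + me[["exponent"]] +
                    rnorm(1, 0, wsd[["exponent"]]), 0)

  peak_names <- names(spec$peaks)
  pk_tab <- base$peaks
  if ("alpha" %in% peak_names) {
    shift <- ce[["alpha_pw"]] + me[["alpha_pw"]] +
      rnorm(1, 0, wsd[["alpha_pw"]])
    pk_tab$pw[pk_tab$name == "alpha"] <-
      pk_tab$pw[pk_tab$name == "alpha"] + shift
  }
  pk_tab$pw <- pmax(pk_tab$pw, 0)

  channels <- spec$channels
  peaks_by_channel <- lapply(channels, function(ch) {
    w <- vapply(pk_tab$name,
                function(nm) spec$topography_weights[[nm]][[ch]], 0)
    keep <- pk_tab$pw * w > 0
    tibble(cf = pk_tab$cf[keep], pw = unname(pk_tab$pw * w)[keep],
           sd = pk_tab$sd[keep])
  })

  tibble(
    subject = subject_id, group = group, session = session,
    condition = condition, channel = channels,
    offset = offset, exponent = exponent,
    peaks = peaks_by_channel
  )
}

# Subject-level (between-subject) parameter draws shared across the
# subject's sessions and conditions. Offset and exponent are drawn from a
# bivariate normal with correlation spec$ap_correlation.
draw_subject_base <- function(spec, group) {
  gp <- spec$group_params[[group]]
  z1 <- rnorm(1); z2 <- rnorm(1)
  rho <- spec$ap_correlation
  offset <- gp$offset[[1]] + gp$offset[[2]] * z1
  exponent <- max(gp$exponent[[1]] + gp$exponent[[2]] *
                    (rho * z1 + sqrt(1 - rho^2) * z2), 0)
  pk <- purrr::imap_dfr(spec$peaks, function(tmpl, nm) {
    tibble(name = nm,
           cf = rnorm(1, tmpl$cf[[1]], tmpl$cf[[2]]),
           pw = max(rnorm(1, tmpl$pw[[1]], tmpl$pw[[2]]), 0),
           sd = max(rnorm(1, tmpl$width[[1]], tmpl$width[[2]]), 0.2))
  })
  fr <- range(spec$freqs)
  pk$cf <- pmin(pmax(pk$cf, fr[1]), fr[2])
  list(offset = offset, exponent = exponent, peaks = pk)
}

#' Synthesize power spectra from ground-truth parameters
#'
#' Evaluates the generative model on the spec's frequency grid for each
#' channel of a parameter draw and adds i.i.d. Gaussian noise on log10
#' power. Output is in linear power units.
#'
#' @param params Per-channel parameter tibble from [sample_subject_params()].
#' @param spec The [cohort_spec()] providing the frequency grid and noise SD.
#' @param noise_sd Override for the spec's `spectral_noise_sd` (e.g. 0 for a
#'   noiseless spectrum).
#' @return A tidy tibble: `subject`, `group`, `session`, `condition`,
#'   `channel`, `freq` (Hz), `power` (linear units).
#' @examples
#' spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Oz")
#' set.seed(1)
#' p <- sample_subject_params(spec, "CTL", NA, "EC")
#' psd <- synthesize_psd(p, spec, noise_sd = 0)
#' @export
synthesize_psd <- function(params, spec, noise_sd = spec$spectral_noise_sd) {
  freqs <- spec$freqs
  if (any(freqs <= 0)) abort("Frequencies must be positive (log10 defined).")
  n_f <- length(freqs)
  n_ch <- nrow(params)
  lp <- matrix(0, nrow = n_f, ncol = n_ch)
  for (i in seq_len(n_ch)) {
    lp[, i] <- aperiodic_model(freqs, params$offset[i],
                               params$exponent[i]) +
      gaussian_sum(freqs, params$peaks[[i]])
  }
  if (noise_sd > 0) lp <- lp + rnorm(n_f * n_ch, 0, noise_sd)
  tibble(
    subject = rep(params$subject, each = n_f),
    group = rep(params$group, each = n_f),
    session = rep(params$session, each = n_f),
    condition = rep(params$condition, each = n_f),
    channel = rep(params$channel, each = n_f),
    freq = rep(freqs, n_ch),
    power = as.vector(10^lp)
  )
}

#' Synthesize a time-domain recording from ground-truth parameters
#'
#' Generates multichannel Gaussian time series whose expected power spectral
#' density follows the parameter model, by shaping white noise in the
#' frequency domain: independent complex-Gaussian Fourier coefficients are
#' scaled by the square root of the target PSD and inverse-transformed.
#' Below `f_floor` the 1/f model is clamped to its `f_floor` value, standing
#' in for the high-pass filtering applied to real recordings.
#'
#' @param params Per-channel parameter tibble from [sample_subject_params()]
#'   (noise-free model; observation noise is a spectral-domain concept).
#' @param duration_s Recording length in seconds (default 60 s).
#' @param fs Sampling rate in Hz (default 500); must exceed twice the
#'   highest peak frequency.
#' @param artifacts Optional list describing injected transients:
#'   `amplitude` (\eqn{\mu}V), `count` (per channel), `width` (samples,
#'   default 5).
#' @param scale Global amplitude multiplier (0 gives an all-zero recording).
#' @param f_floor Low-frequency clamp in Hz.
#' @return A wide tibble: `time` (s) then one \eqn{\mu}V column per channel,
#'   with attributes `fs`, `subject`, `session`, `condition`.
#' @examples
#' spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz")
#' set.seed(1)
#' p <- sample_subject_params(spec, "CTL", NA, "EO")
#' rec <- synthesize_recording(p, duration_s = 4, fs = 200)
#' @export
synthesize_recording <- function(params, duration_s = 60, fs = 500,
                                 artifacts = NULL, scale = 1,
                                 f_floor = 1) {
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict = TRUE)
  stopifnot_scalar_number(fs, "fs", min = 0, strict = TRUE)
  max_cf <- suppressWarnings(
    max(vapply(params$peaks, function(p)
      if (nrow(p)) max(p$cf) else 0, 0)))
  if (fs <= 2 * max_cf) {
    abort("`fs` must exceed twice the highest peak frequency (Nyquist).")
  }
  n <- round(duration_s * fs)
  half <- floor(n / 2)
  f_pos <- (1:half) * fs / n
  channels <- params$channel
  out <- matrix(0, nrow = n, ncol = length(channels))
  for (i in seq_along(channels)) {
    f_eval <- pmax(f_pos, f_floor)
    lp <- aperiodic_model(f_eval, params$offset[i], params$exponent[i]) +
      gaussian_sum(f_pos, params$peaks[[i]])
    s_target <- 10^lp
    # E|X_k|^2 = S(f_k) * fs * n / 2 makes the one-sided periodogram an
    # unbiased estimate of the target PSD.
    amp <- sqrt(s_target * fs * n / 2)
    re <- rnorm(half) / sqrt(2)
    im <- rnorm(half) / sqrt(2)
    spec_pos <- complex(real = amp * re, imaginary = amp * im)
    if (n %% 2 == 0) {
      # real Nyquist coefficient, variance S * fs * n (not doubled)
      spec_pos[half] <- complex(real = sqrt(s_target[half] * fs * n) *
                                  rnorm(1) / sqrt(2) * sqrt(2))
    }
    full <- complex(real = numeric(n))
    full[2:(half + 1)] <- spec_pos
    if (n %% 2 == 0) {
      if (half > 1) full[n:(half + 2)] <- Conj(spec_pos[1:(half - 1)])
    } else {
      full[n:(half + 1)] <- Conj(spec_pos)
    }
    x <- Re(fft(full, inverse = TRUE)) / n
    out[, i] <- scale * x
  }
  if (!is.null(artifacts) && scale != 0) {
    amp <- artifacts$amplitude %||% 300
    count <- artifacts$count %||% 1
    width <- artifacts$width %||% 5
    for (i in seq_along(channels)) {
      starts <- sample.int(n - width, count)
      for (s in starts) out[s:(s + width - 1), i] <- out[s:(s + width - 1), i] + amp
    }
  }
  rec <- tibble(time = (seq_len(n) - 1) / fs)
  for (i in seq_along(channels)) rec[[channels[i]]] <- out[, i]
  attr(rec, "fs") <- fs
  attr(rec, "subject") <- params$subject[1]
  attr(rec, "session") <- params$session[1]
  attr(rec, "condition") <- params$condition[1]
  class(rec) <- c("eeg_recording", class(rec))
  rec
}

#' Generate a full synthetic cohort
#'
#' Draws every subject of a [cohort_spec()] — `n_ctl` controls (session
#' `NA`) and `n_pd` patients with paired ON and OFF sessions — in both EC
#' and EO conditions, and synthesizes a power spectrum (or a time-domain
#' recording) for each subject-session-condition combination. Paired
#' sessions and conditions share the subject's between-subject parameter
#' draw, so ON/OFF contrasts are null by construction under the default
#' spec. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param output `"psd"` (default) for spectra on the spec grid, or
#'   `"recording"` for time-domain signals.
#' @param conditions Conditions to generate (default both EC and EO; a
#'   single condition halves the work for studies that only analyze one).
#' @param duration_s,fs Recording length and sampling rate when
#'   `output = "recording"`.
#' @return An object of class `eeg_cohort`: a list with `manifest` (one row
#'   per subject-session-condition-channel with true parameters), `spectra`
#'   (tidy tibble, when `output = "psd"`) or `recordings` (named list of
#'   recording tibbles), and the `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_ctl = 2, n_pd = 2,
#'                                    channels = c("Oz", "Cz"), seed = 42))
#' dplyr::count(coh$manifest, group, session, condition)
#' @export
generate_cohort <- function(spec, output = c("psd", "recording"),
                            conditions = c("EC", "EO"),
                            duration_s = 60, fs = 500) {
  output <- match.arg(output)
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  with_seed(spec$seed, {
    design <- cohort_design(spec, conditions)
    params_list <- vector("list", nrow(design))
    bases <- list()
    for (i in seq_len(nrow(design))) {
      sid <- design$subject[i]
      if (is.null(bases[[sid]])) {
        bases[[sid]] <- draw_subject_base(spec, design$group[i])
      }
      params_list[[i]] <- sample_subject_params(
        spec, design$group[i], design$session[i], design$condition[i],
        subject_id = sid, subject_base = bases[[sid]]
      )
    }
    params <- dplyr::bind_rows(params_list)
    manifest <- dplyr::mutate(
      dplyr::select(params, "subject", "group", "session", "condition",
                    "channel", true_offset = "offset",
                    true_exponent = "exponent"),
      peaks = vapply(params$peaks, serialize_peaks, "")
    )
    if (output == "psd") {
      spectra <- dplyr::bind_rows(
        lapply(params_list, synthesize_psd, spec = spec))
      res <- list(manifest = manifest, spectra = spectra, spec = spec)
    } else {
      recs <- lapply(params_list, synthesize_recording,
                     duration_s = duration_s, fs = fs)
      names(recs) <- paste(design$subject, design$session,
                           design$condition, sep = ".")
      res <- list(manifest = manifest, recordings = recs, spec = spec)
    }
    structure(res, class = "eeg_cohort")
  })
}

# One row per recording: subject x session x condition.
cohort_design <- function(spec, conditions = c("EC", "EO")) {
  ctl <- tidyr::expand_grid(
    subject = sprintf("CTL%02d", seq_len(spec$n_ctl)),
    session = NA_character_, condition = conditions)
  ctl$group <- "CTL"
  pd <- tidyr::expand_grid(
    subject = sprintf("PD%02d", seq_len(spec$n_pd)),
    session = c("OFF", "ON"), condition = conditions)
  pd$group <- "PD"
  dplyr::bind_rows(ctl, pd)[, c("subject", "group", "session", "condition")]
}

serialize_peaks <- function(pk) {
  if (nrow(pk) == 0) return("")
  paste(sprintf("%.6g:%.6g:%.6g", pk$cf, pk$pw, pk$sd), collapse = ";")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  n_rec <- length(unique(paste(x$manifest$subject, x$manifest$session,
                               x$manifest$condition)))
  cat("<eeg_cohort>\n")
  cat(sprintf("  %d recordings (%s), %d channels, seed %d\n", n_rec,
              if (is.null(x$spectra)) "time series" else "power spectra",
              length(x$spec$channels), x$spec$seed))
  invisible(x)
}

#' Write a cohort to tab-separated files
#'
#' Writes the ground-truth manifest (`manifest.tsv`) and one wide spectrum
#' table per recording (`<subject>_<session>_<condition>.tsv`, first column
#' `freq` in Hz, one linear-power column per channel).
#'
#' @param cohort An `eeg_cohort` with spectra.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "eeg_cohort") || is.null(cohort$spectra)) {
    abort("`cohort` must be an eeg_cohort generated with output = \"psd\".")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "manifest.tsv")
  readr::write_tsv(dplyr::rename(cohort$manifest,
                                 subject_id = "subject"), paths)
  keys <- dplyr::distinct(cohort$spectra, .data$subject, .data$session,
                          .data$condition)
  for (i in seq_len(nrow(keys))) {
    sub <- dplyr::filter(cohort$spectra,
                         .data$subject == keys$subject[i],
                         (is.na(keys$session[i]) & is.na(.data$session)) |
                           (!is.na(keys$session[i]) &
                              .data$session %in% keys$session[i]),
                         .data$condition == keys$condition[i])
    wide <- tidyr::pivot_wider(
      dplyr::select(sub, "freq", "channel", "power"),
      names_from = "channel", values_from = "power")
    p <- file.path(dir, sprintf("%s_%s_%s.tsv", keys$subject[i],
                                ifelse(is.na(keys$session[i]), "NA",
                                       keys$session[i]),
                                keys$condition[i]))
    readr::write_tsv(wide, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
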