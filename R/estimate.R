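#' Segment a recording into overlapping epochs
#'
#' Cuts a continuous multichannel recording into fixed-length epochs at
#' onsets `k * L * (1 - overlap)`, keeping only epochs that lie fully inside
#' the recording: `floor((T - L) / (L * (1 - overlap))) + 1` epochs for a
#' recording of duration `T` and epoch length `L`.
#'
#' @param rec A recording as returned by [synthesize_recording()] or
#'   [read_recording()]: a wide tibble with a `time` column (seconds) and
#'   one \eqn{\mu}V column per channel. The sampling rate is taken from the
#'   `fs` attribute, or from the time step.
#' @param epoch_len_ms Epoch length in milliseconds (default 2000).
#' @param overlap Fractional overlap between consecutive epochs, in
#'   `[0, 1)` (default 0.5).
#' @return An `epoch_set`: epochs array (`epochs x channels x samples`),
#'   sampling rate, onsets, a rejection mask (all `FALSE` initially), and
#'   the retention fraction. A recording shorter than one epoch yields an
#'   empty epoch set flagged with `too_short = TRUE` and a warning.
#' @examples
#' spec <- cohort_spec(n_ctl = 2, n_pd = 2, channels = "Cz")
#' set.seed(1)
#' rec <- synthesize_recording(sample_subject_params(spec, "CTL", NA, "EC"),
#'                             duration_s = 6, fs = 200)
#' segment_recording(rec)
#' @export
segment_recording <- function(rec, epoch_len_ms = 2000, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  stopifnot_scalar_number(epoch_len_ms, "epoch_len_ms", min = 0,
                          strict = TRUE)
  channels <- setdiff(names(rec), "time")
  fs <- attr(rec, "fs") %||% (1 / median(diff(rec$time)))
  x <- as.matrix(rec[, channels, drop = FALSE])
  if (any(!is.finite(x))) abort("Recording contains non-finite values.")
  n <- nrow(x)
  len <- round(epoch_len_ms / 1000 * fs)
  step <- len * (1 - overlap)
  meta <- list(subject = attr(rec, "subject"),
               session = attr(rec, "session"),
               condition = attr(rec, "condition"))
  if (n < len) {
    warn("Recording is shorter than one epoch; returning an empty epoch set.")
    return(new_epoch_set(array(0, dim = c(0, length(channels), len)),
                         fs, numeric(0), logical(0), channels, meta,
                         too_short = TRUE))
  }
  n_epochs <- floor((n - len) / step) + 1
  onsets <- (seq_len(n_epochs) - 1) * step / fs
  ep <- array(0, dim = c(n_epochs, length(channels), len))
  for (k in seq_len(n_epochs)) {
    i0 <- round((k - 1) * step)
    ep[k, , ] <- t(x[(i0 + 1):(i0 + len), , drop = FALSE])
  }
  new_epoch_set(ep, fs, onsets, rep(FALSE, n_epochs), channels, meta)
}

new_epoch_set <- function(epochs, fs, onsets, rejected, channels, meta,
                          too_short = FALSE) {
  structure(
    list(epochs = epochs, fs = fs, onsets = onsets, rejected = rejected,
         channels = channels, meta = meta, too_short = too_short),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz; retention %.3f\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$fs,
              retention_fraction(x)))
  invisible(x)
}

#' Retention fraction of an epoch set
#'
#' Proportion of epochs not marked artifactual.
#' @param es An `epoch_set`.
#' @return A number in `[0, 1]` (1 when no epoch has been rejected).
#' @export
retention_fraction <- function(es) {
  n <- length(es$rejected)
  if (n == 0) return(0)
  sum(!es$rejected) / n
}

#' Mark artifactual epochs by amplitude threshold
#'
#' An epoch is rejected when any channel's absolute deviation from that
#' channel's within-epoch mean exceeds `threshold_uv` (the +/-150 uV
#' criterion). Deviation is measured from the epoch mean rather than from
#' zero so that DC offsets do not trigger rejection.
#'
#' @param es An `epoch_set`.
#' @param threshold_uv Rejection threshold in \eqn{\mu}V (> 0).
#' @return The epoch set with its rejection mask and retention updated.
#' @export
reject_epochs <- function(es, threshold_uv = 150) {
  stopifnot_scalar_number(threshold_uv, "threshold_uv", min = 0,
                          strict = TRUE)
  n_epochs <- dim(es$epochs)[1]
  rej <- logical(n_epochs)
  for (k in seq_len(n_epochs)) {
    seg <- es$epochs[k, , , drop = FALSE]
    dim(seg) <- dim(es$epochs)[2:3]
    dev <- abs(seg - rowMeans(seg))
    rej[k] <- any(dev > threshold_uv)
  }
  es$rejected <- rej
  es
}

#' Retention quality-control check
#'
#' A recording passes when at least `min_fraction` of its epochs survived
#' artifact rejection; it is excluded only when retention is strictly below
#' the threshold (a retention of exactly 0.5 is kept). Subjects with any
#' failing recording are excluded at the pipeline level.
#'
#' @param es An `epoch_set` (after [reject_epochs()]).
#' @param min_fraction Minimum retention fraction (default 0.5).
#' @return `TRUE` (include) or `FALSE` (exclude).
#' @export
check_retention <- function(es, min_fraction = 0.5) {
  if (length(es$rejected) < 1) return(FALSE)
  retention_fraction(es) >= min_fraction
}

#' Averaged-periodogram power spectral density
#'
#' Welch-style PSD: each retained epoch is mean-detrended per channel,
#' tapered (Hamming by default), zero-padded by `pad_factor`, transformed,
#' and the one-sided periodograms are averaged. Density scaling divides by
#' `fs * sum(w^2)` and doubles all bins except DC and Nyquist, so units are
#' \eqn{\mu V^2/Hz} and, with a rectangular window and no padding, the
#' spectrum integrates to the mean epoch variance (Parseval). With 2000 ms
#' epochs at 500 Hz and `pad_factor = 2` the frequency resolution is
#' 0.25 Hz.
#'
#' @param es An `epoch_set`.
#' @param pad_factor Integer zero-padding factor (>= 1); padding interpolates
#'   the spectral grid by the same factor.
#' @param window `"hamming"` (default) or `"rectangular"`.
#' @return A tidy tibble `channel`, `freq` (Hz), `power`
#'   (\eqn{\mu V^2/Hz}), carrying the recording's identifiers as columns
#'   and `n_epochs_used` as an attribute.
#' @export
compute_psd <- function(es, pad_factor = 2,
                        window = c("hamming", "rectangular")) {
  window <- match.arg(window)
  keep <- which(!es$rejected)
  if (length(keep) == 0) {
    abort(paste0("No retained epochs for recording `",
                 es$meta$subject %||% "?", "`."))
  }
  len <- dim(es$epochs)[3]
  n_ch <- dim(es$epochs)[2]
  nfft <- as.integer(pad_factor) * len
  w <- if (window == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (0:(len - 1)) / (len - 1))
  } else {
    rep(1, len)
  }
  wnorm <- es$fs * sum(w^2)
  n_bins <- floor(nfft / 2) + 1
  acc <- matrix(0, nrow = n_bins, ncol = n_ch)
  buf <- matrix(0, nrow = nfft, ncol = n_ch)
  for (k in keep) {
    seg <- t(matrix(es$epochs[k, , ], nrow = n_ch))   # samples x channels
    seg <- sweep(seg, 2, colMeans(seg))
    buf[] <- 0
    buf[1:len, ] <- seg * w
    X <- stats::mvfft(buf)
    acc <- acc + (Mod(X[1:n_bins, , drop = FALSE])^2) / wnorm
  }
  psd <- acc / length(keep)
  psd[2:(n_bins - 1), ] <- 2 * psd[2:(n_bins - 1), ]
  if (nfft %% 2 == 1) psd[n_bins, ] <- 2 * psd[n_bins, ]
  freqs <- (0:(n_bins - 1)) * es$fs / nfft
  out <- tibble(
    subject = es$meta$subject %||% NA_character_,
    session = es$meta$session %||% NA_character_,
    condition = es$meta$condition %||% NA_character_,
    channel = rep(es$channels, each = n_bins),
    freq = rep(freqs, n_ch),
    power = as.vector(psd)
  )
  attr(out, "n_epochs_used") <- length(keep)
  out
}

#' Restrict a spectrum table to a frequency range
#'
#' Inclusive trim of the frequency grid; idempotent.
#'
#' @param psd A tidy spectrum tibble with a `freq` column.
#' @param fmin,fmax Range bounds in Hz (defaults 2 and 40, the fitting
#'   range).
#' @return The rows with `fmin <= freq <= fmax`.
#' @export
restrict_range <- function(psd, fmin = 2, fmax = 40) {
  out <- dplyr::filter(psd, .data$freq >= fmin, .data$freq <= fmax)
  if (nrow(out) == 0) {
    abort(sprintf("No frequencies in [%g, %g] Hz.", fmin, fmax))
  }
  out
}

#' Estimate spectra for every recording of a cohort
#'
#' Runs segmentation, amplitude-based rejection, retention QC and PSD
#' estimation over all recordings of an `eeg_cohort` generated with
#' `output = "recording"`, restricting spectra to the spec's frequency
#' range.
#'
#' @param cohort An `eeg_cohort` with `recordings`.
#' @param epoch_len_ms,overlap,threshold_uv,min_fraction,pad_factor
#'   Stage parameters; see the stage functions.
#' @return A list with `spectra` (tidy tibble over all retained
#'   recordings, including `subject`, `group`, `session`, `condition`) and
#'   `qc` (one row per recording: retention, n_epochs, included flag).
#' @export
estimate_cohort_spectra <- function(cohort, epoch_len_ms = 2000,
                                    overlap = 0.5, threshold_uv = 150,
                                    min_fraction = 0.5, pad_factor = 2) {
  if (!inherits(cohort, "eeg_cohort") || is.null(cohort$recordings)) {
    abort("`cohort` must contain time-domain recordings.")
  }
  groups <- dplyr::distinct(cohort$manifest, .data$subject, .data$group)
  qc <- list(); spectra <- list()
  for (nm in names(cohort$recordings)) {
    es <- segment_recording(cohort$recordings[[nm]], epoch_len_ms, overlap)
    es <- reject_epochs(es, threshold_uv)
    inc <- check_retention(es, min_fraction)
    qc[[nm]] <- tibble(
      recording = nm, subject = es$meta$subject,
      session = es$meta$session %||% NA_character_,
      condition = es$meta$condition,
      n_epochs = length(es$rejected),
      retention = retention_fraction(es), included = inc)
    if (inc) {
      ps <- restrict_range(compute_psd(es, pad_factor),
                           min(cohort$spec$freqs), max(cohort$spec$freqs))
      spectra[[nm]] <- ps
    }
  }
  qc <- dplyr::bind_rows(qc)
  # a subject is excluded entirely if any of its recordings failed QC
  bad_subjects <- unique(qc$subject[!qc$included])
  spectra <- dplyr::bind_rows(spectra)
  if (nrow(spectra) > 0) {
    spectra <- dplyr::filter(spectra, !.data$subject %in% bad_subjects)
    spectra <- dplyr::left_join(spectra, groups, by = "subject")
    spectra <- dplyr::select(spectra, "subject", "group", "session",
                             "condition", "channel", "freq", "power")
  }
  list(spectra = spectra, qc = qc, excluded_subjects = bad_subjects)
}
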