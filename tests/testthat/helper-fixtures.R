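# Shared fixtures, all generated in code.

grid_2_40 <- seq(2, 40, by = 0.25)

# Linear-power spectrum from the fixed-mode model plus Gaussian peaks.
# peaks: data frame with cf, pw, sd (or NULL).
model_spectrum <- function(freqs = grid_2_40, offset = 1, exponent = 1,
                           peaks = NULL, noise_sd = 0) {
  lp <- offset - exponent * log10(freqs)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (k in seq_len(nrow(peaks))) {
      lp <- lp + peaks$pw[k] *
        exp(-(freqs - peaks$cf[k])^2 / (2 * peaks$sd[k]^2))
    }
  }
  if (noise_sd > 0) lp <- lp + rnorm(length(freqs), 0, noise_sd)
  10^lp
}

spectrum_df <- function(...) {
  tibble::tibble(freq = grid_2_40, power = model_spectrum(...))
}

# A minimal three-channel line montage (A - B - C).
montage_line3 <- function() {
  tibble::tibble(channel = c("A", "B", "C"), x = c(0, 1, 2), y = c(0, 0.1, 0))
}

# Tidy measure data for a paired design: n subjects x channels.
paired_data <- function(n, channels, values) {
  dat <- tidyr::expand_grid(subject = sprintf("s%02d", seq_len(n)),
                            channel = channels)
  dat$value <- values
  dat
}

# Tidy measure data for an independent two-group design.
independent_data <- function(n_per_group, channels, values) {
  dat <- tidyr::expand_grid(subject = sprintf("s%02d", seq_len(2 * n_per_group)),
                            channel = channels)
  dat$group <- rep(rep(c("G1", "G2"), each = n_per_group),
                   each = length(channels))
  dat$value <- values
  dat
}

# A single-channel white-noise recording of the given duration.
noise_recording <- function(duration_s, fs = 500, sd = 1,
                            channel = "Cz") {
  n <- round(duration_s * fs)
  rec <- tibble::tibble(time = (seq_len(n) - 1) / fs)
  rec[[channel]] <- rnorm(n, sd = sd)
  attr(rec, "fs") <- fs
  class(rec) <- c("eeg_recording", class(rec))
  rec
}

band_alpha <- function() band_definitions()[1, ]
band_beta <- function() band_definitions()[2, ]
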