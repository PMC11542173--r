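#' Idealized 64-channel 10-10 montage
#'
#' Returns a 64-channel electrode layout following international 10-10
#' nomenclature, with 2D head-disc coordinates obtained by projecting the
#' scalp onto the unit circle (nose up, `y > 0` anterior, `x > 0` right).
#' Rows of electrodes (Fp, AF, F, FC, C, CP, P, PO, O) are placed at evenly
#' spaced anterior-posterior levels and spread across the chord of the head
#' circle at each level, which reproduces the qualitative geometry of a real
#' extended 10-20 cap. The layout is synthetic (computed, not digitized) but
#' topologically faithful, which is all the electrode adjacency graph needs.
#'
#' @param channels Optional character vector to subset and order the montage.
#'   Unknown labels are an error.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' head(montage_64())
#' @export
montage_64 <- function(channels = NULL) {
  rows <- list(
    Fp = list(y = 0.82, spread = 0.45, labels = c("Fp1", "Fpz", "Fp2")),
    AF = list(y = 0.62, spread = 0.80,
              labels = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    F  = list(y = 0.42, spread = 1, labels = c("F7", "F5", "F3", "F1", "Fz",
                                               "F2", "F4", "F6", "F8")),
    FC = list(y = 0.21, spread = 1,
              labels = c("FT7", "FC5", "FC3", "FC1", "FCz",
                         "FC2", "FC4", "FC6", "FT8")),
    C  = list(y = 0.00, spread = 1, labels = c("T7", "C5", "C3", "C1", "Cz",
                                               "C2", "C4", "C6", "T8")),
    CP = list(y = -0.21, spread = 1,
              labels = c("TP7", "CP5", "CP3", "CP1", "CPz",
                         "CP2", "CP4", "CP6", "TP8")),
    P  = list(y = -0.42, spread = 1, labels = c("P7", "P5", "P3", "P1", "Pz",
                                                "P2", "P4", "P6", "P8")),
    PO = list(y = -0.62, spread = 0.80,
              labels = c("PO7", "PO3", "POz", "PO4", "PO8")),
    O  = list(y = -0.82, spread = 0.45, labels = c("O1", "Oz", "O2"))
  )
  tabs <- lapply(rows, function(r) {
    n <- length(r$labels)
    half <- r$spread * 0.92 * sqrt(max(1 - r$y^2, 0))
    x <- if (n == 1) 0 else seq(-half, half, length.out = n)
    tibble(channel = r$labels, x = x, y = r$y)
  })
  out <- dplyr::bind_rows(tabs)
  # inferior ring completions to reach the 64-channel cap
  out <- dplyr::bind_rows(out, tibble(
    channel = c("P9", "P10", "Iz"),
    x = c(-0.97, 0.97, 0),
    y = c(-0.48, -0.48, -0.97)
  ))
  if (!is.null(channels)) {
    missing <- setdiff(channels, out$channel)
    if (length(missing) > 0) {
      abort(paste0("Unknown montage channel(s): ",
                   paste(missing, collapse = ", ")))
    }
    out <- out[match(channels, out$channel), ]
  }
  out
}

#' Compact 16-channel montage subset
#'
#' A scalp-covering subset of [montage_64()] (frontal through occipital
#' midline and lateral sites) used for simulation studies where the full
#' 64-channel cap is unnecessarily expensive.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
montage_16 <- function() {
  montage_64(c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4",
               "P3", "Pz", "P4", "O1", "Oz", "O2", "T7", "T8"))
}
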