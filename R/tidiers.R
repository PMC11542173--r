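#' Tidy a spectral fit
#'
#' One row per model parameter: the aperiodic offset and exponent followed
#' by each peak's center frequency, height and bandwidth.
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.spectral_fit <- function(x, ...) {
  rows <- tibble(
    term = c("offset", "exponent"),
    estimate = c(x$offset, x$exponent),
    unit = c("log10(uV^2/Hz)", "")
  )
  if (nrow(x$peaks) > 0) {
    pk <- x$peaks
    rows <- dplyr::bind_rows(rows, tibble(
      term = c(sprintf("peak%d_cf", seq_len(nrow(pk))),
               sprintf("peak%d_pw", seq_len(nrow(pk))),
               sprintf("peak%d_bw", seq_len(nrow(pk)))),
      estimate = c(pk$cf, pk$pw, pk$bw),
      unit = rep(c("Hz", "log10(uV^2/Hz)", "Hz"), each = nrow(pk))
    ))
  }
  rows
}

#' Fit-level summary of a spectral fit
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `offset`, `exponent`, `n_peaks`, `r_squared`,
#'   `mean_abs_error`, `converged`.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble(offset = x$offset, exponent = x$exponent,
         n_peaks = nrow(x$peaks), r_squared = x$r_squared,
         mean_abs_error = x$mean_abs_error, converged = x$converged)
}

#' Tidy a cluster test
#'
#' One row per cluster (or the single unclustered summary row when no
#' channel crossed the forming threshold), with member channels joined by
#' `;`.
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return A tibble: `cluster`, `channels` (list-column), `n_channels`,
#'   `sign`, `mass`, `t_max`, `d_mean`, `p_value`, `significant`.
#' @export
tidy.cluster_test <- function(x, ...) {
  dplyr::select(x$clusters, "cluster", "channels", "n_channels", "sign",
                "mass", "t_max", "d_mean", "p_value", "significant")
}

#' Test-level summary of a cluster test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return A one-row tibble: design `kind`, numbers of channels, clusters
#'   and significant clusters, the smallest cluster p, the forming
#'   threshold, and the relabeling count.
#' @export
glance.cluster_test <- function(x, ...) {
  cl <- x$clusters
  has <- !all(is.na(cl$cluster))
  tibble(
    kind = x$kind,
    n_channels = nrow(x$t_map),
    n_clusters = if (has) nrow(cl) else 0L,
    n_significant = sum(cl$significant),
    min_p = if (has) min(cl$p_value) else NA_real_,
    forming_threshold = x$forming_threshold,
    n_permutations = x$n_permutations,
    monte_carlo = x$monte_carlo
  )
}
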