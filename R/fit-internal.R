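# Matrix-based internals of the spectral parameterization. Peaks travel as
# a numeric matrix with columns (cf, pw, sd); tibbles appear only at the
# exported API edge — the fit is called hundreds of thousands of times in
# simulation studies.

peaks_empty <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("cf", "pw", "sd")))

gaussian_sum_mat <- function(freqs, pk) {
  out <- numeric(length(freqs))
  if (is.null(pk) || nrow(pk) == 0) return(out)
  for (k in seq_len(nrow(pk))) {
    out <- out + pk[k, 2] * exp(-(freqs - pk[k, 1])^2 / (2 * pk[k, 3]^2))
  }
  out
}

detect_peaks_impl <- function(freqs, flattened, settings) {
  sd_lim <- settings$peak_width_limits / 2
  resid <- flattened
  out <- matrix(0, nrow = settings$max_n_peaks, ncol = 3,
                dimnames = list(NULL, c("cf", "pw", "sd")))
  n_found <- 0L
  while (n_found < settings$max_n_peaks) {
    i_max <- which.max(resid)
    height <- resid[i_max]
    if (height < settings$min_peak_height ||
        height < settings$peak_threshold * sd(resid)) break
    cf <- freqs[i_max]
    half <- height / 2
    left <- which(resid[seq_len(i_max)] <= half)
    right <- which(resid[i_max:length(resid)] <= half)
    d_left <- if (length(left)) cf - freqs[max(left)] else NA_real_
    d_right <- if (length(right)) freqs[i_max + min(right) - 1] - cf else NA_real_
    # full width from both half-height crossings where available (robust
    # to a single noisy dip on one flank); doubled single side otherwise
    fwhm <- if (is.na(d_left) && is.na(d_right)) {
      2.355 * mean(sd_lim)
    } else if (is.na(d_left)) {
      2 * d_right
    } else if (is.na(d_right)) {
      2 * d_left
    } else {
      d_left + d_right
    }
    g_sd <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    n_found <- n_found + 1L
    out[n_found, ] <- c(cf, height, g_sd)
    resid <- resid - height * exp(-(freqs - cf)^2 / (2 * g_sd^2))
  }
  out[seq_len(n_found), , drop = FALSE]
}

prune_guesses_impl <- function(g, settings) {
  if (nrow(g) == 0) return(g)
  fr <- settings$fit_range
  keep <- g[, 1] - settings$edge_sd_limit * g[, 3] >= fr[1] &
    g[, 1] + settings$edge_sd_limit * g[, 3] <= fr[2]
  g <- g[keep, , drop = FALSE]
  if (nrow(g) <= 1) return(g)
  g <- g[order(g[, 1]), , drop = FALSE]
  drop <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(g) - 1)) {
    if (drop[i]) next
    j <- i + 1
    if (abs(g[j, 1] - g[i, 1]) < settings$overlap_sd_limit *
        max(g[i, 3], g[j, 3])) {
      if (g[i, 2] >= g[j, 2]) drop[j] <- TRUE else drop[i] <- TRUE
    }
  }
  g[!drop, , drop = FALSE]
}

peak_bounds <- function(n_pk, settings) {
  sd_lim <- settings$peak_width_limits / 2
  fr <- settings$fit_range
  list(lower = rep(c(fr[1], 0, sd_lim[1]), n_pk),
       upper = rep(c(fr[2], Inf, sd_lim[2]), n_pk))
}

peak_model_par <- function(par, freqs, n_pk) {
  m <- numeric(length(freqs))
  for (k in seq_len(n_pk)) {
    i <- 3 * (k - 1)
    m <- m + par[i + 2] * exp(-(freqs - par[i + 1])^2 / (2 * par[i + 3]^2))
  }
  m
}

peak_jacobian_par <- function(par, freqs, n_pk) {
  J <- matrix(0, nrow = length(freqs), ncol = 3 * n_pk)
  for (k in seq_len(n_pk)) {
    i <- 3 * (k - 1)
    cf <- par[i + 1]; pw <- par[i + 2]; s <- par[i + 3]
    E <- exp(-(freqs - cf)^2 / (2 * s^2))
    J[, i + 1] <- pw * E * (freqs - cf) / s^2
    J[, i + 2] <- E
    J[, i + 3] <- pw * E * (freqs - cf)^2 / s^3
  }
  J
}

# Bounded LM fit of the multi-Gaussian model to a flattened spectrum.
fit_peaks_impl <- function(freqs, flattened, guesses, settings,
                           prune = TRUE) {
  if (prune) guesses <- prune_guesses_impl(guesses, settings)
  if (nrow(guesses) == 0) {
    return(list(peaks = peaks_empty, converged = TRUE))
  }
  n_pk <- nrow(guesses)
  b <- peak_bounds(n_pk, settings)
  par0 <- pmin(pmax(as.vector(t(guesses)), b$lower), b$upper)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, lower = b$lower, upper = b$upper,
      fn = function(p) flattened - peak_model_par(p, freqs, n_pk),
      jac = function(p) -peak_jacobian_par(p, freqs, n_pk),
      control = minpack.lm::nls.lm.control(maxiter = 30, ptol = 1e-8,
                                           ftol = 1e-8))),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  fellback <- is.null(fit) || fit$info == 0
  par <- if (!fellback) fit$par else par0
  pk <- matrix(par, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("cf", "pw", "sd")))
  pk <- pk[pk[, 2] > 0, , drop = FALSE]
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  list(peaks = pk, converged = converged, fellback = fellback)
}

# Variable-projection polish: refit the peaks against the *raw* log10
# spectrum with the aperiodic line profiled out (for any peak parameters,
# the optimal offset/exponent is the OLS solution, so the residual lives
# in the orthogonal complement of the aperiodic design). Converges to the
# exact joint least-squares optimum of aperiodic + peaks.
polish_fit_impl <- function(freqs, y, pk, settings) {
  n_pk <- nrow(pk)
  if (n_pk == 0) return(list(peaks = pk, converged = TRUE))
  X <- cbind(1, -log10(freqs))
  XtXi <- solve(crossprod(X))
  proj_out <- function(v) v - X %*% (XtXi %*% crossprod(X, v))
  yp <- proj_out(y)
  b <- peak_bounds(n_pk, settings)
  par0 <- pmin(pmax(as.vector(t(pk)), b$lower), b$upper)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, lower = b$lower, upper = b$upper,
      fn = function(p) yp - proj_out(peak_model_par(p, freqs, n_pk)),
      jac = function(p) -proj_out(peak_jacobian_par(p, freqs, n_pk)),
      control = minpack.lm::nls.lm.control(maxiter = 60, ptol = 1e-10,
                                           ftol = 1e-10))),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  par <- if (!is.null(fit) && fit$info != 0) fit$par else par0
  pk <- matrix(par, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("cf", "pw", "sd")))
  pk <- pk[pk[, 2] > 0, , drop = FALSE]
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  list(peaks = pk, converged = converged)
}

# Full decomposition of one spectrum; returns a bare list.
fit_spectrum_impl <- function(freqs, pw, settings) {
  y <- log10(pw)
  lx <- log10(freqs)
  ap <- fit_aperiodic_impl(lx, y, settings, robust = TRUE)
  flat <- y - (ap[1] - ap[2] * lx)
  guesses <- detect_peaks_impl(freqs, flat, settings)
  pf <- fit_peaks_impl(freqs, flat, guesses, settings)
  pk <- pf$peaks
  ap <- aperiodic_ols(lx, y - gaussian_sum_mat(freqs, pk))
  if (settings$refine_iter > 0 && nrow(pk) > 0) {
    pol <- polish_fit_impl(freqs, y, pk, settings)
    if (pol$converged) {
      pk <- pol$peaks
      ap <- aperiodic_ols(lx, y - gaussian_sum_mat(freqs, pk))
    }
  }
  model <- ap[1] - ap[2] * lx + gaussian_sum_mat(freqs, pk)
  resid <- y - model
  mae <- mean(abs(resid))
  r2 <- if (sd(y) == 0 || sd(model) == 0) {
    if (mae < 1e-8) 1 else 0
  } else {
    min(max(stats::cor(y, model)^2, 0), 1)
  }
  list(offset = ap[1], exponent = ap[2], peaks = pk, r_squared = r2,
       mean_abs_error = mae, y = y, model = model,
       converged = pf$converged)
}

fit_aperiodic_impl <- function(lx, y, settings, robust = TRUE) {
  co <- aperiodic_ols(lx, y)
  if (robust) {
    res <- y - (co[1] - co[2] * lx)
    # mask points sitting above the initial fit: threshold at a low
    # quantile of the zero-clipped residuals, so oscillatory bumps do not
    # tilt the second pass
    thr <- quantile(pmax(res, 0), settings$robust_percentile,
                    names = FALSE)
    keep <- res <= thr
    if (sum(keep) >= 2 && length(unique(lx[keep])) >= 2) {
      co <- aperiodic_ols(lx[keep], y[keep])
    }
  }
  co
}
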