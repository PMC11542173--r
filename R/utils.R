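# internal helpers shared across modules

# Evaluate a sum of Gaussians over frequencies. `peaks` is a data frame with
# columns cf (Hz), pw (log10 power), sd (Hz).
gaussian_sum <- function(freqs, peaks) {
  out <- numeric(length(freqs))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  for (k in seq_len(nrow(peaks))) {
    out <- out + peaks$pw[k] *
      exp(-(freqs - peaks$cf[k])^2 / (2 * peaks$sd[k]^2))
  }
  out
}

# Aperiodic model in log10 space: offset - exponent * log10(f).
aperiodic_model <- function(freqs, offset, exponent) {
  offset - exponent * log10(freqs)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483629L
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (strict && x <= min) abort(paste0("`", name, "` must be > ", min, "."))
  if (!strict && x < min) abort(paste0("`", name, "` must be >= ", min, "."))
  invisible(x)
}
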