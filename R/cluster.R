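#' Per-electrode t statistics
#'
#' Computes one t value per channel: a pooled-variance independent-samples
#' t between two groups, or a one-sample t on per-subject difference
#' scores for paired designs. A channel with zero variance yields an
#' infinite t (with a warning) when the effect is nonzero, and 0 when both
#' effect and variance are zero.
#'
#' @param data For `kind = "independent"`: a tibble with columns `subject`,
#'   `channel`, `value`, `group` (exactly two levels). For
#'   `kind = "paired"`: `subject`, `channel`, `value` where `value` is the
#'   per-subject difference score.
#' @param kind `"independent"` or `"paired"`.
#' @param groups For independent designs, optional length-2 character
#'   vector fixing the comparison direction (`groups[1] - groups[2]`).
#' @return A tibble `channel`, `t`, `df`.
#' @export
electrode_t_map <- function(data, kind = c("independent", "paired"),
                            groups = NULL) {
  kind <- match.arg(kind)
  mats <- contrast_matrices(data, kind, groups)
  tv <- if (kind == "independent") {
    t_independent(mats$A, mats$B)
  } else {
    t_paired(mats$D)
  }
  tibble(channel = mats$channels, t = tv$t, df = tv$df)
}

# Wide subjects x channels matrices from the tidy contrast data.
contrast_matrices <- function(data, kind, groups = NULL) {
  wide <- tidyr::pivot_wider(
    data, id_cols = dplyr::any_of(c("subject", "group")),
    names_from = "channel", values_from = "value")
  channels <- setdiff(names(wide), c("subject", "group"))
  M <- as.matrix(wide[, channels, drop = FALSE])
  if (kind == "independent") {
    if (!"group" %in% names(wide)) {
      abort("Independent designs need a `group` column.")
    }
    gl <- groups %||% sort(unique(wide$group))
    if (length(gl) != 2) abort("Independent designs need exactly two groups.")
    list(A = M[wide$group == gl[1], , drop = FALSE],
         B = M[wide$group == gl[2], , drop = FALSE],
         channels = channels, groups = gl)
  } else {
    list(D = M, channels = channels)
  }
}

t_independent <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 subjects.")
  m1 <- colMeans(A); m2 <- colMeans(B)
  ss1 <- colSums(A^2) - n1 * m1^2
  ss2 <- colSums(B^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  zero <- se == 0
  if (any(zero)) {
    warn("Zero pooled variance at some channel(s); t set to 0 or +/-Inf.")
    t[zero] <- ifelse(m1[zero] == m2[zero], 0,
                      sign(m1[zero] - m2[zero]) * Inf)
  }
  list(t = unname(t), df = n1 + n2 - 2)
}

t_paired <- function(D) {
  n <- nrow(D)
  if (n < 2) abort("Paired designs need at least 2 subjects.")
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  se <- s / sqrt(n)
  t <- m / se
  zero <- se == 0
  if (any(zero)) {
    warn("Zero variance at some channel(s); t set to 0 or +/-Inf.")
    t[zero] <- ifelse(m[zero] == 0, 0, sign(m[zero]) * Inf)
  }
  list(t = unname(t), df = n - 1)
}

#' Per-electrode Cohen's d
#'
#' Independent designs use the pooled-SD standardized mean difference;
#' paired designs use mean difference over the SD of the differences.
#' Channels with zero SD yield `NA` with a warning.
#'
#' @inheritParams electrode_t_map
#' @return A tibble `channel`, `d`.
#' @export
cohens_d <- function(data, kind = c("independent", "paired"),
                     groups = NULL) {
  kind <- match.arg(kind)
  mats <- contrast_matrices(data, kind, groups)
  if (kind == "independent") {
    A <- mats$A; B <- mats$B
    n1 <- nrow(A); n2 <- nrow(B)
    sp <- sqrt(((n1 - 1) * apply(A, 2, var) +
                  (n2 - 1) * apply(B, 2, var)) / (n1 + n2 - 2))
    d <- (colMeans(A) - colMeans(B)) / sp
  } else {
    s <- apply(mats$D, 2, sd)
    d <- colMeans(mats$D) / s
    sp <- s
  }
  if (any(sp == 0)) {
    warn("Zero SD at some channel(s); Cohen's d undefined there.")
    d[sp == 0] <- NA_real_
  }
  tibble(channel = mats$channels, d = unname(d))
}

#' Form clusters from a t map
#'
#' Thresholds the t map at the two-tailed critical value for
#' `cluster_alpha`, then partitions supra-threshold channels into connected
#' components of same-signed t. Cluster mass is the sum of member t values.
#'
#' @param t_map Tibble `channel`, `t` from [electrode_t_map()].
#' @param adjacency An [build_adjacency()] graph over the same channels.
#' @param df Degrees of freedom for the forming threshold.
#' @param cluster_alpha Two-tailed forming threshold (default 0.05).
#' @return A tibble with one row per cluster: `cluster`, `channels`
#'   (list-column), `sign`, `mass`, `n_channels`.
#' @export
form_clusters <- function(t_map, adjacency, df, cluster_alpha = 0.05) {
  tv <- align_t(t_map, adjacency)
  thr <- qt(1 - cluster_alpha / 2, df)
  comp <- cluster_components(tv, thr, adjacency$neighbors)
  if (length(comp) == 0) {
    return(tibble(cluster = integer(0), channels = list(), sign = integer(0),
                  mass = numeric(0), n_channels = integer(0)))
  }
  tibble(
    cluster = seq_along(comp),
    channels = lapply(comp, function(i) adjacency$channels[i]),
    sign = vapply(comp, function(i) as.integer(sign(tv[i[1]])), 1L),
    mass = vapply(comp, function(i) sum(tv[i]), 0),
    n_channels = lengths(comp)
  )
}

align_t <- function(t_map, adjacency) {
  i <- match(adjacency$channels, t_map$channel)
  if (anyNA(i)) abort("t map does not cover the adjacency channels.")
  t_map$t[i]
}

# Connected components of same-signed supra-threshold channels, ordered by
# descending |mass|. Infinite t values are capped so masses stay finite.
cluster_components <- function(tv, thr, neighbors) {
  tv[is.infinite(tv)] <- sign(tv[is.infinite(tv)]) * 1e6
  supra <- which(abs(tv) > thr)
  if (length(supra) == 0) return(list())
  in_supra <- logical(length(tv)); in_supra[supra] <- TRUE
  seen <- logical(length(tv))
  comps <- list()
  for (s in supra) {
    if (seen[s]) next
    sgn <- sign(tv[s])
    members <- integer(0)
    stack <- s; seen[s] <- TRUE
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      members <- c(members, v)
      for (u in neighbors[[v]]) {
        if (!seen[u] && in_supra[u] && sign(tv[u]) == sgn) {
          seen[u] <- TRUE; stack <- c(stack, u)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps[order(vapply(comps, function(i) -abs(sum(tv[i])), 0))]
}

# max |cluster mass| of one t vector (fast path for permutation nulls)
max_cluster_mass <- function(tv, thr, neighbors) {
  if (!any(abs(tv) > thr)) return(0)
  comp <- cluster_components(tv, thr, neighbors)
  if (length(comp) == 0) return(0)
  tv[is.infinite(tv)] <- sign(tv[is.infinite(tv)]) * 1e6
  max(vapply(comp, function(i) abs(sum(tv[i])), 0))
}

#' Cluster-based permutation test over electrodes
#'
#' Nonparametric familywise-error-controlling test of a per-electrode
#' measure. Observed clusters are formed at the two-tailed
#' `cluster_alpha` threshold; the null distribution of the maximum
#' absolute cluster mass is built by `n_permutations` random relabelings —
#' group-label permutations for independent designs, whole-subject sign
#' flips of the difference vectors for paired designs (channels are never
#' permuted within a subject). Cluster p values use the
#' `(1 + b) / (n_permutations + 1)` convention. When no cluster forms, the
#' result carries one unclustered summary row with the maximum |t| and the
#' Cohen's d averaged over all channels.
#'
#' @inheritParams electrode_t_map
#' @param adjacency An [build_adjacency()] graph.
#' @param n_permutations Number of Monte Carlo permutations (default
#'   10000).
#' @param cluster_alpha Forming threshold and significance level.
#' @param seed Optional integer; fixes the permutation stream without
#'   touching the caller's RNG.
#' @return An object of class `cluster_test`; see [tidy.cluster_test()].
#' @export
permutation_cluster_test <- function(data,
                                     adjacency,
                                     kind = c("independent", "paired"),
                                     groups = NULL,
                                     n_permutations = 10000,
                                     cluster_alpha = 0.05,
                                     seed = NULL) {
  kind <- match.arg(kind)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  mats <- contrast_matrices(data, kind, groups)
  run <- function() {
    if (kind == "independent") {
      null_independent(mats$A, mats$B, adjacency, cluster_alpha,
                       n_permutations)
    } else {
      null_paired(mats$D, adjacency, cluster_alpha, n_permutations)
    }
  }
  nul <- if (is.null(seed)) run() else with_seed(seed, run())
  finalize_cluster_test(mats, kind, adjacency, cluster_alpha, nul,
                        mc = TRUE, data = data, groups = groups,
                        n_permutations = n_permutations, seed = seed)
}

#' Exhaustive-enumeration cluster test
#'
#' Identical construction to [permutation_cluster_test()] but enumerating
#' the complete relabeling space — all `2^n` sign-flip assignments for
#' paired designs, all `choose(n, n1)` group partitions for independent
#' designs — giving exact p values (`p = b / n_total`, identity included).
#' Serves as the oracle for the Monte Carlo procedure on small designs.
#'
#' @inheritParams permutation_cluster_test
#' @param max_space Refuse enumeration beyond this many relabelings.
#' @return An object of class `cluster_test`.
#' @export
exhaustive_cluster_test <- function(data,
                                    adjacency,
                                    kind = c("independent", "paired"),
                                    groups = NULL,
                                    cluster_alpha = 0.05,
                                    max_space = 2^20) {
  kind <- match.arg(kind)
  mats <- contrast_matrices(data, kind, groups)
  if (kind == "paired") {
    n <- nrow(mats$D)
    if (2^n > max_space) {
      abort("Permutation space too large to enumerate; use permutation_cluster_test().")
    }
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    nul <- null_paired(mats$D, adjacency, cluster_alpha,
                       n_perm = NULL, signs = signs)
  } else {
    n1 <- nrow(mats$A); n <- n1 + nrow(mats$B)
    if (choose(n, n1) > max_space) {
      abort("Permutation space too large to enumerate; use permutation_cluster_test().")
    }
    sel <- combn(n, n1)
    nul <- null_independent(mats$A, mats$B, adjacency, cluster_alpha,
                            n_perm = NULL, selections = sel)
  }
  finalize_cluster_test(mats, kind, adjacency, cluster_alpha, nul,
                        mc = FALSE, data = data, groups = groups,
                        n_permutations = length(nul$null_max), seed = NULL)
}

# Null max-|mass| distribution for independent designs. `selections`
# (optional, one column per relabeling) enumerates group-1 memberships.
null_independent <- function(A, B, adjacency, cluster_alpha, n_perm,
                             selections = NULL) {
  n1 <- nrow(A); n2 <- nrow(B); n <- n1 + n2
  Y <- rbind(A, B)
  Y2 <- Y^2
  df <- n - 2
  thr <- qt(1 - cluster_alpha / 2, df)
  S <- colSums(Y); Q <- colSums(Y2)
  if (is.null(selections)) {
    selections <- replicate(n_perm, sample.int(n, n1))
  }
  n_tot <- ncol(selections)
  # group-1 membership as a 0/1 matrix: all permutation sums in two
  # matrix products
  P <- matrix(0, nrow = n_tot, ncol = n)
  P[cbind(rep(seq_len(n_tot), each = n1), as.vector(selections))] <- 1
  S1 <- P %*% Y
  Q1 <- P %*% Y2
  M1 <- S1 / n1
  M2 <- sweep(-S1, 2, S, `+`) / n2
  SP2 <- (Q1 - n1 * M1^2 + sweep(-Q1, 2, Q, `+`) - n2 * M2^2) / df
  SE <- sqrt(pmax(SP2, 0) * (1 / n1 + 1 / n2))
  TV <- (M1 - M2) / SE
  bad <- !is.finite(TV)
  if (any(bad)) TV[bad] <- ifelse((M1 - M2)[bad] == 0, 0,
                                  sign((M1 - M2)[bad]) * 1e6)
  null_max <- numeric(n_tot)
  for (p in seq_len(n_tot)) {
    null_max[p] <- max_cluster_mass(TV[p, ], thr, adjacency$neighbors)
  }
  obs <- t_independent(A, B)
  list(t = obs$t, df = df, thr = thr, null_max = null_max)
}

t_from_sums <- function(S1, Q1, S2, Q2, n1, n2) {
  m1 <- S1 / n1; m2 <- S2 / n2
  sp2 <- (Q1 - n1 * m1^2 + Q2 - n2 * m2^2) / (n1 + n2 - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- ifelse(m1[!is.finite(t)] == m2[!is.finite(t)], 0,
                             sign((m1 - m2)[!is.finite(t)]) * 1e6)
  t
}

# Null max-|mass| distribution for paired designs via whole-subject sign
# flips; `signs` (optional, one row per relabeling) enumerates them.
null_paired <- function(D, adjacency, cluster_alpha, n_perm,
                        signs = NULL) {
  n <- nrow(D)
  df <- n - 1
  thr <- qt(1 - cluster_alpha / 2, df)
  if (is.null(signs)) {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
  }
  sums <- signs %*% D                      # n_perm x channels
  Q <- colSums(D^2)
  n_tot <- nrow(signs)
  M <- sums / n
  S2 <- sweep(-n * M^2, 2, Q, `+`) / (n - 1)
  TV <- M / sqrt(pmax(S2, 0) / n)
  bad <- !is.finite(TV)
  if (any(bad)) TV[bad] <- ifelse(M[bad] == 0, 0, sign(M[bad]) * 1e6)
  null_max <- numeric(n_tot)
  for (p in seq_len(n_tot)) {
    null_max[p] <- max_cluster_mass(TV[p, ], thr, adjacency$neighbors)
  }
  obs <- t_paired(D)
  list(t = obs$t, df = df, thr = thr, null_max = null_max)
}

finalize_cluster_test <- function(mats, kind, adjacency, cluster_alpha,
                                  nul, mc, data, groups, n_permutations,
                                  seed) {
  t_map <- tibble(channel = mats$channels, t = nul$t, df = nul$df)
  d_map <- cohens_d(data, kind, groups)
  clusters <- form_clusters(t_map, adjacency, nul$df, cluster_alpha)
  if (nrow(clusters) > 0) {
    p <- vapply(clusters$mass, function(m) {
      b <- sum(nul$null_max >= abs(m))
      if (mc) (1 + b) / (length(nul$null_max) + 1)
      else b / length(nul$null_max)
    }, 0)
    stats <- lapply(clusters$channels, function(chs) {
      i <- match(chs, t_map$channel)
      tt <- unname(t_map$t[i])
      c(t_max = tt[which.max(abs(tt))],
        d_mean = mean(d_map$d[match(chs, d_map$channel)]))
    })
    clusters$p_value <- p
    clusters$t_max <- vapply(stats, `[[`, 0, "t_max")
    clusters$d_mean <- vapply(stats, `[[`, 0, "d_mean")
    clusters$significant <- clusters$p_value < cluster_alpha
  } else {
    clusters <- tibble(
      cluster = NA_integer_, channels = list(t_map$channel),
      sign = NA_integer_, mass = NA_real_, n_channels = NA_integer_,
      p_value = NA_real_,
      t_max = t_map$t[which.max(abs(t_map$t))],
      d_mean = mean(d_map$d, na.rm = TRUE),
      significant = FALSE)
  }
  structure(
    list(clusters = clusters, t_map = t_map, d_map = d_map,
         null_max = nul$null_max, kind = kind, groups = groups,
         cluster_alpha = cluster_alpha, forming_threshold = nul$thr,
         n_permutations = n_permutations, monte_carlo = mc, seed = seed,
         adjacency = adjacency),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s design, %d channels, %s %d relabelings\n",
              x$kind, nrow(x$t_map),
              if (x$monte_carlo) "Monte Carlo" else "exhaustive",
              x$n_permutations))
  cl <- x$clusters
  if (all(is.na(cl$cluster))) {
    cat(sprintf("  no clusters formed; max |t| = %.3f, mean d = %.3f\n",
                abs(cl$t_max[1]), cl$d_mean[1]))
  } else {
    for (i in seq_len(nrow(cl))) {
      cat(sprintf("  cluster %d (%+d): %d channels, mass %.2f, t_max %.2f, d_mean %.2f, p %s\n",
                  cl$cluster[i], cl$sign[i], cl$n_channels[i], cl$mass[i],
                  cl$t_max[i], cl$d_mean[i], format.pval(cl$p_value[i])))
    }
  }
  invisible(x)
}

#' Build contrast data from a measure table
#'
#' Extracts the tidy per-subject data for one of the standard contrasts:
#' `OFF_vs_CTL` and `ON_vs_CTL` (independent, patient session vs.
#' controls), `ON_vs_OFF` (paired within patients), `EC_vs_EO` (paired
#' within subjects of one group/session).
#'
#' @param measures Long measure table from [measure_table()].
#' @param measure One of `"offset"`, `"exponent"`, `"total_alpha"`,
#'   `"total_beta"`, `"param_alpha"`, `"param_beta"`.
#' @param pair Contrast name (see description).
#' @param condition `"EC"` or `"EO"` (ignored for `EC_vs_EO`).
#' @param group For `EC_vs_EO`: which group's subjects to difference;
#'   with a `session` for PD (`"OFF"`/`"ON"`).
#' @param session For `EC_vs_EO` within PD subjects.
#' @return A list with `data`, `kind`, `groups` ready for
#'   [permutation_cluster_test()].
#' @export
build_contrast <- function(measures, measure,
                           pair = c("OFF_vs_CTL", "ON_vs_CTL", "ON_vs_OFF",
                                    "EC_vs_EO"),
                           condition = "EC", group = "CTL",
                           session = NA_character_) {
  pair <- match.arg(pair)
  mm <- dplyr::filter(measures, .data$measure == !!measure)
  if (nrow(mm) == 0) abort(paste0("Unknown measure `", measure, "`."))
  if (pair %in% c("OFF_vs_CTL", "ON_vs_CTL")) {
    ses <- if (pair == "OFF_vs_CTL") "OFF" else "ON"
    dat <- dplyr::filter(mm, .data$condition == !!condition,
                         (.data$group == "PD" & .data$session %in% ses) |
                           .data$group == "CTL")
    list(data = dplyr::select(dat, "subject", "group", "channel", "value"),
         kind = "independent", groups = c("PD", "CTL"))
  } else if (pair == "ON_vs_OFF") {
    dat <- dplyr::filter(mm, .data$condition == !!condition,
                         .data$group == "PD")
    wide <- tidyr::pivot_wider(
      dplyr::select(dat, "subject", "channel", "session", "value"),
      names_from = "session", values_from = "value")
    dat <- dplyr::transmute(wide, subject = .data$subject,
                            channel = .data$channel,
                            value = .data$ON - .data$OFF)
    list(data = dat, kind = "paired", groups = NULL)
  } else {
    dat <- dplyr::filter(mm, .data$group == !!group)
    if (!is.na(session)) {
      dat <- dplyr::filter(dat, .data$session %in% !!session)
    }
    wide <- tidyr::pivot_wider(
      dplyr::select(dat, "subject", "channel", "condition", "value"),
      names_from = "condition", values_from = "value")
    dat <- dplyr::transmute(wide, subject = .data$subject,
                            channel = .data$channel,
                            value = .data$EC - .data$EO)
    list(data = dat, kind = "paired", groups = NULL)
  }
}
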