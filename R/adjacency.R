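#' Electrode adjacency graph from montage coordinates
#'
#' Builds the spatial neighborhood used by the cluster-based permutation
#' tests: a Delaunay triangulation of the 2D-projected electrode positions
#' (Bowyer-Watson insertion, deterministic for a fixed row order), with
#' edges longer than `prune_factor` times the median edge length removed.
#' Collinear layouts fall back to a nearest-neighbor chain. The resulting
#' graph must be connected.
#'
#' @param montage A tibble with columns `channel`, `x`, `y` (at least 3
#'   rows).
#' @param prune_factor Edge-length pruning multiplier (default 1.5).
#' @return An object of class `adjacency`: channel labels, coordinates, an
#'   edge tibble (`from`, `to`, labels), and a neighbor index list.
#' @examples
#' adj <- build_adjacency(montage_16())
#' adj
#' @export
build_adjacency <- function(montage, prune_factor = 1.5) {
  if (nrow(montage) < 3) abort("Need at least 3 electrode positions.")
  pts <- cbind(montage$x, montage$y)
  if (anyDuplicated(pts) > 0) abort("Electrode positions must be distinct.")
  edges <- if (is_collinear(pts)) {
    chain_edges(pts)
  } else {
    delaunay_edges(pts)
  }
  # prune implausibly long edges (spanning the head)
  len <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                         pts[edges[, 2], , drop = FALSE])^2))
  keep <- len <= prune_factor * median(len)
  edges <- edges[keep, , drop = FALSE]
  nb <- neighbor_list(edges, nrow(pts))
  if (!is_connected(nb)) {
    abort("Adjacency graph is disconnected after pruning; increase `prune_factor`.")
  }
  structure(
    list(channels = montage$channel,
         coords = tibble(channel = montage$channel,
                         x = montage$x, y = montage$y),
         edges = tibble(from = edges[, 1], to = edges[, 2],
                        from_channel = montage$channel[edges[, 1]],
                        to_channel = montage$channel[edges[, 2]]),
         neighbors = nb),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<adjacency> %d channels, %d edges; degree %d-%d (median %g)\n",
              length(x$channels), nrow(x$edges), min(deg), max(deg),
              median(deg)))
  invisible(x)
}

is_collinear <- function(pts, tol = 1e-9) {
  ctr <- sweep(pts, 2, colMeans(pts))
  s <- svd(ctr, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

# Nearest-neighbor chain for degenerate (collinear) layouts: order points
# along the principal axis and connect consecutive ones.
chain_edges <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  ax <- svd(ctr, nu = 0, nv = 2)$v[, 1]
  ord <- order(ctr %*% ax)
  cbind(ord[-length(ord)], ord[-1])
}

# Bowyer-Watson Delaunay triangulation; returns a 2-column matrix of
# vertex-index pairs (from < to), sorted for determinism.
delaunay_edges <- function(pts) {
  n <- nrow(pts)
  # super-triangle comfortably containing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  sup <- rbind(c(cx - 20 * span, cy - 10 * span),
               c(cx + 20 * span, cy - 10 * span),
               c(cx, cy + 20 * span))
  P <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(circumcircle(P, tris[[1]]))
  for (i in seq_len(n)) {
    bad <- which(vapply(circ, function(cc) {
      (P[i, 1] - cc[1])^2 + (P[i, 2] - cc[2])^2 < cc[3] * (1 - 1e-12)
    }, TRUE))
    # boundary of the cavity: edges of bad triangles not shared by two
    edge_tab <- do.call(rbind, lapply(bad, function(ti) {
      tr <- tris[[ti]]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edge_tab[, 1], edge_tab[, 2])
    boundary <- edge_tab[key %in% names(which(table(key) == 1)), ,
                         drop = FALSE]
    tris[bad] <- NULL; circ[bad] <- NULL
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], i)
      tris[[length(tris) + 1]] <- tr
      circ[[length(circ) + 1]] <- circumcircle(P, tr)
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), TRUE)
  tris <- tris[keep]
  if (length(tris) == 0) abort("Triangulation failed (degenerate layout).")
  edges <- unique(do.call(rbind, lapply(tris, function(tr) {
    rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
  })))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# circumcenter (x, y) and squared radius of triangle `tr` over points P
circumcircle <- function(P, tr) {
  a <- P[tr[1], ]; b <- P[tr[2], ]; c <- P[tr[3], ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(c(Inf, Inf, Inf))
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) +
           (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) +
           (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

neighbor_list <- function(edges, n) {
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) sort(unique(v)))
}

is_connected <- function(nb) {
  n <- length(nb)
  seen <- logical(n)
  stack <- 1L; seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (u in nb[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
  }
  all(seen)
}
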