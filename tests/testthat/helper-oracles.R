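# Independent brute-force oracles used to check the geometry layer.

# Owner index of every probe on an n_probe x n_probe pixel grid over the
# window, by exhaustive nearest-center scan (ties -> lowest index, as
# which.min does).  Pixel centers avoid probes exactly on bisectors that
# align with the grid.
raster_owner <- function(centers, window, n_probe = 200L) {
  xs <- window$xmin + (seq_len(n_probe) - 0.5) / n_probe *
    (window$xmax - window$xmin)
  ys <- window$ymin + (seq_len(n_probe) - 0.5) / n_probe *
    (window$ymax - window$ymin)
  owner <- matrix(0L, n_probe, n_probe)
  for (r in seq_len(n_probe)) {
    dx2 <- outer(centers[, 1L], xs, function(c, x) (c - x)^2)
    dy2 <- (centers[, 2L] - ys[r])^2
    owner[r, ] <- apply(dx2 + dy2, 2L, which.min)
  }
  owner  # rows indexed by y, columns by x
}

# Unordered pairs of owners that touch over an orthogonal pixel edge.
raster_adjacency <- function(owner) {
  pairs <- rbind(
    cbind(as.vector(owner[, -ncol(owner)]), as.vector(owner[, -1L])),
    cbind(as.vector(owner[-nrow(owner), ]), as.vector(owner[-1L, ])))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  unique(t(apply(pairs, 1L, sort)))
}

edge_set_string <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(pmin(edges[, 1L], edges[, 2L]),
             pmax(edges[, 1L], edges[, 2L]), sep = "-"))
}

# Ray-casting point-in-polygon (boundary treated as inside via tolerance).
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # on-edge check
    d <- abs((xj - xi) * (yi - py) - (xi - px) * (yj - yi)) /
      max(sqrt((xj - xi)^2 + (yj - yi)^2), tol)
    if (d < tol &&
        px >= min(xi, xj) - tol && px <= max(xi, xj) + tol &&
        py >= min(yi, yj) - tol && py <= max(yi, yj) + tol) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Transform rows of `base` so the sample mean/covariance are exactly
# `target_mu` / `target_sigma` (used to build fixtures with known
# ellipse parameters).
with_exact_moments <- function(base, target_mu, target_sigma) {
  ctr <- scale(base, center = TRUE, scale = FALSE)
  w <- ctr %*% solve(chol(stats::cov(ctr)))
  sweep(w %*% chol(target_sigma), 2L, target_mu, "+")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# rebuild the tessellation graph the plotting path uses, independently
resolve_table_fixture <- function(d, ...) {
  ps <- point_set(as.matrix(d[, c("x", "y")]))
  tess <- tessellate(ps)
  list(points = ps, tess = tess, graph = neighbor_graph(ps, tess))
}

# minimum Euclidean distance between two point sets
proxy_min_dist <- function(a, b) {
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)))
}

window_area_of <- function(tess) {
  (tess$window$xmax - tess$window$xmin) *
    (tess$window$ymax - tess$window$ymin)
}
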