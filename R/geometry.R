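# Bounded Voronoi tessellation of a 2-D point set, built by clipping each
# cell (an intersection of half-planes) against a rectangular window, plus
# the Delaunay-dual neighbor graph read off the shared cell boundaries.

#' Construct a validated 2-D point set
#'
#' Bundles an \code{n x 2} coordinate matrix with per-point case identifiers
#' and validates the geometric preconditions of the tessellation: at least
#' one point, all coordinates finite, and no two points coincident within a
#' relative tolerance of \code{1e-9} of the coordinate range (duplicate
#' centers make cell ownership undefined, so they are a hard error naming
#' the offending cases rather than something silently averaged away).
#'
#' @param coords Numeric matrix or data frame with two columns (x, y).
#' @param case_ids Optional character vector of point identifiers; defaults
#'   to the row number as a string.
#' @return An object of class \code{point_set} with elements \code{coords},
#'   \code{case_ids} and \code{n}.
#' @examples
#' ps <- point_set(cbind(c(0, 1, 2), c(0, 1, 0)))
#' ps$n
#' @export
point_set <- function(coords, case_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2) {
    stop("`coords` must have exactly 2 columns, got ", ncol(coords),
         call. = FALSE)
  }
  n <- nrow(coords)
  if (n < 1) stop("`coords` must contain at least one point", call. = FALSE)
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))
    stop("non-finite coordinates in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (is.null(case_ids)) {
    case_ids <- as.character(seq_len(n))
  } else {
    case_ids <- as.character(case_ids)
    if (length(case_ids) != n) {
      stop("`case_ids` length (", length(case_ids),
           ") does not match number of points (", n, ")", call. = FALSE)
    }
  }
  scale <- max(diff(range(coords[, 1L])), diff(range(coords[, 2L])), 1)
  tol <- 1e-9 * scale
  if (n >= 2L) {
    d <- stats::dist(coords)
    if (any(d < tol)) {
      pr <- which(as.matrix(d) < tol & upper.tri(matrix(0, n, n)),
                  arr.ind = TRUE)
      ids <- unique(case_ids[as.vector(pr)])
      stop("duplicate points (coincident within tolerance): case ids ",
           paste(utils::head(ids, 10L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(coords = coords, case_ids = case_ids, n = n),
            class = "point_set")
}

as_point_set <- function(x) {
  if (inherits(x, "point_set")) x else point_set(x)
}

#' Rectangular tessellation window around a point set
#'
#' The tessellation is computed over a finite rectangular domain: the
#' bounding box of the points expanded by \code{margin_frac} of each axis
#' range per side.  A degenerate axis (zero range) is expanded by 1.0 in
#' absolute units so the window always has positive area.
#'
#' @param points A \code{point_set} (or coercible coordinate matrix).
#' @param margin_frac Non-negative expansion fraction per side (default
#'   0.05, the framing used for all plots).
#' @return An object of class \code{voronoi_window} with fields
#'   \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax}.
#' @examples
#' compute_window(point_set(rbind(c(0, 0), c(10, 10))), 0.05)
#' @export
compute_window <- function(points, margin_frac = 0.05) {
  points <- as_point_set(points)
  if (!is.numeric(margin_frac) || length(margin_frac) != 1L ||
      !is.finite(margin_frac) || margin_frac < 0) {
    stop("`margin_frac` must be a single non-negative number", call. = FALSE)
  }
  xr <- range(points$coords[, 1L])
  yr <- range(points$coords[, 2L])
  dx <- diff(xr)
  dy <- diff(yr)
  mx <- if (dx > 0) margin_frac * dx else 1.0
  my <- if (dy > 0) margin_frac * dy else 1.0
  structure(list(xmin = xr[1L] - mx, xmax = xr[2L] + mx,
                 ymin = yr[1L] - my, ymax = yr[2L] + my),
            class = "voronoi_window")
}

window_diag <- function(w) {
  sqrt((w$xmax - w$xmin)^2 + (w$ymax - w$ymin)^2)
}

window_area <- function(w) {
  (w$xmax - w$xmin) * (w$ymax - w$ymin)
}

window_polygon <- function(w) {
  # counter-clockwise rectangle
  cbind(x = c(w$xmin, w$xmax, w$xmax, w$xmin),
        y = c(w$ymin, w$ymin, w$ymax, w$ymax))
}

in_window <- function(w, x, y) {
  x >= w$xmin & x <= w$xmax & y >= w$ymin & y <= w$ymax
}

# Sutherland-Hodgman clip of a convex polygon against the half-plane
# a1*x + a2*y <= b.  Returns NULL when the intersection is empty.
clip_halfplane <- function(poly, a1, a2, b, eps) {
  nv <- nrow(poly)
  s <- a1 * poly[, 1L] + a2 * poly[, 2L] - b
  if (all(s <= eps)) return(poly)
  if (all(s >= -eps)) return(NULL)
  keep <- s <= eps
  outx <- numeric(nv + 2L)
  outy <- numeric(nv + 2L)
  m <- 0L
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    if (keep[k]) {
      m <- m + 1L
      outx[m] <- poly[k, 1L]
      outy[m] <- poly[k, 2L]
    }
    if (xor(keep[k], keep[k2])) {
      t <- s[k] / (s[k] - s[k2])
      m <- m + 1L
      outx[m] <- poly[k, 1L] + t * (poly[k2, 1L] - poly[k, 1L])
      outy[m] <- poly[k, 2L] + t * (poly[k2, 2L] - poly[k, 2L])
    }
  }
  if (m < 3L) return(NULL)
  cbind(outx[seq_len(m)], outy[seq_len(m)])
}

# Drop consecutive near-duplicate vertices introduced by clipping.
dedupe_vertices <- function(poly, eps) {
  nv <- nrow(poly)
  if (nv < 2L) return(poly)
  nxt <- c(seq_len(nv)[-1L], 1L)
  d2 <- (poly[, 1L] - poly[nxt, 1L])^2 + (poly[, 2L] - poly[nxt, 2L])^2
  keep <- d2 > eps^2
  if (all(keep)) poly else poly[keep, , drop = FALSE]
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  nxt <- c(seq_along(x)[-1L], 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Bounded Voronoi tessellation of a point set
#'
#' Partitions the rectangular window into one convex cell per point, the
#' cell of point i holding every location of the window closer (in
#' Euclidean distance) to point i than to any other point.  Each cell is
#' the intersection of the window with the half-planes bounded by the
#' perpendicular bisectors towards the other points; unbounded Voronoi
#' regions are thereby clipped exactly.  Bisectors are applied in order of
#' increasing center distance and clipping stops once the remaining
#' centers are provably too far to cut the current cell, so the cost is
#' close to linear in the number of actual neighbors.
#'
#' @param points A \code{point_set} (or coordinate matrix).
#' @param window A \code{voronoi_window}; defaults to
#'   \code{compute_window(points, margin_frac)}.  Must contain all points.
#' @param margin_frac Window margin used when \code{window} is NULL.
#' @return An object of class \code{voronoi_tessellation}: list with
#'   \code{cells} (list of counter-clockwise vertex matrices),
#'   \code{points}, \code{window}.
#' @examples
#' tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
#' length(tess$cells)
#' @export
tessellate <- function(points, window = NULL, margin_frac = 0.05) {
  points <- as_point_set(points)
  if (is.null(window)) window <- compute_window(points, margin_frac)
  if (!inherits(window, "voronoi_window")) {
    stop("`window` must be a voronoi_window", call. = FALSE)
  }
  xy <- points$coords
  if (!all(in_window(window, xy[, 1L], xy[, 2L]))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  n <- points$n
  diag_len <- window_diag(window)
  eps <- 1e-12 * diag_len
  rect <- window_polygon(window)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    if (n == 1L) {
      cells[[1L]] <- rect
      break
    }
    pi_ <- xy[i, ]
    d2 <- (xy[, 1L] - pi_[1L])^2 + (xy[, 2L] - pi_[2L])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- rect
    for (j in ord) {
      # prune: the bisector to j cannot cut the cell when half the center
      # distance exceeds the farthest current vertex
      vmax2 <- max((poly[, 1L] - pi_[1L])^2 + (poly[, 2L] - pi_[2L])^2)
      if (d2[j] > 4 * vmax2) break
      a1 <- xy[j, 1L] - pi_[1L]
      a2 <- xy[j, 2L] - pi_[2L]
      b <- a1 * (pi_[1L] + xy[j, 1L]) / 2 + a2 * (pi_[2L] + xy[j, 2L]) / 2
      poly <- clip_halfplane(poly, a1, a2, b, eps)
      if (is.null(poly)) {
        stop("empty Voronoi cell for case id ", points$case_ids[i],
             " (coincident points?)", call. = FALSE)
      }
    }
    cells[[i]] <- dedupe_vertices(poly, eps)
  }
  structure(list(cells = cells, points = points, window = window),
            class = "voronoi_tessellation")
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat("Voronoi tessellation:", x$points$n, "cells over window [",
      format(x$window$xmin), ",", format(x$window$xmax), "] x [",
      format(x$window$ymin), ",", format(x$window$ymax), "]\n")
  invisible(x)
}

#' Delaunay-dual neighbor graph of a tessellation
#'
#' Two points are neighbors exactly when their clipped Voronoi cells share
#' a boundary segment of positive length (longer than \code{1e-9} times
#' the window diagonal) -- the Delaunay-dual relation restricted to the
#' window.  Cocircular configurations whose dual edge has zero length
#' (e.g. the diagonals of four points on a square) are therefore not
#' adjacent.  Each cell edge is attributed by testing which rival center
#' is equidistant from the edge midpoint.
#'
#' @param points The \code{point_set} the tessellation was built from
#'   (optional; taken from \code{tess} when omitted).
#' @param tess A \code{voronoi_tessellation}.
#' @return An object of class \code{neighbor_graph}: list with \code{n},
#'   \code{edges} (two-column matrix of index pairs, i < j),
#'   \code{adjacency} (list of neighbor index vectors), \code{case_ids}.
#' @examples
#' tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
#' neighbor_graph(tess = tess)$edges
#' @export
neighbor_graph <- function(points = NULL, tess) {
  if (missing(tess) && inherits(points, "voronoi_tessellation")) {
    tess <- points
    points <- NULL
  }
  if (!inherits(tess, "voronoi_tessellation")) {
    stop("`tess` must be a voronoi_tessellation", call. = FALSE)
  }
  if (is.null(points)) points <- tess$points
  points <- as_point_set(points)
  if (!isTRUE(all.equal(points$coords, tess$points$coords,
                        check.attributes = FALSE))) {
    stop("`tess` was not derived from `points`", call. = FALSE)
  }
  xy <- points$coords
  n <- points$n
  diag_len <- window_diag(tess$window)
  min_len <- 1e-9 * diag_len
  eps_eq <- 1e-7 * diag_len
  pairs <- matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    seen <- new.env(hash = TRUE)
    for (i in seq_len(n)) {
      poly <- tess$cells[[i]]
      nv <- nrow(poly)
      nxt <- c(seq_len(nv)[-1L], 1L)
      len <- sqrt((poly[, 1L] - poly[nxt, 1L])^2 +
                  (poly[, 2L] - poly[nxt, 2L])^2)
      mx <- (poly[, 1L] + poly[nxt, 1L]) / 2
      my <- (poly[, 2L] + poly[nxt, 2L]) / 2
      for (k in which(len > min_len)) {
        d <- sqrt((xy[, 1L] - mx[k])^2 + (xy[, 2L] - my[k])^2)
        di <- d[i]
        d[i] <- Inf
        j <- which.min(d)
        if (d[j] - di <= eps_eq) {
          key <- paste0(min(i, j), "_", max(i, j))
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            pairs <- rbind(pairs, c(min(i, j), max(i, j)))
          }
        }
      }
    }
  }
  adjacency <- rep(list(integer(0)), n)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      adjacency[[i]] <- c(adjacency[[i]], j)
      adjacency[[j]] <- c(adjacency[[j]], i)
    }
    adjacency <- lapply(adjacency, sort)
    ord <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(n = n, edges = pairs, adjacency = adjacency,
                 case_ids = points$case_ids),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("Voronoi neighbor graph:", x$n, "points,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Locate the owning cell of a query point
#'
#' Returns the index of the nearest center (the cell the query point
#' belongs to); ties on the boundary between cells resolve to the lowest
#' index.
#'
#' @param tess A \code{voronoi_tessellation}.
#' @param x Numeric length-2 query point, inside the window.
#' @return Integer point index.
#' @examples
#' tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
#' locate(tess, c(0.4, 0.1))
#' @export
locate <- function(tess, x) {
  if (!inherits(tess, "voronoi_tessellation")) {
    stop("`tess` must be a voronoi_tessellation", call. = FALSE)
  }
  x <- as.numeric(x)
  if (length(x) != 2L || !all(is.finite(x))) {
    stop("`x` must be a finite length-2 numeric point", call. = FALSE)
  }
  w <- tess$window
  if (!in_window(w, x[1L], x[2L])) {
    stop("query point lies outside the tessellation window", call. = FALSE)
  }
  xy <- tess$points$coords
  d2 <- (xy[, 1L] - x[1L])^2 + (xy[, 2L] - x[2L])^2
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

#' Areas of the clipped Voronoi cells
#'
#' @param tess A \code{voronoi_tessellation}.
#' @return Numeric vector of polygon areas; they sum to the window area.
#' @export
cell_areas <- function(tess) {
  if (!inherits(tess, "voronoi_tessellation")) {
    stop("`tess` must be a voronoi_tessellation", call. = FALSE)
  }
  vapply(tess$cells, polygon_area, numeric(1))
}
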