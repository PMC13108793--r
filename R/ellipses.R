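# Per-group bivariate confidence ellipses: the set of plane points whose
# squared Mahalanobis distance from the group mean is at most the
# chi-squared (df = 2) quantile for the chosen level.

#' Chi-squared threshold for a bivariate confidence ellipse
#'
#' The quantile of the chi-squared distribution with two degrees of
#' freedom at the given level; for df = 2 this equals
#' \code{-2 * log(1 - level)}.
#'
#' @param level Confidence level in (0, 1).
#' @return The threshold c of the ellipse inequality.
#' @examples
#' chi2_threshold(0.95)  # 5.9915
#' @export
chi2_threshold <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  stats::qchisq(level, df = 2)
}

#' Fit a confidence ellipse to a group of 2-D points
#'
#' Centers the ellipse at the sample mean with shape given by the sample
#' covariance (divisor n - 1); the semi-axes are \code{sqrt(c * lambda_k)}
#' along the covariance eigenvectors.  By default this is a data ellipse
#' (a region for observations); \code{type = "mean"} scales the covariance
#' by 1/n to cover the group mean instead.
#'
#' Groups with fewer than 3 points or a singular covariance (e.g.
#' collinear points) yield a warning and \code{NULL} so that plotting can
#' proceed without the ellipse.
#'
#' @param points An \code{n x 2} coordinate matrix (or \code{point_set}).
#' @param level Confidence level, default 0.95.
#' @param group Optional group label stored in the result.
#' @param type \code{"data"} (default) or \code{"mean"}.
#' @return An \code{ellipse_spec} (list with \code{group}, \code{mean},
#'   \code{cov}, \code{level}, \code{threshold}) or \code{NULL}.
#' @examples
#' xy <- cbind(rnorm(50), rnorm(50))
#' spec <- fit_ellipse(xy, 0.95)
#' @export
fit_ellipse <- function(points, level = 0.95, group = NULL,
                        type = c("data", "mean")) {
  type <- match.arg(type)
  if (inherits(points, "point_set")) points <- points$coords
  xy <- as.matrix(points)
  if (ncol(xy) != 2L) stop("`points` must have two columns", call. = FALSE)
  n <- nrow(xy)
  if (n < 3L) {
    warning("group ", if (!is.null(group)) paste0("'", group, "' "),
            "has fewer than 3 points; ellipse omitted", call. = FALSE)
    return(NULL)
  }
  mu <- colMeans(xy)
  sigma <- stats::cov(xy)
  if (type == "mean") sigma <- sigma / n
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(sigma))
  if (scale == 0 || min(ev) <= 1e-12 * scale) {
    warning("group ", if (!is.null(group)) paste0("'", group, "' "),
            "has a singular covariance (collinear points?); ellipse omitted",
            call. = FALSE)
    return(NULL)
  }
  structure(list(group = group, mean = mu, cov = sigma, level = level,
                 threshold = chi2_threshold(level), type = type),
            class = "ellipse_spec")
}

#' Test whether a point lies inside a confidence ellipse
#'
#' True exactly when the squared Mahalanobis distance of \code{x} from the
#' ellipse mean is at most the threshold (the region is closed, so
#' boundary points are inside).
#'
#' @param spec An \code{ellipse_spec}.
#' @param x Length-2 point, or an \code{n x 2} matrix of points.
#' @return Logical scalar or vector.
#' @export
in_ellipse <- function(spec, x) {
  stopifnot(inherits(spec, "ellipse_spec"))
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 2L)
  d2 <- stats::mahalanobis(x, center = spec$mean, cov = spec$cov)
  unname(d2 <= spec$threshold)
}

#' Sample the boundary polygon of a confidence ellipse
#'
#' Vertices are \code{mu + sqrt(c) * S \%*\% (cos t, sin t)} with S a
#' symmetric square root of the covariance, at \code{n_vertices} uniform
#' angles; every vertex has squared Mahalanobis distance exactly c.
#'
#' @param spec An \code{ellipse_spec}.
#' @param n_vertices Number of boundary vertices (at least 8; default 100).
#' @return An \code{n_vertices x 2} matrix forming a closed ring (the
#'   first vertex follows the last).
#' @export
ellipse_polygon <- function(spec, n_vertices = 100L) {
  stopifnot(inherits(spec, "ellipse_spec"))
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 8L) stop("`n_vertices` must be at least 8", call. = FALSE)
  e <- eigen(spec$cov, symmetric = TRUE)
  sqrt_sigma <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  circ <- rbind(cos(theta), sin(theta))
  ring <- t(spec$mean + sqrt(spec$threshold) * sqrt_sigma %*% circ)
  colnames(ring) <- c("x", "y")
  ring
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat("Confidence ellipse",
      if (!is.null(x$group)) paste0("for group '", x$group, "'"),
      sprintf("(level %.3g, threshold %.4f, %s type)\n",
              x$level, x$threshold, x$type))
  invisible(x)
}
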