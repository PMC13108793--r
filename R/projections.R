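# Minimal, deterministic 2-D projections (PCA and NIPALS PLS-DA) plus the
# two clustering routines used in the Lsun demonstration.  The supervised
# projection is kept self-contained so that score plots and island counts
# are reproducible bit-for-bit from a seed.

autoscale_matrix <- function(X, scale. = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in the feature table", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  if (scale.) {
    sds <- apply(X, 2L, stats::sd)
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      nm <- colnames(X)[zero]
      if (is.null(nm)) nm <- which(zero)
      stop("zero-variance column(s) under autoscaling: ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  Xc
}

# flip component signs so the largest-|loading| entry of each column is
# positive; applied consistently to loadings and scores
apply_sign_rule <- function(scores, loadings) {
  for (k in seq_len(ncol(loadings))) {
    imax <- which.max(abs(loadings[, k]))
    if (loadings[imax, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

projection_result <- function(scores, loadings, method, axis_names,
                              explained = NULL) {
  colnames(scores) <- axis_names
  structure(list(scores = scores, loadings = loadings, method = method,
                 axis_names = axis_names, explained = explained),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(toupper(x$method), "projection:", nrow(x$scores), "scores on axes",
      paste(x$axis_names, collapse = ", "))
  if (!is.null(x$explained)) {
    cat(sprintf(" (%.1f%%, %.1f%% variance)", 100 * x$explained[1L],
                100 * x$explained[2L]))
  }
  cat("\n")
  invisible(x)
}

#' First two principal component scores
#'
#' Column-centers (and optionally autoscales) the feature table and
#' returns the first two principal component scores and loadings via the
#' singular value decomposition.  Signs are fixed so that each loading
#' column's largest-magnitude entry is positive, making the projection
#' deterministic.
#'
#' @param X Numeric matrix or data frame, n rows (cases) by p features;
#'   n >= 3, p >= 2, no missing values.
#' @param autoscale Divide each centered column by its standard deviation
#'   (default FALSE); zero-variance columns are an error then.
#' @return A \code{projection_result} with \code{scores} (n x 2),
#'   \code{loadings} (p x 2) and \code{explained} (variance fractions).
#' @examples
#' pca_scores(matrix(rnorm(60), 20, 3))
#' @export
pca_scores <- function(X, autoscale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 feature columns", call. = FALSE)
  Xs <- autoscale_matrix(X, scale. = autoscale)
  sv <- svd(Xs, nu = 2L, nv = 2L)
  scores <- sv$u %*% diag(sv$d[1:2], 2L, 2L)
  fixed <- apply_sign_rule(scores, sv$v)
  explained <- (sv$d[1:2]^2) / sum(sv$d^2)
  projection_result(fixed$scores, fixed$loadings, "pca",
                    c("PC1", "PC2"), explained)
}

#' Two-component PLS-DA scores
#'
#' Partial least squares discriminant analysis: the class factor is coded
#' as a centered one-hot indicator matrix Y, the feature table is
#' autoscaled, and components are extracted by the iterative NIPALS PLS2
#' algorithm with deflation of both blocks.  The X-scores of the first
#' two components form the projection plane.  The same sign rule as PCA
#' (largest-|weight| entry positive) makes the result deterministic.
#'
#' @param X Numeric matrix or data frame, n x p, no missing values.
#' @param labels Class labels (vector, factor, or \code{class_labels});
#'   at least 2 classes with at least 2 members each.
#' @param n_comp Number of components (default 2).
#' @param tol Relative convergence tolerance on the score vector
#'   (default 1e-9).
#' @param max_iter Maximum NIPALS iterations per component (default 500);
#'   exceeding it is an error naming the component.
#' @return A \code{projection_result}; \code{explained} holds the X-block
#'   variance fractions captured by each component.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
#' plsda_scores(X, rep(c("a", "b"), each = 10))
#' @export
plsda_scores <- function(X, labels, n_comp = 2L, tol = 1e-9,
                         max_iter = 500L) {
  X <- as.matrix(X)
  labels <- as_class_labels(labels)$primary
  if (length(labels) != nrow(X)) {
    stop("labels length does not match rows of X", call. = FALSE)
  }
  if (nlevels(labels) < 2L) {
    stop("PLS-DA needs at least 2 classes", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 members", call. = FALSE)
  }
  Xs <- autoscale_matrix(X, scale. = TRUE)
  Y <- stats::model.matrix(~ labels - 1)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  n <- nrow(Xs); p <- ncol(Xs)
  n_comp <- min(as.integer(n_comp), p)
  ssx_total <- sum(Xs^2)
  Xd <- Xs; Yd <- Yc
  scores <- matrix(0, n, n_comp)
  weights <- matrix(0, p, n_comp)
  xload <- matrix(0, p, n_comp)
  explained <- numeric(n_comp)
  for (h in seq_len(n_comp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      wn <- sqrt(sum(w^2))
      if (wn < .Machine$double.eps) {
        stop("PLS-DA component ", h, " degenerated (zero weight vector)",
             call. = FALSE)
      }
      w <- w / wn
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      u <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) {
        converged <- TRUE
        break
      }
      t_old <- tt
    }
    if (!converged) {
      stop("PLS-DA component ", h, " did not converge in ", max_iter,
           " iterations", call. = FALSE)
    }
    imax <- which.max(abs(w))
    if (w[imax] < 0) {
      w <- -w
      tt <- -tt
    }
    pl <- drop(crossprod(Xd, tt)) / sum(tt^2)
    ql <- drop(crossprod(Yd, tt)) / sum(tt^2)
    explained[h] <- sum(tt^2) * sum(pl^2) / ssx_total
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, ql)
    scores[, h] <- tt
    weights[, h] <- w
    xload[, h] <- pl
  }
  res <- projection_result(scores, weights, "plsda",
                           paste("Component", seq_len(n_comp)), explained)
  res$x_loadings <- xload
  res
}

#' k-means clustering labels (Lloyd's algorithm, multiple restarts)
#'
#' Thin seeded wrapper around \code{\link[stats]{kmeans}} returning the
#' best-inertia assignment over \code{n_restarts} random starts, as used
#' in the Lsun clustering demonstration (k = 3, 100 restarts).
#'
#' @param X Numeric matrix of coordinates.
#' @param k Number of clusters, 1 <= k <= n.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Optional integer seed for reproducible restarts.
#' @return Factor of cluster labels ("1" ... "k").
#' @export
cluster_kmeans <- function(X, k, n_restarts = 100L, seed = NULL) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > nrow(X)) {
    stop("`k` (", k, ") exceeds the number of points (", nrow(X), ")",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (k == 1L) return(factor(rep(1L, nrow(X))))
  fit <- stats::kmeans(X, centers = k, nstart = n_restarts,
                       iter.max = 100L)
  factor(fit$cluster)
}

#' Single-linkage hierarchical clustering labels
#'
#' Agglomerative clustering merging by the minimum inter-cluster point
#' distance, cut to k clusters -- the method that recovers the chained,
#' non-spherical classes of the Lsun benchmark where k-means fails.
#'
#' @param X Numeric matrix of coordinates.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Factor of cluster labels.
#' @export
cluster_single_linkage <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > nrow(X)) {
    stop("`k` (", k, ") exceeds the number of points (", nrow(X), ")",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(X), method = "single")
  factor(stats::cutree(hc, k = k))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
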