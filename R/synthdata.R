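# Seeded synthetic benchmark generators: a well-separated two-class
# dataset (with a label-switch variant), a three-class dataset with mixed
# effect sizes (with a permuted, non-significant variant), and an
# Lsun-style 2-D clustering problem.  All randomness funnels through the
# `seed` argument, and the global RNG state is restored afterwards, so a
# given seed reproduces a dataset bit-for-bit.

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

synthetic_dataset <- function(X, y, variant, seed, meta = list()) {
  structure(list(X = X, y = factor(y), variant = variant, seed = seed,
                 meta = meta),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset '", x$variant, "' (seed ", x$seed, "): ",
      nrow(x$X), " cases x ", ncol(x$X), " features; class counts: ",
      paste(sprintf("%s=%d", levels(x$y), table(x$y)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.synthetic_dataset <- function(x, ...) {
  cbind(as.data.frame(x$X), class = x$y)
}

feature_names <- c("A", "B", "C", "D", "E", "G", "H", "I", "J")

# class-bounded uniform around mu with jittered bounds: U(mu-1+u, mu+1+u),
# u ~ U(-0.25, 0.25) drawn once per class
runif_class_band <- function(n, mu) {
  u <- stats::runif(1L, -0.25, 0.25)
  stats::runif(n, mu - 1 + u, mu + 1 + u)
}

# weighted sampling from the integers 1..10 with class-tilted weights
# w propto position^class_index, plus N(0, 0.1) jitter
weighted_jittered <- function(n, class_index) {
  vals <- sample(1:10, n, replace = TRUE, prob = (1:10)^class_index)
  vals + stats::rnorm(n, 0, 0.1)
}

build_features <- function(sizes, mu, sigma, b_mean_fac, b_var_fac = 0.9,
                           b_sd_scale = rep(1, length(sizes))) {
  n <- sum(sizes)
  k <- length(sizes)
  cls <- rep(seq_len(k), sizes)
  A <- B <- E <- G <- numeric(n)
  C <- D <- numeric(n)
  for (i in seq_len(k)) {
    idx <- cls == i
    ni <- sizes[i]
    A[idx] <- stats::rnorm(ni, mu[i], sigma[i])
    B[idx] <- stats::rnorm(ni, b_mean_fac[i] * mu[i],
                           sqrt(b_var_fac) * b_sd_scale[i] * sigma[i])
    E[idx] <- runif_class_band(ni, mu[i])
    G[idx] <- runif_class_band(ni, mu[i])
    C[idx] <- weighted_jittered(ni, i)
    D[idx] <- weighted_jittered(ni, i)
  }
  H <- stats::runif(n, 0, 10)
  I <- 0.8 * H + 1 + stats::rnorm(n, 0, 0.3)
  J <- stats::rnorm(n, 0, 1)
  X <- data.frame(A = A, B = B, C = C, D = D, E = E, G = G,
                  H = H, I = I, J = J)
  list(X = X, cls = cls)
}

#' Generate the two-class synthetic benchmark
#'
#' Nine continuous features for n = 80 cases in two classes of 40.
#' Feature A is Normal with class means (4, 8) and unit standard
#' deviations; B uses scaled, cross-referenced parameters (mean 0.3*mu1 /
#' 0.5*mu2, variance 0.9*sigma^2), inverting the class relationship; E and
#' G are class-banded uniforms with jittered bounds; C and D come from
#' class-tilted weighted sampling of the integers 1..10 with Gaussian
#' jitter; H is a common Uniform(0, 10), I a jittered linear map of H, and
#' J pure standard-normal noise.  Classes are strongly separated on A (4
#' pooled standard deviations), so a supervised projection shows two clean
#' clouds.
#'
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A \code{synthetic_dataset} with fields \code{X} (80 x 9
#'   data frame, columns A, B, C, D, E, G, H, I, J), \code{y} (factor
#'   "C1"/"C2"), \code{variant}, \code{seed}.
#' @examples
#' ds <- gen_two_class(1)
#' table(ds$y)
#' @export
gen_two_class <- function(seed = 1L) {
  with_seed(seed, {
    sizes <- c(40L, 40L)
    mu <- c(4, 8)
    sigma <- c(1, 1)
    f <- build_features(sizes, mu, sigma, b_mean_fac = c(0.3, 0.5))
    synthetic_dataset(f$X, paste0("C", f$cls), "two_class", seed,
                      meta = list(sizes = sizes, mu = mu, sigma = sigma))
  })
}

#' Reassign labels of k cases per class to the opposite class
#'
#' Introduces controlled label noise into a two-class dataset: exactly
#' \code{k_per_class} cases per class, chosen uniformly at random, get the
#' opposite label while all features stay untouched.  Selection is
#' stratified by the dataset's labels as generated (stored at creation),
#' so applying the operation twice with the same seed toggles the same
#' cases and restores the original labels.  The flipped case indices are
#' recorded in \code{meta$flipped}.
#'
#' @param ds A two-class \code{synthetic_dataset}.
#' @param k_per_class Number of cases to flip per class (default 3).
#' @param seed Integer seed for the case selection.
#' @return The modified \code{synthetic_dataset} (variant
#'   \code{"two_class_switched"}).
#' @examples
#' ds <- gen_two_class(1)
#' dsf <- flip_labels(ds, 3, seed = 2)
#' sum(dsf$y != ds$y)  # 6
#' @export
flip_labels <- function(ds, k_per_class = 3L, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  y <- ds$y
  if (nlevels(y) != 2L) {
    stop("label flipping requires exactly two classes", call. = FALSE)
  }
  base <- ds$meta$base_labels
  if (is.null(base)) base <- y
  k_per_class <- as.integer(k_per_class)
  if (k_per_class < 0L) stop("`k_per_class` must be >= 0", call. = FALSE)
  if (k_per_class > min(table(base))) {
    stop("`k_per_class` (", k_per_class, ") exceeds the smallest class (",
         min(table(base)), ")", call. = FALSE)
  }
  lv <- levels(y)
  flipped <- with_seed(seed, {
    sort(c(sample(which(base == lv[1L]), k_per_class),
           sample(which(base == lv[2L]), k_per_class)))
  })
  y2 <- y
  y2[flipped] <- ifelse(y[flipped] == lv[1L], lv[2L], lv[1L])
  synthetic_dataset(ds$X, y2, "two_class_switched", seed,
                    meta = c(ds$meta[setdiff(names(ds$meta),
                                             c("flipped", "base_labels"))],
                             list(flipped = flipped, base_labels = base)))
}

#' Generate the three-class synthetic dataset
#'
#' Nine continuous features for n = 75 cases in classes of 20, 40 and 15.
#' Feature A is Normal with class means (4, 6, 8) and standard deviations
#' (2, 4, 3); B uses the scaled analogues (means 0.5*mu_i, variances
#' 0.9*sigma_i^2); E and G are class-banded uniforms; C and D weighted
#' jittered draws; H, I and J carry no class signal.  Group differences
#' are strong for E and G, moderate for A, and weak-to-moderate for B and
#' C/D, giving a mixed-effect-size testbed.
#'
#' @param seed Integer seed.
#' @return A \code{synthetic_dataset} (variant \code{"three_class"}).
#' @examples
#' table(gen_three_class(1)$y)
#' @export
gen_three_class <- function(seed = 1L) {
  with_seed(seed, {
    sizes <- c(20L, 40L, 15L)
    mu <- c(4, 6, 8)
    sigma <- c(2, 4, 3)
    f <- build_features(sizes, mu, sigma, b_mean_fac = c(0.5, 0.5, 0.5),
                        b_sd_scale = c(0.5, 0.5, 0.5))
    synthetic_dataset(f$X, paste0("C", f$cls), "three_class", seed,
                      meta = list(sizes = sizes, mu = mu, sigma = sigma))
  })
}

#' Permute a dataset's features until no class association remains
#'
#' Independently permutes each feature column, destroying the association
#' between features and class membership while preserving each column's
#' marginal distribution.  Columns whose Kruskal-Wallis p-value against
#' the (unchanged) class vector is still at or below \code{alpha} are
#' re-permuted, so the output is guaranteed to have all per-feature
#' p-values above \code{alpha}.
#'
#' @param ds A \code{synthetic_dataset} with at least 2 classes.
#' @param alpha Significance threshold to clear (default 0.05).
#' @param max_iter Maximum re-permutations per column (default 100).
#' @param seed Integer seed.
#' @return A \code{synthetic_dataset} (variant suffix
#'   \code{"_permuted"}).
#' @examples
#' dsp <- permute_to_nonsignificance(gen_three_class(1), seed = 2)
#' min(kruskal_wallis_screen(dsp))  # > 0.05
#' @export
permute_to_nonsignificance <- function(ds, alpha = 0.05, max_iter = 100L,
                                       seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (nlevels(ds$y) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  X <- ds$X
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        X[[j]] <- sample(ds$X[[j]])
        p <- stats::kruskal.test(X[[j]], ds$y)$p.value
        if (p > alpha) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("column ", colnames(X)[j], " still class-associated after ",
             max_iter, " permutations", call. = FALSE)
      }
    }
  })
  synthetic_dataset(X, ds$y, paste0(ds$variant, "_permuted"), seed,
                    meta = c(ds$meta, list(parent_seed = ds$seed,
                                           alpha = alpha)))
}

#' Generate an Lsun-style 2-D clustering benchmark
#'
#' 400 points in three well-separated classes with deliberately unequal
#' geometry: two axis-aligned uniform rectangles of different sizes
#' forming an "L" (150 points each) and one isotropic Gaussian disk
#' (100 points, truncated at 3 standard deviations).  Inter-class gaps
#' exceed 0.2 times the smallest rectangle side, so single-linkage
#' clustering recovers the classes exactly, while the elongated bricks
#' violate k-means' spherical-cluster assumption.
#'
#' @param seed Integer seed.
#' @return A \code{synthetic_dataset} with \code{X} holding columns
#'   \code{x}, \code{y} and classes "C1" (horizontal brick), "C2"
#'   (vertical brick), "C3" (disk).
#' @examples
#' table(gen_lsun(1)$y)
#' @export
gen_lsun <- function(seed = 1L) {
  with_seed(seed, {
    n1 <- 150L; n2 <- 150L; n3 <- 100L
    # horizontal brick: [0,6] x [0,0.8]; vertical brick: [0,0.8] x [1.3,4.3]
    x1 <- cbind(stats::runif(n1, 0, 6), stats::runif(n1, 0, 0.8))
    x2 <- cbind(stats::runif(n2, 0, 0.8), stats::runif(n2, 1.3, 4.3))
    # disk: isotropic Gaussian, sd 0.3, truncated at 3 sd, center (3.5, 3)
    ctr <- c(3.5, 3)
    pts <- matrix(numeric(0), 0L, 2L)
    while (nrow(pts) < n3) {
      cand <- matrix(stats::rnorm(2L * n3, 0, 0.3), ncol = 2L)
      cand <- cand[rowSums(cand^2) <= (3 * 0.3)^2, , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    x3 <- sweep(pts[seq_len(n3), , drop = FALSE], 2L, ctr, "+")
    X <- data.frame(x = c(x1[, 1L], x2[, 1L], x3[, 1L]),
                    y = c(x1[, 2L], x2[, 2L], x3[, 2L]))
    y <- rep(c("C1", "C2", "C3"), c(n1, n2, n3))
    synthetic_dataset(X, y, "lsun", seed,
                      meta = list(sizes = c(n1, n2, n3)))
  })
}

#' Per-feature Kruskal-Wallis screen against the class factor
#'
#' Runs the tie-corrected Kruskal-Wallis rank test of each feature column
#' against the class vector and returns the p-values.  A constant column
#' carries no rank information and yields p = 1 with a warning.
#'
#' @param ds A \code{synthetic_dataset}, or a data frame / matrix of
#'   features (then \code{y} must be given).
#' @param y Class labels when \code{ds} is a plain table.
#' @return Named numeric vector of p-values, one per feature.
#' @examples
#' kruskal_wallis_screen(gen_three_class(1))
#' @export
kruskal_wallis_screen <- function(ds, y = NULL) {
  if (inherits(ds, "synthetic_dataset")) {
    X <- ds$X
    y <- ds$y
  } else {
    X <- as.data.frame(ds)
    if (is.null(y)) stop("`y` labels are required", call. = FALSE)
    y <- factor(y)
  }
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  vapply(stats::setNames(seq_along(X), colnames(X)), function(j) {
    x <- X[[j]]
    if (length(unique(x)) == 1L) {
      warning("constant column '", colnames(X)[j], "': p set to 1",
              call. = FALSE)
      return(1)
    }
    stats::kruskal.test(x, y)$p.value
  }, numeric(1))
}

#' Write a synthetic dataset to CSV
#'
#' Plain comma-separated file with a header: the feature columns followed
#' by a \code{class} column.
#'
#' @param ds A \code{synthetic_dataset}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
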