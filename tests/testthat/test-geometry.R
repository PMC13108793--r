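test_that("the window is the margin-expanded bounding box", {
  w <- compute_window(point_set(rbind(c(0, 0), c(10, 10))), 0.05)
  expect_equal(unclass(w)[c("xmin", "xmax", "ymin", "ymax")],
               list(xmin = -0.5, xmax = 10.5, ymin = -0.5, ymax = 10.5))
  # degenerate ranges expand by 1.0 absolute
  w1 <- compute_window(point_set(matrix(c(3, 4), 1L)), 0.05)
  expect_equal(c(w1$xmin, w1$xmax, w1$ymin, w1$ymax), c(2, 4, 3, 5))
  w2 <- compute_window(point_set(rbind(c(0, 0), c(4, 0))), 0)
  expect_equal(c(w2$xmin, w2$xmax, w2$ymin, w2$ymax), c(0, 4, -1, 1))
  expect_error(compute_window(point_set(rbind(c(0, 0), c(1, 1))), -0.1),
               "non-negative")
})

test_that("point validation rejects bad input with informative errors", {
  expect_error(point_set(rbind(c(0, 0), c(0, Inf))), "non-finite")
  expect_error(point_set(rbind(c(1, 2), c(1, 2), c(3, 4)),
                         case_ids = c("a", "b", "c")),
               "duplicate points.*a, b")
  expect_error(point_set(matrix(0, 1L, 3L)), "2 columns")
})

test_that("two points split the window along the perpendicular bisector", {
  w <- structure(list(xmin = -1, xmax = 3, ymin = -1, ymax = 1),
                 class = "voronoi_window")
  tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))), w)
  # cells cover the window in two equal halves, boundary at x = 1
  expect_equal(cell_areas(tess), c(4, 4))
  expect_true(all(tess$cells[[1L]][, 1L] <= 1 + 1e-12))
  expect_true(all(tess$cells[[2L]][, 1L] >= 1 - 1e-12))
  expect_true(any(abs(tess$cells[[1L]][, 1L] - 1) < 1e-12))
})

test_that("a single point owns the whole window", {
  tess <- tessellate(point_set(matrix(c(3, 4), 1L)))
  expect_equal(cell_areas(tess), window_area_of(tess))
})

test_that("the 3x3 grid has a unit-square center cell", {
  grid <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  ps <- point_set(grid)
  w <- compute_window(ps, 0.25)  # margin 0.5 absolute on a range of 2
  tess <- tessellate(ps, w)
  ctr <- which(grid[, 1L] == 1 & grid[, 2L] == 1)
  cell <- tess$cells[[ctr]]
  expect_equal(nrow(cell), 4L)
  expect_equal(sort(cell[, 1L]), c(0.5, 0.5, 1.5, 1.5))
  expect_equal(sort(cell[, 2L]), c(0.5, 0.5, 1.5, 1.5))
})

test_that("adjacency matches the brute-force rasterization oracle", {
  fixtures <- list(
    grid3 = as.matrix(expand.grid(x = 0:2, y = 0:2)),
    square = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    collinear = rbind(c(0, 0), c(1, 0), c(2, 0)))
  for (nm in names(fixtures)) {
    ps <- point_set(fixtures[[nm]])
    tess <- tessellate(ps)
    g <- neighbor_graph(ps, tess)
    oracle <- raster_adjacency(raster_owner(ps$coords, tess$window, 200L))
    expect_equal(edge_set_string(g$edges), edge_set_string(oracle),
                 info = nm)
  }
})

test_that("cocircular square corners have no diagonal neighbors", {
  ps <- point_set(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- neighbor_graph(ps, tessellate(ps))
  expect_equal(edge_set_string(g$edges), c("1-2", "1-4", "2-3", "3-4"))
})

test_that("collinear strip cells only touch their immediate neighbors", {
  ps <- point_set(rbind(c(0, 0), c(1, 0), c(2, 0)))
  g <- neighbor_graph(ps, tessellate(ps))
  expect_equal(edge_set_string(g$edges), c("1-2", "2-3"))
})

test_that("locate agrees with the exhaustive nearest-center oracle", {
  set.seed(42)
  centers <- matrix(runif(100, 0, 10), ncol = 2L)
  ps <- point_set(centers)
  tess <- tessellate(ps)
  w <- tess$window
  qx <- runif(1000, w$xmin, w$xmax)
  qy <- runif(1000, w$ymin, w$ymax)
  got <- vapply(seq_along(qx),
                function(k) locate(tess, c(qx[k], qy[k])), integer(1))
  oracle <- vapply(seq_along(qx), function(k) {
    d2 <- (centers[, 1L] - qx[k])^2 + (centers[, 2L] - qy[k])^2
    which(d2 == min(d2))[1L]
  }, integer(1))
  expect_equal(got, oracle)
  # tie on the bisector resolves to the lowest index
  t2 <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
  expect_identical(locate(t2, c(1, 0)), 1L)
  expect_identical(locate(t2, c(0.4, 0.1)), 1L)
  expect_error(locate(t2, c(100, 0)), "outside")
})

test_that("cells partition the window and contain their sampled interiors", {
  set.seed(7)
  for (rep_ in 1:3) {
    centers <- matrix(rnorm(60), ncol = 2L)
    ps <- point_set(centers)
    tess <- tessellate(ps)
    expect_equal(sum(cell_areas(tess)), window_area_of(tess),
                 tolerance = 1e-6)
    # sampled probes: the located cell's polygon contains the probe
    w <- tess$window
    px <- runif(300, w$xmin, w$xmax)
    py <- runif(300, w$ymin, w$ymax)
    tol <- 1e-7 * sqrt((w$xmax - w$xmin)^2 + (w$ymax - w$ymin)^2)
    ok <- vapply(seq_along(px), function(k) {
      i <- locate(tess, c(px[k], py[k]))
      point_in_polygon(px[k], py[k], tess$cells[[i]], tol = tol)
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("the neighbor graph is invariant under rigid motions", {
  set.seed(11)
  centers <- matrix(rnorm(40), ncol = 2L)
  g0 <- neighbor_graph(tess = tessellate(point_set(centers)))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  moved <- centers %*% rot + matrix(c(5, -3), nrow(centers), 2L,
                                    byrow = TRUE)
  g1 <- neighbor_graph(tess = tessellate(point_set(moved)))
  expect_equal(edge_set_string(g0$edges), edge_set_string(g1$edges))
})

test_that("permuting point order permutes adjacency consistently", {
  set.seed(13)
  centers <- matrix(rnorm(40), ncol = 2L)
  ids <- sprintf("c%02d", seq_len(nrow(centers)))
  g0 <- neighbor_graph(tess = tessellate(point_set(centers, ids)))
  perm <- sample(nrow(centers))
  g1 <- neighbor_graph(tess = tessellate(point_set(centers[perm, ],
                                                   ids[perm])))
  by_id <- function(g) {
    sort(apply(g$edges, 1L, function(e) {
      paste(sort(g$case_ids[e]), collapse = "-")
    }))
  }
  expect_equal(by_id(g0), by_id(g1))
})

test_that("every point has a neighbor for n >= 2", {
  set.seed(17)
  for (n in c(2L, 5L, 30L)) {
    centers <- matrix(runif(2L * n), ncol = 2L)
    g <- neighbor_graph(tess = tessellate(point_set(centers)))
    expect_true(all(lengths(g$adjacency) >= 1L))
  }
})
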