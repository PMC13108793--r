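# Fixture: neighbor graph of a k x k integer grid (tessellation of a grid
# is the grid graph, established in test-geometry).
grid_graph <- function(k) {
  grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k)))
  ps <- point_set(grid)
  list(graph = neighbor_graph(tess = tessellate(ps)), coords = grid)
}

test_that("a uniformly labelled map has no islands", {
  gg <- grid_graph(3L)
  rep_ <- find_islands(gg$graph, rep("A", 9L))
  expect_equal(rep_$count, 0L)
  expect_equal(rep_$rate, 0)
})

test_that("two opposite-class points are both islands", {
  tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
  rep_ <- find_islands(neighbor_graph(tess = tess), c("A", "B"))
  expect_equal(rep_$islands, c(1L, 2L))
  expect_equal(rep_$count, 2L)
  expect_equal(rep_$rate, 1.0)
})

test_that("a foreign center in a 3x3 grid is the single island", {
  gg <- grid_graph(3L)
  lab <- rep("A", 9L)
  ctr <- which(gg$coords[, 1L] == 2 & gg$coords[, 2L] == 2)
  lab[ctr] <- "B"
  rep_ <- find_islands(gg$graph, lab)
  expect_equal(rep_$islands, ctr)
  expect_equal(rep_$rate, 1 / 9)
})

test_that("two adjacent foreign points deep inside a field are not islands", {
  # paired discordance: each of the two B points keeps one same-class
  # neighbor, so neither is an island
  gg <- grid_graph(5L)
  lab <- rep("A", 25L)
  b1 <- which(gg$coords[, 1L] == 3 & gg$coords[, 2L] == 3)
  b2 <- which(gg$coords[, 1L] == 4 & gg$coords[, 2L] == 3)
  lab[c(b1, b2)] <- "B"
  expect_true(b2 %in% gg$graph$adjacency[[b1]])
  expect_equal(find_islands(gg$graph, lab)$count, 0L)
  # the same two B points separated -> both islands again
  lab2 <- rep("A", 25L)
  b3 <- which(gg$coords[, 1L] == 2 & gg$coords[, 2L] == 2)
  b4 <- which(gg$coords[, 1L] == 4 & gg$coords[, 2L] == 4)
  lab2[c(b3, b4)] <- "B"
  expect_equal(sort(find_islands(gg$graph, lab2)$islands), sort(c(b3, b4)))
})

test_that("boundary-adjacent discordance is not an island", {
  # a point disagreeing with most but not all neighbors never qualifies
  gg <- grid_graph(3L)
  lab <- rep("A", 9L)
  ctr <- which(gg$coords[, 1L] == 2 & gg$coords[, 2L] == 2)
  lab[ctr] <- "B"
  one_nb <- gg$graph$adjacency[[ctr]][1L]
  lab[one_nb] <- "B"  # give the center one same-class neighbor
  rep_ <- find_islands(gg$graph, lab)
  expect_false(ctr %in% rep_$islands)
})

test_that("island status is equivariant under class relabelling", {
  set.seed(23)
  for (rep_i in 1:5) {
    centers <- matrix(rnorm(60), ncol = 2L)
    g <- neighbor_graph(tess = tessellate(point_set(centers)))
    lab <- sample(c("A", "B", "C"), 30L, replace = TRUE)
    swap <- c(A = "x", B = "y", C = "z")[lab]
    expect_equal(find_islands(g, lab)$islands,
                 find_islands(g, swap)$islands)
  }
})

test_that("adding a same-class neighbor can only remove island status", {
  set.seed(29)
  for (rep_i in 1:10) {
    centers <- matrix(rnorm(50), ncol = 2L)
    g <- neighbor_graph(tess = tessellate(point_set(centers)))
    lab <- sample(c("A", "B"), 25L, replace = TRUE)
    isl <- find_islands(g, lab)$islands
    if (!length(isl)) next
    i <- isl[1L]
    lab2 <- lab
    lab2[g$adjacency[[i]][1L]] <- lab[i]
    isl2 <- find_islands(g, lab2)$islands
    expect_false(i %in% isl2)
  }
})

test_that("which = alternative requires alternative labels", {
  g <- neighbor_graph(tess = tessellate(point_set(rbind(c(0, 0),
                                                        c(2, 0)))))
  expect_error(find_islands(g, class_labels(c("A", "B")), "alternative"),
               "alternative")
  labs <- class_labels(c("A", "B"), c("u", "u"))
  expect_equal(find_islands(g, labs, "alternative")$count, 0L)
  expect_equal(find_islands(g, labs, "alternative")$labels_used,
               "alternative")
})

test_that("missing labels are rejected", {
  expect_error(class_labels(c("A", NA, "B")), "missing")
  expect_error(class_labels(c("A", "", "B")), "missing")
})

test_that("rates render half-up to one decimal with a percent sign", {
  mk <- function(count, n) {
    structure(list(islands = seq_len(count), case_ids = character(count),
                   count = count, rate = count / n,
                   labels_used = "primary", n = n),
              class = "island_report")
  }
  expect_equal(island_rate_percent(mk(4L, 80L)), "5.0%")
  expect_equal(island_rate_percent(mk(0L, 13L)), "0.0%")
  expect_equal(island_rate_percent(mk(2L, 72L)), "2.8%")
  expect_equal(island_rate_percent(mk(3L, 107L)), "2.8%")
  expect_equal(subtitle_text(mk(4L, 72L)), "Voronoi islands: 4 (5.6%)")
  expect_equal(subtitle_text(mk(0L, 10L)), "Voronoi islands: 0 (0.0%)")
  expect_equal(subtitle_text(mk(3L, 107L)), "Voronoi islands: 3 (2.8%)")
})

test_that("the JSON export round-trips the report", {
  tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0)),
                               case_ids = c("p1", "p2")))
  rep_ <- find_islands(neighbor_graph(tess = tess), c("A", "B"))
  parsed <- jsonlite::fromJSON(island_report_json(rep_))
  expect_equal(parsed$n, 2L)
  expect_equal(parsed$count, 2L)
  expect_equal(parsed$rate, 1)
  expect_equal(parsed$islands, c("p1", "p2"))
  expect_equal(parsed$labels_used, "primary")
})

test_that("island status depends only on adjacency, not coordinates", {
  set.seed(31)
  centers <- matrix(rnorm(40), ncol = 2L)
  lab <- sample(c("A", "B"), 20L, replace = TRUE)
  g0 <- neighbor_graph(tess = tessellate(point_set(centers)))
  g1 <- neighbor_graph(tess = tessellate(point_set(centers * 3 + 10)))
  expect_equal(edge_set_string(g0$edges), edge_set_string(g1$edges))
  expect_equal(find_islands(g0, lab)$islands, find_islands(g1, lab)$islands)
})
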