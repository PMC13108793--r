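# Plot assembly: the three plot types (confidence ellipses, Voronoi
# tessellation, combined) with dual class coloring, optional case labels,
# and the island-count subtitle.  Figures are ggplot objects; parameter
# semantics follow the published function surface exactly, visual parity
# is approximate by design.

#' Default colorblind-safe palette
#'
#' The first \code{n_classes} colors of a fixed Okabe-Ito cycle (orange,
#' sky blue, bluish green, yellow, blue, vermillion, reddish purple,
#' gray), or a custom palette returned verbatim.  When more than 8 colors
#' are needed the cycle repeats with each further cycle lightened 30%
#' towards white, deterministically.
#'
#' @param n_classes Number of colors needed (>= 1).
#' @param custom Optional character vector of colors; must have at least
#'   \code{n_classes} entries.
#' @return Character vector of \code{n_classes} colors.
#' @examples
#' resolve_palette(3)
#' @export
resolve_palette <- function(n_classes, custom = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("`n_classes` must be >= 1", call. = FALSE)
  if (!is.null(custom)) {
    custom <- as.character(custom)
    if (length(custom) < n_classes) {
      stop("custom palette has ", length(custom), " colors but ",
           n_classes, " classes", call. = FALSE)
    }
    return(custom[seq_len(n_classes)])
  }
  base <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
            "#0072B2", "#D55E00", "#CC79A7", "#999999")
  k <- length(base)
  idx <- seq_len(n_classes)
  cycle <- (idx - 1L) %/% k          # 0 for the first 8, 1 for the next 8...
  cols <- base[((idx - 1L) %% k) + 1L]
  lighten <- function(col, amount) {
    rgb_ <- grDevices::col2rgb(col) / 255
    grDevices::rgb(t(rgb_ + (1 - rgb_) * amount))
  }
  ifelse(cycle == 0L, cols,
         mapply(lighten, cols, pmin(0.3 * cycle, 0.9)))
}

#' Place case labels with greedy overlap reduction
#'
#' Labels set to the empty string are suppressed; the remaining labels
#' are offset from their points, trying eight compass directions at
#' increasing radii until the candidate position is clear of previously
#' placed labels.  Purely cosmetic: the returned positions feed
#' \code{geom_text}.
#'
#' @param points \code{point_set} or coordinate matrix.
#' @param labels Character vector of label texts (empty string = hidden);
#'   defaults to the case ids.
#' @param which \code{"all"} or \code{"islands_only"}.
#' @param island_report Required when \code{which = "islands_only"}: only
#'   cases in the report keep their label.
#' @return Data frame with columns \code{x}, \code{y}, \code{label} (one
#'   row per rendered label; possibly zero rows).
#' @export
place_labels <- function(points, labels = NULL,
                         which = c("all", "islands_only"),
                         island_report = NULL) {
  which <- match.arg(which)
  points <- as_point_set(points)
  if (is.null(labels)) labels <- points$case_ids
  labels <- as.character(labels)
  if (length(labels) != points$n) {
    stop("labels length does not match number of points", call. = FALSE)
  }
  show <- labels != ""
  if (which == "islands_only") {
    if (is.null(island_report)) {
      stop("`island_report` is required for islands_only labeling",
           call. = FALSE)
    }
    show <- show & seq_len(points$n) %in% island_report$islands
  }
  idx <- which(show)
  if (!length(idx)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      label = character(0)))
  }
  xy <- points$coords
  rng <- max(diff(range(xy[, 1L])), diff(range(xy[, 2L])), 1)
  step <- 0.02 * rng
  angles <- pi / 2 - (0:7) * pi / 4   # start above the point
  placed <- matrix(numeric(0), 0L, 2L)
  out <- data.frame(x = numeric(length(idx)), y = numeric(length(idx)),
                    label = labels[idx])
  for (r in seq_along(idx)) {
    p <- xy[idx[r], ]
    pos <- p + c(0, step)
    for (mult in 1:4) {
      done <- FALSE
      for (a in angles) {
        cand <- p + mult * step * c(cos(a), sin(a))
        if (!nrow(placed) ||
            all(sqrt((placed[, 1L] - cand[1L])^2 +
                     (placed[, 2L] - cand[2L])^2) > step)) {
          pos <- cand
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    placed <- rbind(placed, pos)
    out$x[r] <- pos[1L]
    out$y[r] <- pos[2L]
  }
  out
}

resolve_classification <- function(labels, which, what) {
  if (is.null(labels)) return(NULL)
  lab <- labels[[which]]
  if (is.null(lab)) {
    stop("`", what, " = \"alternative\"` but no alternative class labels ",
         "were provided", call. = FALSE)
  }
  lab
}

cells_data_frame <- function(tess, fill) {
  do.call(rbind, lapply(seq_along(tess$cells), function(i) {
    poly <- tess$cells[[i]]
    data.frame(x = poly[, 1L], y = poly[, 2L], cell = i,
               fill = fill[i])
  }))
}

ellipse_data_frame <- function(xy, lab, level) {
  out <- NULL
  for (g in levels(lab)) {
    spec <- fit_ellipse(xy[lab == g, , drop = FALSE], level = level,
                        group = g)
    if (!is.null(spec)) {
      ring <- ellipse_polygon(spec, 100L)
      out <- rbind(out, data.frame(x = ring[, 1L], y = ring[, 2L],
                                   group = g))
    }
  }
  out
}

base_theme <- function(legend_position, add_grid_lines) {
  th <- ggplot2::theme_bw() +
    ggplot2::theme(legend.position = legend_position,
                   panel.grid = ggplot2::element_blank())
  th
}

#' Build the three class-map plots for a 2-D dataset
#'
#' The full plot bundle: a scatter plot with per-group confidence
#' ellipses, a Voronoi tessellation plot with class-colored cells, and a
#' combined plot carrying both layers.  All three share axes, palette and
#' legend.  Cells may be filled by an alternative classification (e.g. a
#' clustering) while points keep their prior class colors, which makes
#' disagreement between the two directly visible.  When
#' \code{show_island_count = TRUE} the Voronoi island count and rate are
#' appended as a subtitle, always computed on the classification that
#' fills the cells so the metric describes the visible map.
#'
#' @param data Data frame with at least two numeric coordinate columns.
#' @param class_column Column name, or a vector of class labels.
#' @param alternative_class_column Optional second classification (column
#'   name or vector).
#' @param coordinate_columns Character vector of the two coordinate
#'   column names; NULL uses the first two numeric columns.
#' @param case_labels Character vector of case labels (empty strings are
#'   suppressed); NULL uses row numbers.
#' @param coord_names Axis titles, default \code{c("Dim1", "Dim2")}.
#' @param title Optional plot title.
#' @param show_labels Render case labels (default FALSE).
#' @param ellipse_alpha Fill transparency of the ellipses (default 0.1).
#' @param ellipse_level Confidence level of the ellipses (default 0.95).
#' @param voronoi_alpha Fill transparency of the cells (default 0.3).
#' @param point_size Point size (default 2).
#' @param legend_position Legend position (default "bottom").
#' @param color_palette Custom palette (character vector) or NULL for the
#'   built-in colorblind-safe cycle.
#' @param add_grid_lines Draw origin grid lines (default FALSE).
#' @param color_points Classification for point colors: "primary" or
#'   "alternative".
#' @param fill_voronoi Classification for cell fills: "primary" or
#'   "alternative".
#' @param point_shape Classification for point glyph shapes: "primary",
#'   "alternative" or "none" (uniform glyph, the default).
#' @param label_fontface Font face for case labels.
#' @param label_size Size of case labels (default 3.88).
#' @param show_island_count Append the island count/rate subtitle
#'   (default FALSE).
#' @param label_islands_only Label only island cases; requires
#'   \code{show_island_count = TRUE}.
#' @param margin_frac Window margin around the data (default 0.05).
#' @return List of class \code{plot_bundle}: \code{scatter_plot},
#'   \code{voronoi_plot}, \code{combined_plot} (ggplot objects), plus
#'   \code{islands} (an \code{island_report}, or NULL), and the
#'   underlying \code{tessellation} and \code{graph}.
#' @examples
#' d <- data.frame(x = rnorm(20), y = rnorm(20),
#'                 grp = rep(c("a", "b"), 10))
#' res <- create_tessellation_plots(d, class_column = "grp")
#' names(res)
#' @export
create_tessellation_plots <- function(data,
                                      class_column = NULL,
                                      alternative_class_column = NULL,
                                      coordinate_columns = NULL,
                                      case_labels = NULL,
                                      coord_names = c("Dim1", "Dim2"),
                                      title = NULL,
                                      show_labels = FALSE,
                                      ellipse_alpha = 0.1,
                                      ellipse_level = 0.95,
                                      voronoi_alpha = 0.3,
                                      point_size = 2,
                                      legend_position = "bottom",
                                      color_palette = NULL,
                                      add_grid_lines = FALSE,
                                      color_points = "primary",
                                      fill_voronoi = "primary",
                                      point_shape = "none",
                                      label_fontface = "plain",
                                      label_size = 3.88,
                                      show_island_count = FALSE,
                                      label_islands_only = FALSE,
                                      margin_frac = 0.05) {
  built <- build_map_layers(data, class_column, alternative_class_column,
                            coordinate_columns, case_labels, coord_names,
                            title, show_labels, voronoi_alpha, point_size,
                            legend_position, color_palette, add_grid_lines,
                            color_points, fill_voronoi, point_shape,
                            label_fontface, label_size, show_island_count,
                            label_islands_only, margin_frac)
  ell_layer <- NULL
  if (!is.null(built$color_lab)) {
    edf <- ellipse_data_frame(built$ps$coords, built$color_lab,
                              ellipse_level)
    if (!is.null(edf)) {
      ell_layer <- ggplot2::geom_polygon(
        data = edf,
        ggplot2::aes(x = x, y = y, fill = group,
                     color = group),
        alpha = ellipse_alpha, linewidth = 0.4, inherit.aes = FALSE)
    }
  }
  scatter <- built$base + ell_layer + built$point_layers +
    built$label_layer + built$titles_scatter
  voronoi <- built$base + built$cell_layer + built$point_layers +
    built$label_layer + built$titles_voronoi
  combined <- built$base + built$cell_layer + ell_layer +
    built$point_layers + built$label_layer + built$titles_voronoi
  structure(list(scatter_plot = scatter,
                 voronoi_plot = voronoi,
                 combined_plot = combined,
                 islands = built$islands,
                 tessellation = built$tess,
                 graph = built$graph),
            class = "plot_bundle")
}

#' Build only the Voronoi tessellation plot
#'
#' The reduced entry point: the class-colored Voronoi cell variant with
#' points overlaid, without confidence ellipses.  Same parameters and
#' semantics as \code{\link{create_tessellation_plots}}.
#'
#' @inheritParams create_tessellation_plots
#' @return A ggplot object; the island report (when computed) is attached
#'   as attribute \code{"islands"}.
#' @export
create_voronoi_plot <- function(data,
                                class_column = NULL,
                                alternative_class_column = NULL,
                                coordinate_columns = NULL,
                                case_labels = NULL,
                                coord_names = c("Dim1", "Dim2"),
                                title = NULL,
                                show_labels = FALSE,
                                voronoi_alpha = 0.3,
                                point_size = 2,
                                legend_position = "bottom",
                                color_palette = NULL,
                                add_grid_lines = FALSE,
                                color_points = "primary",
                                fill_voronoi = "primary",
                                point_shape = "none",
                                label_fontface = "plain",
                                label_size = 3.88,
                                show_island_count = FALSE,
                                label_islands_only = FALSE,
                                margin_frac = 0.05) {
  built <- build_map_layers(data, class_column, alternative_class_column,
                            coordinate_columns, case_labels, coord_names,
                            title, show_labels, voronoi_alpha, point_size,
                            legend_position, color_palette, add_grid_lines,
                            color_points, fill_voronoi, point_shape,
                            label_fontface, label_size, show_island_count,
                            label_islands_only, margin_frac)
  p <- built$base + built$cell_layer + built$point_layers +
    built$label_layer + built$titles_voronoi
  attr(p, "islands") <- built$islands
  p
}

# shared assembly of point set, tessellation, islands and ggplot layers
build_map_layers <- function(data, class_column, alternative_class_column,
                             coordinate_columns, case_labels, coord_names,
                             title, show_labels, voronoi_alpha, point_size,
                             legend_position, color_palette, add_grid_lines,
                             color_points, fill_voronoi, point_shape,
                             label_fontface, label_size, show_island_count,
                             label_islands_only, margin_frac) {
  if (!voronoi_alpha >= 0 || !voronoi_alpha <= 1) {
    stop("`voronoi_alpha` must be in [0, 1]", call. = FALSE)
  }
  ok_tags <- c("primary", "alternative")
  if (!color_points %in% ok_tags) {
    stop("`color_points` must be \"primary\" or \"alternative\"",
         call. = FALSE)
  }
  if (!fill_voronoi %in% ok_tags) {
    stop("`fill_voronoi` must be \"primary\" or \"alternative\"",
         call. = FALSE)
  }
  if (!point_shape %in% c(ok_tags, "none")) {
    stop("`point_shape` must be \"primary\", \"alternative\" or \"none\"",
         call. = FALSE)
  }
  if (label_islands_only && !show_island_count) {
    stop("`label_islands_only = TRUE` requires `show_island_count = TRUE`",
         call. = FALSE)
  }
  parsed <- resolve_table(data, class_column, alternative_class_column,
                          coordinate_columns, case_labels)
  ps <- parsed$points
  labels <- parsed$labels
  tess <- tessellate(ps, margin_frac = margin_frac)
  graph <- neighbor_graph(ps, tess)
  color_lab <- resolve_classification(labels, color_points, "color_points")
  fill_lab <- resolve_classification(labels, fill_voronoi, "fill_voronoi")
  shape_lab <- if (point_shape == "none") NULL else {
    resolve_classification(labels, point_shape, "point_shape")
  }
  islands <- NULL
  subtitle <- NULL
  if (show_island_count) {
    isl_lab <- if (is.null(fill_lab)) {
      factor(rep("all", ps$n))
    } else {
      fill_lab
    }
    islands <- find_islands(graph, class_labels(isl_lab), "primary")
    islands$labels_used <- fill_voronoi
    subtitle <- subtitle_text(islands)
  }
  all_levels <- unique(c(if (!is.null(color_lab)) levels(color_lab),
                         if (!is.null(fill_lab)) levels(fill_lab)))
  pal <- if (length(all_levels)) {
    stats::setNames(resolve_palette(length(all_levels), color_palette),
                    all_levels)
  } else {
    NULL
  }
  df <- data.frame(x = ps$coords[, 1L], y = ps$coords[, 2L])
  base <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::labs(x = coord_names[1L], y = coord_names[2L]) +
    base_theme(legend_position, add_grid_lines)
  if (add_grid_lines) {
    base <- base +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                          color = "grey60") +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                          color = "grey60")
  }
  if (!is.null(pal)) {
    base <- base +
      ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
      ggplot2::scale_color_manual(values = pal, drop = FALSE)
  }
  # cells
  fill_values <- if (is.null(fill_lab)) {
    factor(rep("all", ps$n))
  } else {
    fill_lab
  }
  cdf <- cells_data_frame(tess, fill_values)
  cell_layer <- if (is.null(fill_lab)) {
    ggplot2::geom_polygon(data = cdf,
                          ggplot2::aes(x = x, y = y,
                                       group = cell),
                          fill = "grey80", alpha = voronoi_alpha,
                          color = "white", linewidth = 0.3,
                          inherit.aes = FALSE)
  } else {
    ggplot2::geom_polygon(data = cdf,
                          ggplot2::aes(x = x, y = y,
                                       group = cell,
                                       fill = fill),
                          alpha = voronoi_alpha, color = "white",
                          linewidth = 0.3, inherit.aes = FALSE)
  }
  # points
  pdf_ <- df
  point_aes <- ggplot2::aes()
  if (!is.null(color_lab)) {
    pdf_$color <- color_lab
    point_aes$colour <- quote(color)
  }
  if (!is.null(shape_lab)) {
    pdf_$shape <- shape_lab
    point_aes$shape <- quote(shape)
  }
  point_layers <- ggplot2::geom_point(data = pdf_, point_aes,
                                      size = point_size,
                                      inherit.aes = TRUE)
  # labels
  label_layer <- NULL
  if (show_labels || label_islands_only) {
    lab_df <- place_labels(ps, parsed$case_labels,
                           which = if (label_islands_only) "islands_only"
                                   else "all",
                           island_report = islands)
    if (nrow(lab_df)) {
      label_layer <- ggplot2::geom_text(
        data = lab_df,
        ggplot2::aes(x = x, y = y, label = label),
        size = label_size, fontface = label_fontface,
        inherit.aes = FALSE)
    }
  }
  list(ps = ps, labels = labels, tess = tess, graph = graph,
       islands = islands, color_lab = color_lab, fill_lab = fill_lab,
       base = base, cell_layer = cell_layer, point_layers = point_layers,
       label_layer = label_layer,
       titles_scatter = ggplot2::labs(title = title),
       titles_voronoi = ggplot2::labs(title = title, subtitle = subtitle))
}

#' @export
print.plot_bundle <- function(x, ...) {
  cat("Class-map plot bundle: scatter_plot, voronoi_plot, combined_plot")
  if (!is.null(x$islands)) cat(" |", subtitle_text(x$islands))
  cat("\n")
  invisible(x)
}

#' Save a figure to PNG, SVG or PDF
#'
#' @param plot A ggplot object.
#' @param path Output path; format follows the extension (.png, .svg,
#'   .pdf).
#' @param width,height Figure size in inches.
#' @param dpi Resolution for raster output.
#' @return The path, invisibly.
#' @export
save_figure <- function(plot, path, width = 7, height = 6, dpi = 150) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = dpi)
  invisible(path)
}
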