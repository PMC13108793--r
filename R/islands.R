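# Voronoi island detection: a point whose every Voronoi neighbor carries a
# different class label is the strongest local class-discordance signal the
# tessellation can show.  The island count and rate summarize it.

#' Bundle primary and alternative class labels
#'
#' Pairs the prior classification (\code{primary}) with an optional second
#' classification (\code{alternative}, e.g. a clustering solution) of the
#' same points.  Missing labels are rejected: island status is undefined
#' for an unlabeled point.
#'
#' @param primary Vector or factor of class labels, one per point.
#' @param alternative Optional second label vector of the same length.
#' @return An object of class \code{class_labels}.
#' @examples
#' class_labels(c("a", "a", "b"))
#' @export
class_labels <- function(primary, alternative = NULL) {
  primary <- validate_labels(primary, "primary")
  if (!is.null(alternative)) {
    alternative <- validate_labels(alternative, "alternative")
    if (length(alternative) != length(primary)) {
      stop("`alternative` labels length (", length(alternative),
           ") does not match `primary` (", length(primary), ")",
           call. = FALSE)
    }
  }
  structure(list(primary = primary, alternative = alternative,
                 n = length(primary)),
            class = "class_labels")
}

validate_labels <- function(x, what) {
  if (is.factor(x)) x <- droplevels(x) else x <- factor(x)
  if (anyNA(x) || any(as.character(x) == "", na.rm = TRUE)) {
    bad <- which(is.na(x) | as.character(x) == "")
    stop("missing ", what, " class labels in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (nlevels(x) < 1L) stop("no ", what, " class levels", call. = FALSE)
  x
}

as_class_labels <- function(x) {
  if (inherits(x, "class_labels")) x else class_labels(x)
}

#' Detect Voronoi islands
#'
#' A point is a Voronoi island when it has at least one neighbor in the
#' Delaunay-dual graph and none of its neighbors shares its class label:
#' its cell is entirely enclosed in foreign-class territory.  Two
#' same-class points that sit deep inside the opposite class but are
#' adjacent to each other are deliberately not islands -- each retains one
#' same-class neighbor, a weaker form of discordance.
#'
#' @param graph A \code{neighbor_graph}.
#' @param labels A \code{class_labels} object (or plain label vector).
#' @param which Which label vector defines discordance: \code{"primary"}
#'   (default) or \code{"alternative"}.  This must mirror the
#'   classification used to fill the Voronoi cells in a plot, so the
#'   metric describes the visible tessellation.
#' @return An object of class \code{island_report}: list with
#'   \code{islands} (integer indices), \code{case_ids}, \code{count},
#'   \code{rate} (= count / n), \code{labels_used}, \code{n}.
#' @examples
#' tess <- tessellate(point_set(rbind(c(0, 0), c(2, 0))))
#' g <- neighbor_graph(tess = tess)
#' find_islands(g, c("A", "B"))$count
#' @export
find_islands <- function(graph, labels, which = c("primary", "alternative")) {
  if (!inherits(graph, "neighbor_graph")) {
    stop("`graph` must be a neighbor_graph", call. = FALSE)
  }
  which <- match.arg(which)
  labels <- as_class_labels(labels)
  lab <- labels[[which]]
  if (is.null(lab)) {
    stop("no alternative class labels were provided", call. = FALSE)
  }
  if (length(lab) != graph$n) {
    stop("labels length (", length(lab), ") does not match graph size (",
         graph$n, ")", call. = FALSE)
  }
  islands <- integer(0)
  if (graph$n >= 2L) {
    for (i in seq_len(graph$n)) {
      nb <- graph$adjacency[[i]]
      if (length(nb) >= 1L && !any(lab[nb] == lab[i])) {
        islands <- c(islands, i)
      }
    }
  }
  structure(list(islands = islands,
                 case_ids = graph$case_ids[islands],
                 count = length(islands),
                 rate = if (graph$n > 0L) length(islands) / graph$n else 0,
                 labels_used = which,
                 n = graph$n),
            class = "island_report")
}

# round half away from zero at `digits` decimals; matches the printed
# rates (5.0, 2.8, 5.6) where round-half-even would disagree
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format an island rate as a percentage
#'
#' Rate times 100, rounded half-up to one decimal, with a \code{"\%"}
#' suffix, e.g. 4 islands among 80 points gives \code{"5.0\%"}.
#'
#' @param report An \code{island_report}.
#' @return Character scalar.
#' @export
island_rate_percent <- function(report) {
  stopifnot(inherits(report, "island_report"))
  sprintf("%.1f%%", round_half_up(report$rate * 100, 1L))
}

#' Plot subtitle for an island report
#'
#' The fixed subtitle string shown on tessellation plots when the island
#' count display is enabled: \code{"Voronoi islands: {count} ({rate})"}.
#'
#' @param report An \code{island_report}.
#' @return Character scalar, e.g. \code{"Voronoi islands: 4 (5.6\%)"}.
#' @export
subtitle_text <- function(report) {
  stopifnot(inherits(report, "island_report"))
  sprintf("Voronoi islands: %d (%s)", report$count,
          island_rate_percent(report))
}

#' Serialize an island report to JSON
#'
#' @param report An \code{island_report}.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
island_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "island_report"))
  x <- list(n = report$n,
            labels_used = report$labels_used,
            islands = as.list(report$case_ids),
            count = report$count,
            rate = report$rate)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(json)
  } else {
    json
  }
}

#' @export
print.island_report <- function(x, ...) {
  cat(subtitle_text(x), "out of", x$n, "points, using", x$labels_used,
      "labels\n")
  if (x$count > 0L) {
    cat("island case ids:", paste(x$case_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
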