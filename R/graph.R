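#' Weighted bipartite graph as a tidy edge list
#'
#' A `bipartite_graph` is a tibble with columns `x` (tumor-side gene), `y`
#' (stroma-side gene) and `weight` (edge weight in (0, 1]), plus vertex
#' attributes holding the full vertex sets of both sides (vertices may be
#' isolated). Vertex ids are opaque case-sensitive strings; the two sides are
#' kept separate so the same gene symbol may appear on both sides.
#'
#' @param edges data frame with columns `x`, `y`, `weight`.
#' @param x_vertices,y_vertices character vectors of vertex ids for each side;
#'   default: the ids present in `edges`.
#' @return A `bipartite_graph` tibble.
#' @export
#' @examples
#' g <- bipartite_graph(data.frame(x = "t1", y = "s1", weight = 0.9))
#' graph_vertices(g)
bipartite_graph <- function(edges, x_vertices = NULL, y_vertices = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("x", "y", "weight") %in% names(edges)))
  edges <- dplyr::select(edges, "x", "y", "weight")
  edges$x <- as.character(edges$x)
  edges$y <- as.character(edges$y)
  if (anyDuplicated(edges[, c("x", "y")])) {
    abort("duplicate (x, y) edge pairs are not allowed")
  }
  if (nrow(edges) && (any(edges$weight <= 0) || any(edges$weight > 1))) {
    abort("edge weights must lie in (0, 1]")
  }
  x_vertices <- sort(unique(c(as.character(x_vertices %||% character()), edges$x)))
  y_vertices <- sort(unique(c(as.character(y_vertices %||% character()), edges$y)))
  edges <- dplyr::arrange(edges, dplyr::desc(.data$weight), .data$x, .data$y)
  structure(edges,
    x_vertices = x_vertices, y_vertices = y_vertices,
    class = c("bipartite_graph", class(tibble::tibble()))
  )
}

#' @rdname bipartite_graph
#' @param graph a `bipartite_graph`.
#' @export
graph_vertices <- function(graph) {
  list(x = attr(graph, "x_vertices"), y = attr(graph, "y_vertices"))
}

# internal: dense weight matrix (rows = x vertices, cols = y vertices, both in
# sorted id order; absent edges are 0, consistent with thresholded construction)
graph_weight_matrix <- function(graph) {
  xv <- attr(graph, "x_vertices")
  yv <- attr(graph, "y_vertices")
  W <- matrix(0, length(xv), length(yv), dimnames = list(xv, yv))
  if (nrow(graph)) {
    W[cbind(match(graph$x, xv), match(graph$y, yv))] <- graph$weight
  }
  W
}

#' @export
print.bipartite_graph <- function(x, ...) {
  v <- graph_vertices(x)
  cat(sprintf(
    "# Weighted bipartite graph: %d x-vertices, %d y-vertices, %d edges\n",
    length(v$x), length(v$y), nrow(x)
  ))
  NextMethod()
}
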