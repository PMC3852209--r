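#' Density of the union of two vertex-set pairs
#'
#' The density (see [binet_density()]) of the bipartite sub-network induced
#' by the unions of the two x sides and of the two y sides. Merging a network
#' with itself returns its own density.
#'
#' @param graph a [bipartite_graph()].
#' @param x1,y1 member sets of the first network.
#' @param x2,y2 member sets of the second network.
#' @return The merged density.
#' @export
merged_density <- function(graph, x1, y1, x2, y2) {
  binet_density(graph, union(x1, x2), union(y1, y2))
}

#' Merge BiNets into macro bipartite networks
#'
#' Best-first agglomerative merging with a guaranteed minimum merged density:
#' starting from one cluster per BiNet, the pair of clusters whose merged
#' density (recomputed exactly on the graph) is maximal is merged, as long as
#' that density is at least `threshold`; ties go to the smallest pair of
#' cluster ids. The result is a partition of the BiNets (gene sets may still
#' overlap across macro networks) together with the merge dendrogram, a
#' forest with one binary tree per macro network.
#'
#' @param result a `bcm_result` (typically after [filter_min_genes()]).
#' @param graph the [bipartite_graph()] the BiNets were mined from.
#' @param threshold minimum merged density, in (0, 1]; default 0.3.
#' @return A `binet_merge` list: `macro`, a tibble with one row per macro
#'   network (member BiNet ids, merged vertex sets, sizes, recomputed
#'   density); `dendrogram`, a list of root nodes (leaves are labelled
#'   `B<binet_id>`, internal nodes carry `merge_density` and `height`); and
#'   `threshold`.
#' @export
merge_binets <- function(result, graph, threshold = 0.3) {
  stopifnot(inherits(result, "bcm_result"), inherits(graph, "bipartite_graph"))
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must be in (0, 1]")
  if (!nrow(result)) {
    return(structure(
      list(macro = empty_macro_tibble(), dendrogram = list(),
           threshold = threshold),
      class = "binet_merge"
    ))
  }
  W <- graph_weight_matrix(graph)
  clusters <- purrr::pmap(
    list(result$binet_id, result$x_members, result$y_members),
    function(id, xs, ys) {
      list(
        ids = id, xs = xs, ys = ys,
        node = list(label = paste0("B", id), height = 0)
      )
    }
  )
  pair_density <- function(a, b) {
    xs <- union(a$xs, b$xs)
    ys <- union(a$ys, b$ys)
    sum(W[xs, ys, drop = FALSE]) / (length(xs) * length(ys))
  }
  while (length(clusters) > 1) {
    # clusters stay sorted by smallest member id, so scanning pairs in index
    # order with a strict '>' makes the smallest id pair win density ties
    best <- -Inf
    best_pair <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- pair_density(clusters[[i]], clusters[[j]])
        if (d > best) {
          best <- d
          best_pair <- c(i, j)
        }
      }
    }
    if (best < threshold) break
    a <- clusters[[best_pair[[1]]]]
    b <- clusters[[best_pair[[2]]]]
    merged <- list(
      ids = sort(c(a$ids, b$ids)),
      xs = union(a$xs, b$xs), ys = union(a$ys, b$ys),
      node = list(
        left = a$node, right = b$node, merge_density = best,
        height = max(a$node$height, b$node$height) + 1
      )
    )
    clusters <- clusters[-best_pair]
    clusters <- append(clusters, list(merged))
    clusters <- clusters[order(purrr::map_dbl(clusters, ~ min(.x$ids)))]
  }
  macro <- tibble::tibble(
    macro_id = seq_along(clusters),
    member_binet_ids = purrr::map(clusters, "ids"),
    x_union = purrr::map(clusters, "xs"),
    y_union = purrr::map(clusters, "ys"),
    n_binets = purrr::map_int(clusters, ~ length(.x$ids)),
    n_x = purrr::map_int(clusters, ~ length(.x$xs)),
    n_y = purrr::map_int(clusters, ~ length(.x$ys)),
    density = purrr::map_dbl(
      clusters,
      ~ sum(W[.x$xs, .x$ys, drop = FALSE]) / (length(.x$xs) * length(.x$ys))
    )
  )
  structure(
    list(
      macro = macro, dendrogram = purrr::map(clusters, "node"),
      threshold = threshold
    ),
    class = "binet_merge"
  )
}

empty_macro_tibble <- function() {
  tibble::tibble(
    macro_id = integer(), member_binet_ids = list(), x_union = list(),
    y_union = list(), n_binets = integer(), n_x = integer(), n_y = integer(),
    density = double()
  )
}

#' Newick serialization of the merge dendrogram
#'
#' Each macro network's binary merge tree becomes one Newick string; branch
#' lengths carry the merge density of the parent node (leaves of an unmerged
#' singleton are emitted as a bare leaf).
#'
#' @param merge a `binet_merge` from [merge_binets()].
#' @return Character vector of Newick strings, one per macro network.
#' @export
dendrogram_newick <- function(merge) {
  stopifnot(inherits(merge, "binet_merge"))
  render <- function(node) {
    if (!is.null(node$label)) {
      return(node$label)
    }
    d <- format(node$merge_density, digits = 10)
    paste0("(", render(node$left), ":", d, ",", render(node$right), ":", d, ")")
  }
  vapply(merge$dendrogram, function(n) paste0(render(n), ";"), character(1))
}

#' @export
print.binet_merge <- function(x, ...) {
  cat(sprintf(
    "# BiNet merge: %d macro network(s) at density threshold %g\n",
    nrow(x$macro), x$threshold
  ))
  print(x$macro, ...)
  invisible(x)
}
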