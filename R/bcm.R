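#' BCM mining parameters
#'
#' The admission schedule is controlled by two nonnegative integers `C` and
#' `tau`: a candidate vertex is admitted to a growing BiNet only if its
#' density contribution is at least \eqn{\alpha} times the current density,
#' with \eqn{\alpha = 1 - 1/(\lambda (i + \tau + 1))} and
#' \eqn{\lambda = \max\{1, C/(i + \tau + 1)^2\}} for current side size
#' \eqn{i}. `beta` restricts seeding to heavy edges: only unselected edges
#' with weight at least `beta` times the heaviest edge weight start a BiNet.
#' `C` must exceed \eqn{(\tau + 2)^2} for the density bound to hold.
#'
#' Defaults `C = 36`, `tau = 2`, `beta = 0.7` are the settings used for the
#' tumor-stroma network analysis.
#'
#' @param C positive integer, `C > (tau + 2)^2`.
#' @param tau nonnegative integer.
#' @param beta seed-weight fraction, in (0, 1].
#' @param min_seed_weight optional absolute floor on seed-edge weight,
#'   applied in addition to `beta * w_max`.
#' @return A `bcm_params` list.
#' @export
bcm_params <- function(C = 36, tau = 2, beta = 0.7, min_seed_weight = NULL) {
  stopifnot(length(C) == 1, length(tau) == 1, length(beta) == 1)
  if (tau < 0 || tau != round(tau)) abort("tau must be a nonnegative integer")
  if (C != round(C) || C <= (tau + 2)^2) {
    abort("C must be an integer larger than (tau + 2)^2")
  }
  if (!(beta > 0 && beta <= 1)) abort("beta must be in (0, 1]")
  structure(
    list(
      C = as.integer(C), tau = as.integer(tau), beta = beta,
      min_seed_weight = min_seed_weight
    ),
    class = "bcm_params"
  )
}

#' Admission threshold of the growth schedule
#'
#' \eqn{\alpha = 1 - 1/(\lambda (size + \tau + 1))} with
#' \eqn{\lambda = \max\{1, C/(size + \tau + 1)^2\}}: equal to
#' \eqn{1 - (size+\tau+1)/C} while \eqn{(size+\tau+1)^2 < C}, and
#' \eqn{1 - 1/(size+\tau+1)} beyond that crossover.
#'
#' @param size current vertex count of the side being grown (>= 1); vectorized.
#' @param C,tau schedule parameters (see [bcm_params()]).
#' @return Threshold value(s) in (0, 1).
#' @export
bcm_alpha <- function(size, C, tau) {
  stopifnot(all(size >= 1))
  m <- size + tau + 1
  lambda <- pmax(1, C / m^2)
  1 - 1 / (lambda * m)
}

#' Density of a bipartite vertex-set pair
#'
#' The density of a BiNet with sides of size \eqn{a} and \eqn{b} is the sum of
#' induced edge weights divided by \eqn{a b} — the average weight over all
#' vertex pairs, with absent edges counting 0.
#'
#' @param graph a [bipartite_graph()].
#' @param x_members,y_members character vectors of member vertex ids
#'   (both non-empty).
#' @return The density, a real in [0, 1].
#' @export
binet_density <- function(graph, x_members, y_members) {
  if (!length(x_members) || !length(y_members)) {
    abort("density undefined for an empty side")
  }
  W <- graph_weight_matrix(graph)
  check_members(x_members, rownames(W), "x")
  check_members(y_members, colnames(W), "y")
  sum(W[x_members, y_members, drop = FALSE]) /
    (length(x_members) * length(y_members))
}

#' Density contribution of a candidate vertex
#'
#' The mean edge weight from `vertex` to the opposite side's current members;
#' absent edges count 0.
#'
#' @param graph a [bipartite_graph()].
#' @param vertex candidate vertex id, not already a member of its side.
#' @param side `"x"` or `"y"`: the side `vertex` would join.
#' @param x_members,y_members current member sets.
#' @return The contribution, a real in [0, 1].
#' @export
vertex_contribution <- function(graph, vertex, side = c("x", "y"),
                                x_members, y_members) {
  side <- match.arg(side)
  W <- graph_weight_matrix(graph)
  if (side == "x") {
    check_members(vertex, rownames(W), "x")
    check_members(y_members, colnames(W), "y")
    if (vertex %in% x_members) abort("vertex is already a member of side x")
    sum(W[vertex, y_members]) / length(y_members)
  } else {
    check_members(vertex, colnames(W), "y")
    check_members(x_members, rownames(W), "x")
    if (vertex %in% y_members) abort("vertex is already a member of side y")
    sum(W[x_members, vertex]) / length(x_members)
  }
}

check_members <- function(ids, universe, side) {
  missing <- setdiff(ids, universe)
  if (length(missing)) {
    abort(sprintf(
      "unknown %s-side vertex id(s): %s", side,
      paste(head(missing, 5), collapse = ", ")
    ))
  }
}

#' Mine dense bipartite sub-networks (BiNets) with a density guarantee
#'
#' Greedy seed-and-grow mining of a weighted bipartite graph. Edges are
#' visited in descending weight order (ties broken lexicographically by
#' endpoint ids); each unselected edge with weight at least
#' `beta * w_max` seeds a BiNet that grows by repeatedly taking the
#' highest-contribution candidate on each side (ties to the smallest vertex
#' id), comparing the two sides' best contributions (equal bests go to the
#' y side), and admitting the winner only if its contribution is at least
#' \eqn{\alpha} times the current density (see [bcm_alpha()]); growth stops
#' the first time the winning side fails its test. On admission, every graph
#' edge from the new vertex into the current opposite member set is marked
#' selected (the seed edge is marked at creation), so later seeds skip
#' already-covered heavy edges; vertices may still be shared between BiNets.
#'
#' Every mined BiNet's final density is guaranteed to be at least
#' [density_bound()]`(C, tau)` times its seed-edge weight.
#'
#' @param graph a [bipartite_graph()].
#' @param params a [bcm_params()] object.
#' @return A `bcm_result` tibble with one row per BiNet: ids and weight of the
#'   seed edge, member list-columns, side sizes, distinct-gene count, final
#'   density, and a `trace` list-column recording every growth step (vertex,
#'   side, contribution, alpha used, density after). Attributes: `params`,
#'   `w_max`, `n_selected_edges`.
#' @export
#' @examples
#' g <- simulate_bipartite_graph(8, 8, 0.6, c(0.5, 1), seed = 1)
#' res <- bcm_mine(g, bcm_params())
#' res[, c("binet_id", "n_x", "n_y", "density")]
bcm_mine <- function(graph, params = bcm_params()) {
  stopifnot(inherits(graph, "bipartite_graph"), inherits(params, "bcm_params"))
  if (!nrow(graph)) {
    return(new_bcm_result(list(), params, w_max = NA_real_, n_selected = 0L))
  }
  W <- graph_weight_matrix(graph)
  xv <- rownames(W)
  yv <- colnames(W)
  # graph edges are already sorted by descending weight, then x, then y
  ei <- match(graph$x, xv)
  ej <- match(graph$y, yv)
  w_max <- graph$weight[[1]]
  seed_floor <- max(params$beta * w_max, params$min_seed_weight %||% 0)
  selected <- matrix(FALSE, nrow(W), ncol(W))
  binets <- list()

  for (k in seq_len(nrow(graph))) {
    if (graph$weight[[k]] < seed_floor) break
    i <- ei[[k]]
    j <- ej[[k]]
    if (selected[i, j]) next
    selected[i, j] <- TRUE
    xs <- i
    ys <- j
    dens <- graph$weight[[k]]
    steps <- list()
    repeat {
      cand_x <- setdiff(seq_along(xv), xs)
      cand_y <- setdiff(seq_along(yv), ys)
      if (length(cand_x)) {
        cx <- rowSums(W[cand_x, ys, drop = FALSE]) / length(ys)
        px <- cand_x[[which.max(cx)]] # first max = smallest id (sorted order)
        best_x <- max(cx)
      } else {
        best_x <- -Inf
      }
      if (length(cand_y)) {
        cy <- colSums(W[xs, cand_y, drop = FALSE]) / length(xs)
        py <- cand_y[[which.max(cy)]]
        best_y <- max(cy)
      } else {
        best_y <- -Inf
      }
      if (best_x > best_y) {
        alpha <- bcm_alpha(length(xs), params$C, params$tau)
        if (best_x >= alpha * dens) {
          dens <- (dens * length(xs) * length(ys) + sum(W[px, ys])) /
            ((length(xs) + 1) * length(ys))
          selected[px, ys[W[px, ys] > 0]] <- TRUE
          xs <- c(xs, px)
          steps[[length(steps) + 1]] <- list(
            vertex = xv[[px]], side = "x", contribution = best_x,
            alpha = alpha, density_after = dens
          )
        } else {
          break
        }
      } else {
        if (!is.finite(best_y)) break
        alpha <- bcm_alpha(length(ys), params$C, params$tau)
        if (best_y >= alpha * dens) {
          dens <- (dens * length(xs) * length(ys) + sum(W[xs, py])) /
            (length(xs) * (length(ys) + 1))
          selected[xs[W[xs, py] > 0], py] <- TRUE
          ys <- c(ys, py)
          steps[[length(steps) + 1]] <- list(
            vertex = yv[[py]], side = "y", contribution = best_y,
            alpha = alpha, density_after = dens
          )
        } else {
          break
        }
      }
    }
    binets[[length(binets) + 1]] <- list(
      seed_x = xv[[i]], seed_y = yv[[j]], seed_weight = graph$weight[[k]],
      x_members = xv[xs], y_members = yv[ys], density = dens,
      trace = steps_to_tibble(steps)
    )
  }
  new_bcm_result(binets, params, w_max, sum(selected))
}

steps_to_tibble <- function(steps) {
  if (!length(steps)) {
    return(tibble::tibble(
      step = integer(), vertex = character(), side = character(),
      contribution = double(), alpha = double(), density_after = double()
    ))
  }
  dplyr::bind_cols(
    tibble::tibble(step = seq_along(steps)),
    purrr::map_dfr(steps, tibble::as_tibble)
  )
}

new_bcm_result <- function(binets, params, w_max, n_selected) {
  tbl <- if (length(binets)) {
    tibble::tibble(
      binet_id = seq_along(binets),
      seed_x = purrr::map_chr(binets, "seed_x"),
      seed_y = purrr::map_chr(binets, "seed_y"),
      seed_weight = purrr::map_dbl(binets, "seed_weight"),
      x_members = purrr::map(binets, "x_members"),
      y_members = purrr::map(binets, "y_members"),
      n_x = purrr::map_int(binets, ~ length(.x$x_members)),
      n_y = purrr::map_int(binets, ~ length(.x$y_members)),
      n_genes = purrr::map_int(
        binets, ~ length(union(.x$x_members, .x$y_members))
      ),
      density = purrr::map_dbl(binets, "density"),
      trace = purrr::map(binets, "trace")
    )
  } else {
    tibble::tibble(
      binet_id = integer(), seed_x = character(), seed_y = character(),
      seed_weight = double(), x_members = list(), y_members = list(),
      n_x = integer(), n_y = integer(), n_genes = integer(),
      density = double(), trace = list()
    )
  }
  structure(tbl,
    params = params, w_max = w_max, n_selected_edges = n_selected,
    class = c("bcm_result", class(tibble::tibble()))
  )
}

#' Keep BiNets with enough distinct genes
#'
#' Counts the union of the two sides (a symbol present on both sides counts
#' once) and keeps BiNets whose distinct-gene count meets `min_genes`.
#'
#' @param result a `bcm_result` from [bcm_mine()].
#' @param min_genes minimum distinct gene count; default 10.
#' @return The filtered `bcm_result` (attributes preserved).
#' @export
filter_min_genes <- function(result, min_genes = 10) {
  stopifnot(inherits(result, "bcm_result"))
  keep <- result$n_genes >= min_genes
  out <- result[keep, , drop = FALSE]
  attributes(out)[c("params", "w_max", "n_selected_edges")] <-
    attributes(result)[c("params", "w_max", "n_selected_edges")]
  class(out) <- class(result)
  out
}

#' @export
print.bcm_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "# BCM mining result: %d BiNets (C = %d, tau = %d, beta = %g, w_max = %s)\n",
    nrow(x), p$C, p$tau, p$beta, format(attr(x, "w_max"), digits = 4)
  ))
  NextMethod()
}
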