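# Independent reference implementations used as oracles. These are written
# naively (explicit loops, densities recomputed from scratch at every step)
# and deliberately share no code with the package internals.

# density of a member-set pair on a weight matrix, by exhaustive pair sum
ref_density <- function(W, xs, ys) {
  total <- 0
  for (i in xs) for (j in ys) total <- total + W[i, j]
  total / (length(xs) * length(ys))
}

# mean edge weight from one vertex into the opposite member set
ref_contribution_x <- function(W, v, ys) {
  s <- 0
  for (j in ys) s <- s + W[v, j]
  s / length(ys)
}
ref_contribution_y <- function(W, v, xs) {
  s <- 0
  for (i in xs) s <- s + W[i, v]
  s / length(xs)
}

ref_alpha <- function(size, C, tau) {
  m <- size + tau + 1
  lambda <- max(1, C / m^2)
  1 - 1 / (lambda * m)
}

# step-by-step transliteration of the seed-and-grow pseudocode; returns a list
# of BiNets with member names, seed, density and a per-step trace
ref_bcm <- function(W, C, tau, beta) {
  xn <- rownames(W)
  yn <- colnames(W)
  edges <- NULL
  for (i in seq_along(xn)) {
    for (j in seq_along(yn)) {
      if (W[i, j] > 0) {
        edges <- rbind(edges, data.frame(
          x = xn[i], y = yn[j], w = W[i, j], stringsAsFactors = FALSE
        ))
      }
    }
  }
  edges <- edges[order(-edges$w, edges$x, edges$y), ]
  w_max <- edges$w[1]
  selected <- character()
  out <- list()
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    if (e$w < beta * w_max) break
    if (paste(e$x, e$y) %in% selected) next
    selected <- c(selected, paste(e$x, e$y))
    xs <- e$x
    ys <- e$y
    trace <- NULL
    repeat {
      cand_x <- setdiff(xn, xs)
      cand_y <- setdiff(yn, ys)
      best_x <- -Inf
      best_y <- -Inf
      p <- q <- NA
      for (v in cand_x) { # sorted names: first strict max = smallest id
        cv <- ref_contribution_x(W, v, ys)
        if (cv > best_x) {
          best_x <- cv
          p <- v
        }
      }
      for (v in cand_y) {
        cv <- ref_contribution_y(W, v, xs)
        if (cv > best_y) {
          best_y <- cv
          q <- v
        }
      }
      d <- ref_density(W, xs, ys)
      if (best_x > best_y) {
        a <- ref_alpha(length(xs), C, tau)
        if (is.finite(best_x) && best_x >= a * d) {
          for (j in ys) if (W[p, j] > 0) selected <- c(selected, paste(p, j))
          xs <- c(xs, p)
          trace <- rbind(trace, data.frame(
            vertex = p, side = "x", contribution = best_x, alpha = a,
            stringsAsFactors = FALSE
          ))
        } else {
          break
        }
      } else {
        a <- ref_alpha(length(ys), C, tau)
        if (is.finite(best_y) && best_y >= a * d) {
          for (i in xs) if (W[i, q] > 0) selected <- c(selected, paste(i, q))
          ys <- c(ys, q)
          trace <- rbind(trace, data.frame(
            vertex = q, side = "y", contribution = best_y, alpha = a,
            stringsAsFactors = FALSE
          ))
        } else {
          break
        }
      }
    }
    out[[length(out) + 1]] <- list(
      seed = c(e$x, e$y), seed_weight = e$w, xs = xs, ys = ys,
      density = ref_density(W, xs, ys), trace = trace
    )
  }
  out
}

# exhaustive best-first agglomerative merge; clusters tracked as binet-id sets
ref_greedy_merge <- function(W, binets, threshold) {
  clusters <- lapply(seq_along(binets), function(i) {
    list(ids = i, xs = binets[[i]]$xs, ys = binets[[i]]$ys)
  })
  repeat {
    if (length(clusters) < 2) break
    clusters <- clusters[order(sapply(clusters, function(cl) min(cl$ids)))]
    best <- -Inf
    bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- ref_density(
          W,
          union(clusters[[i]]$xs, clusters[[j]]$xs),
          union(clusters[[i]]$ys, clusters[[j]]$ys)
        )
        if (d > best) {
          best <- d
          bi <- i
          bj <- j
        }
      }
    }
    if (best < threshold) break
    merged <- list(
      ids = sort(c(clusters[[bi]]$ids, clusters[[bj]]$ids)),
      xs = union(clusters[[bi]]$xs, clusters[[bj]]$xs),
      ys = union(clusters[[bi]]$ys, clusters[[bj]]$ys)
    )
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  clusters <- clusters[order(sapply(clusters, function(cl) min(cl$ids)))]
  lapply(clusters, `[[`, "ids")
}

# merge densities non-increasing from leaves to root: every internal child
# merged at a density >= its parent's merge density
dendrogram_monotone <- function(node) {
  if (!is.null(node$label)) {
    return(TRUE)
  }
  ok <- TRUE
  for (child in list(node$left, node$right)) {
    if (is.null(child$label)) {
      ok <- ok && child$merge_density >= node$merge_density - 1e-9 &&
        dendrogram_monotone(child)
    }
  }
  ok
}

# the documented 3x3 toy instance: two heavy blocks and a stray heavy edge
toy_graph_3x3 <- function() {
  edges <- expand.grid(
    x = c("x1", "x2", "x3"), y = c("y1", "y2", "y3"),
    stringsAsFactors = FALSE
  )
  edges$weight <- 0.1
  heavy <- c(
    "x1 y1" = 1.0, "x2 y1" = 0.95, "x1 y2" = 0.9, "x2 y2" = 0.9,
    "x3 y3" = 0.85
  )
  key <- paste(edges$x, edges$y)
  edges$weight[match(names(heavy), key)] <- heavy
  bipartite_graph(edges)
}

# weight matrix from a bipartite_graph without using package internals
ref_weight_matrix <- function(graph) {
  v <- graph_vertices(graph)
  W <- matrix(0, length(v$x), length(v$y), dimnames = list(v$x, v$y))
  for (k in seq_len(nrow(graph))) {
    W[graph$x[k], graph$y[k]] <- graph$weight[k]
  }
  W
}
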