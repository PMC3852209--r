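test_that("density and contribution match exhaustive oracles", {
  g <- simulate_bipartite_graph(6, 6, 0.7, c(0.3, 1), seed = 5)
  W <- ref_weight_matrix(g)
  v <- graph_vertices(g)
  set.seed(5)
  for (i in 1:20) {
    xs <- sample(v$x, sample(1:4, 1))
    ys <- sample(v$y, sample(1:4, 1))
    expect_equal(binet_density(g, xs, ys), ref_density(W, xs, ys),
      tolerance = 1e-12
    )
    cand_x <- setdiff(v$x, xs)[1]
    expect_equal(
      vertex_contribution(g, cand_x, "x", xs, ys),
      ref_contribution_x(W, cand_x, ys),
      tolerance = 1e-12
    )
    cand_y <- setdiff(v$y, ys)[1]
    expect_equal(
      vertex_contribution(g, cand_y, "y", xs, ys),
      ref_contribution_y(W, cand_y, xs),
      tolerance = 1e-12
    )
  }
})

test_that("density handles hand-checkable cases and errors", {
  g <- bipartite_graph(data.frame(
    x = c("a", "b"), y = c("u", "u"), weight = c(0.8, 0.6)
  ))
  expect_equal(binet_density(g, "a", "u"), 0.8)
  expect_equal(binet_density(g, c("a", "b"), "u"), 0.7)
  expect_error(binet_density(g, character(), "u"), "empty side")
  expect_equal(vertex_contribution(g, "b", "x", "a", "u"), 0.6)

  g2 <- bipartite_graph(
    data.frame(x = c("a", "a"), y = c("u", "v"), weight = c(0.9, 0.5)),
    x_vertices = c("a", "b")
  )
  expect_equal(vertex_contribution(g2, "b", "x", "a", c("u", "v")), 0)
})

test_that("alpha schedule matches its closed form in both regimes", {
  expect_equal(bcm_alpha(1, 100, 1), 0.97) # lambda > 1 branch
  expect_equal(bcm_alpha(9, 100, 1), 1 - 1 / 11) # lambda = 1 branch
  # 1 - (size+tau+1)/C before the crossover (decreasing), 1 - 1/(size+tau+1)
  # after it (increasing); crossover for C=100, tau=1 at size 8
  expect_true(all(diff(bcm_alpha(1:7, 100, 1)) < 0))
  expect_true(all(diff(bcm_alpha(8:20, 100, 1)) > 0))
  expect_true(all(bcm_alpha(1:20, 100, 1) > 0 & bcm_alpha(1:20, 100, 1) < 1))
})

test_that("mining a single-edge graph yields that edge as its own BiNet", {
  g <- bipartite_graph(data.frame(x = "t", y = "s", weight = 0.8))
  res <- bcm_mine(g, bcm_params())
  expect_equal(nrow(res), 1)
  expect_equal(res$density, 0.8)
  expect_identical(res$x_members[[1]], "t")
  expect_identical(res$y_members[[1]], "s")
  expect_equal(nrow(res$trace[[1]]), 0)
})

test_that("mining the documented 3x3 instance reproduces the hand trace", {
  res <- bcm_mine(toy_graph_3x3(), bcm_params(36, 2, 0.7))
  expect_equal(nrow(res), 2)
  # first BiNet: grow x2 (0.95 vs alpha 8/9), then y2 (0.9), then stop
  expect_identical(sort(res$x_members[[1]]), c("x1", "x2"))
  expect_identical(sort(res$y_members[[1]]), c("y1", "y2"))
  expect_equal(res$density[[1]], 0.9375, tolerance = 1e-9)
  tr <- res$trace[[1]]
  expect_identical(tr$vertex, c("x2", "y2"))
  expect_equal(tr$contribution, c(0.95, 0.9), tolerance = 1e-12)
  expect_equal(tr$alpha, c(8 / 9, 8 / 9), tolerance = 1e-12)
  expect_equal(tr$density_after, c(0.975, 0.9375), tolerance = 1e-12)
  # second BiNet: the stray heavy edge, no admissible growth
  expect_equal(res$seed_weight[[2]], 0.85)
  expect_equal(res$n_genes[[2]], 2)
})

test_that("mining agrees with the pseudocode oracle on random graphs", {
  for (s in 1:8) {
    g <- simulate_bipartite_graph(10, 10, 0.5, c(0.4, 1), seed = s)
    res <- bcm_mine(g, bcm_params(36, 2, 0.7))
    ref <- ref_bcm(ref_weight_matrix(g), 36, 2, 0.7)
    expect_equal(nrow(res), length(ref))
    for (k in seq_along(ref)) {
      expect_identical(res$x_members[[k]], ref[[k]]$xs)
      expect_identical(res$y_members[[k]], ref[[k]]$ys)
      expect_equal(res$density[[k]], ref[[k]]$density, tolerance = 1e-9)
      if (!is.null(ref[[k]]$trace)) {
        expect_identical(res$trace[[k]]$vertex, ref[[k]]$trace$vertex)
        expect_equal(res$trace[[k]]$alpha, ref[[k]]$trace$alpha,
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("every seed respects the beta pruning rule and Selected skipping", {
  for (s in c(2, 9, 17)) {
    g <- simulate_bipartite_graph(15, 15, 0.6, c(0.3, 1), seed = s)
    res <- bcm_mine(g, bcm_params(36, 2, 0.7))
    w_max <- attr(res, "w_max")
    expect_equal(w_max, max(g$weight))
    expect_true(all(res$seed_weight >= 0.7 * w_max))
    # a seed may never be an edge covered by an earlier BiNet's membership
    for (k in seq_len(nrow(res))[-1]) {
      for (j in seq_len(k - 1)) {
        covered <- res$seed_x[[k]] %in% res$x_members[[j]] &&
          res$seed_y[[k]] %in% res$y_members[[j]]
        expect_false(covered)
      }
    }
  }
})

test_that("replaying growth traces re-verifies the admission inequality", {
  g <- simulate_bipartite_graph(20, 20, 0.5, c(0.5, 1), seed = 1)
  res <- bcm_mine(g, bcm_params())
  for (k in seq_len(nrow(res))) {
    tr <- res$trace[[k]]
    xs <- res$seed_x[[k]]
    ys <- res$seed_y[[k]]
    dens <- res$seed_weight[[k]]
    for (i in seq_len(nrow(tr))) {
      expect_gte(tr$contribution[[i]], tr$alpha[[i]] * dens)
      if (tr$side[[i]] == "x") xs <- c(xs, tr$vertex[[i]]) else ys <- c(ys, tr$vertex[[i]])
      dens <- binet_density(g, xs, ys)
      expect_equal(dens, tr$density_after[[i]], tolerance = 1e-9)
    }
    expect_equal(dens, res$density[[k]], tolerance = 1e-9)
  }
})

test_that("mining is deterministic and vertices may be shared across BiNets", {
  g <- simulate_bipartite_graph(12, 12, 0.8, c(0.6, 1), seed = 4)
  r1 <- bcm_mine(g, bcm_params())
  r2 <- bcm_mine(g, bcm_params())
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))

  # hand-built instance where the second BiNet reuses vertices of the first
  g2 <- bipartite_graph(data.frame(
    x = c("x1", "x2", "x1"), y = c("y1", "y2", "y2"),
    weight = c(1.0, 0.98, 0.97)
  ))
  res <- bcm_mine(g2, bcm_params(36, 2, 0.7))
  expect_equal(nrow(res), 2)
  expect_identical(res$x_members[[1]], "x1")
  expect_identical(sort(res$y_members[[1]]), c("y1", "y2"))
  expect_identical(sort(res$x_members[[2]]), c("x1", "x2"))
  expect_identical(res$y_members[[2]], "y2")
})

test_that("distinct-gene filtering counts the union of both sides", {
  binets <- list(
    list(
      seed_x = "g1", seed_y = "g1", seed_weight = 0.9,
      x_members = paste0("g", 1:5), y_members = paste0("g", 1:5),
      density = 0.9, trace = NULL
    ),
    list(
      seed_x = "t1", seed_y = "s1", seed_weight = 0.9,
      x_members = paste0("t", 1:6), y_members = paste0("s", 1:5),
      density = 0.8, trace = NULL
    )
  )
  res <- binetminer:::new_bcm_result(
    lapply(binets, function(b) {
      b$trace <- tibble::tibble()
      b
    }),
    bcm_params(), 0.9, 0L
  )
  expect_equal(res$n_genes, c(5, 11))
  kept <- filter_min_genes(res, 10)
  expect_equal(kept$binet_id, 2L)
  # census equals a brute-force union count
  expect_equal(
    res$n_genes,
    vapply(binets, function(b) length(unique(c(b$x_members, b$y_members))), 1L)
  )
})

test_that("empty graphs mine to an empty result", {
  g <- bipartite_graph(
    data.frame(x = character(), y = character(), weight = double()),
    x_vertices = "a", y_vertices = "b"
  )
  res <- bcm_mine(g, bcm_params())
  expect_equal(nrow(res), 0)
})

test_that("parameter validation enforces the schedule precondition", {
  expect_error(bcm_params(C = 16, tau = 2), "larger than")
  expect_error(bcm_params(beta = 0), "beta")
  expect_error(bcm_params(tau = -1), "tau")
  expect_silent(bcm_params(C = 17, tau = 2))
})
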