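make_paired <- function(seed = 11, n_genes = 8, n_samples = 10, shift = 0) {
  set.seed(seed)
  tv <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
    dimnames = list(paste0("T", 1:n_genes), paste0("S", 1:n_samples))
  )
  sv <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
    dimnames = list(paste0("G", 1:n_genes), paste0("S", 1:n_samples))
  ) + shift
  paired_expression(as_expression_tibble(tv), as_expression_tibble(sv))
}

test_that("median matching aligns global medians and is idempotent", {
  paired <- make_paired(shift = 3.7)
  out <- median_match_normalize(paired)
  expect_equal(
    median(expr_values(out$stroma)), median(expr_values(out$tumor)),
    tolerance = 1e-12
  )
  expect_identical(out$tumor, paired$tumor)
  # a pure shift leaves within-matrix ranks untouched
  expect_identical(
    order(expr_values(out$stroma)), order(expr_values(paired$stroma))
  )
  again <- median_match_normalize(out)
  expect_equal(expr_values(again$stroma), expr_values(out$stroma),
    tolerance = 1e-12
  )
})

test_that("a stroma matrix equal to tumor plus a constant maps back exactly", {
  set.seed(4)
  tv <- matrix(rnorm(50), 5, 10,
    dimnames = list(paste0("T", 1:5), paste0("S", 1:10))
  )
  paired <- paired_expression(
    as_expression_tibble(tv), as_expression_tibble(tv + 2)
  )
  out <- median_match_normalize(paired)
  expect_equal(expr_values(out$stroma), expr_values(out$tumor),
    tolerance = 1e-12
  )
  # equal medians already: unchanged
  same <- median_match_normalize(paired_expression(
    as_expression_tibble(tv), as_expression_tibble(tv)
  ))
  expect_equal(expr_values(same$stroma), tv, tolerance = 1e-15)
})

test_that("low-variation filtering removes the right genes in both modes", {
  set.seed(1)
  samples <- paste0("S", 1:20)
  # quantile mode: variances 1..10 by construction
  rows <- lapply(1:10, function(k) sqrt(k) * scale(rnorm(20))[, 1])
  mat <- do.call(rbind, rows) # row k has variance exactly k
  dimnames(mat) <- list(paste0("g", 1:10), samples)
  out <- filter_low_variation(as_expression_tibble(mat),
    threshold = 0.2, mode = "quantile"
  )
  expect_setequal(out$gene, paste0("g", 3:10))

  # cv mode: mean 10 sd 5 kept at 0.2; constant profile always removed
  profile <- scale(rnorm(20))[, 1] * 5 + 10
  cv_mat <- rbind(kept = profile, flat = rep(3, 20))
  colnames(cv_mat) <- samples
  out <- filter_low_variation(as_expression_tibble(cv_mat), 0.2, "cv")
  expect_identical(out$gene, "kept")

  # exactly-zero-mean gene treated as zero-variation in cv mode
  zm <- rbind(zero_mean = rep(c(-1, 1), 10), ok = profile)
  colnames(zm) <- samples
  expect_identical(
    filter_low_variation(as_expression_tibble(zm), 0.2, "cv")$gene, "ok"
  )

  expect_warning(
    filter_low_variation(as_expression_tibble(cv_mat[2, , drop = FALSE]),
      0.2, "cv"
    ),
    "all genes removed"
  )
})

test_that("pearson correlation matches hand values and a two-pass oracle", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")

  two_pass <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    expect_equal(pearson_cor(x, y), two_pass(x, y), tolerance = 1e-12)
  }
})

test_that("co-expression graph keeps exactly the above-threshold pairs", {
  set.seed(5)
  z <- rnorm(30)
  tv <- rbind(T1 = z + rnorm(30, sd = 0.1), T2 = rnorm(30))
  sv <- rbind(G1 = z + rnorm(30, sd = 0.1), G2 = rnorm(30))
  colnames(tv) <- colnames(sv) <- paste0("S", 1:30)
  paired <- paired_expression(as_expression_tibble(tv), as_expression_tibble(sv))
  g <- build_coexpression_graph(paired, min_weight = 0.9)
  expect_equal(nrow(g), 1)
  expect_identical(g$x, "T1")
  expect_identical(g$y, "G1")
  expect_gt(g$weight, 0.9)

  expect_warning(
    empty <- build_coexpression_graph(paired, min_weight = 0.9995),
    "no correlations"
  )
  expect_equal(nrow(empty), 0)
})

test_that("graph construction is symmetric under swapping tissues", {
  sim <- simulate_paired_expression(15, 12, 80, list(module_spec(5, 5, 0.8)),
    seed = 3
  )
  fwd <- build_coexpression_graph(
    paired_expression(sim$tumor, sim$stroma),
    min_weight = 0.5
  )
  rev <- build_coexpression_graph(
    paired_expression(sim$stroma, sim$tumor),
    min_weight = 0.5
  )
  expect_equal(
    dplyr::arrange(tibble::tibble(x = fwd$x, y = fwd$y, w = fwd$weight), x, y),
    dplyr::arrange(tibble::tibble(x = rev$y, y = rev$x, w = rev$weight), x, y)
  )
})

test_that("blockwise correlation equals the naive all-pairs computation", {
  sim <- simulate_paired_expression(23, 17, 40, list(module_spec(6, 6, 0.7)),
    seed = 9
  )
  paired <- paired_expression(sim$tumor, sim$stroma)
  small_blocks <- build_coexpression_graph(paired, 0.4, block_size = 5L)
  one_block <- build_coexpression_graph(paired, 0.4, block_size = 1000L)
  expect_equal(
    as.data.frame(small_blocks[1:3]), as.data.frame(one_block[1:3])
  )
})

test_that("planted-module pairs dominate the retained edge set", {
  sim <- simulate_paired_expression(40, 40, 200, list(module_spec(15, 15, 0.8)),
    seed = 7
  )
  g <- build_coexpression_graph(
    median_match_normalize(paired_expression(sim$tumor, sim$stroma)),
    min_weight = 0.5
  )
  m <- sim$truth$modules[[1]]
  member_edge <- g$x %in% m$tumor_genes & g$y %in% m$stroma_genes
  expect_gte(mean(member_edge), 0.95)
})
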