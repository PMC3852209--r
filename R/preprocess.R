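#' Expression tibbles and paired-tissue datasets
#'
#' Expression data travel as wide tibbles: a `gene` column of unique ids plus
#' one numeric column per sample (log-scale intensities, no missing values).
#' `expr_values()` extracts the genes-by-samples matrix; `as_expression_tibble()`
#' converts such a matrix back. `paired_expression()` bundles a tumor and a
#' stroma tibble whose sample columns must be identical and identically
#' ordered (matched specimen pairs).
#'
#' @param expr an expression tibble.
#' @return `expr_values()`: a numeric matrix with gene rownames.
#' @export
expr_values <- function(expr) {
  expr <- validate_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  m
}

#' @rdname expr_values
#' @param mat genes-by-samples numeric matrix with row and column names.
#' @export
as_expression_tibble <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(mat)), tibble::as_tibble(mat))
}

#' @rdname expr_values
#' @param tumor,stroma expression tibbles over the same ordered samples.
#' @export
paired_expression <- function(tumor, stroma) {
  tumor <- validate_expression(tumor)
  stroma <- validate_expression(stroma)
  if (!identical(names(tumor)[-1], names(stroma)[-1])) {
    abort("tumor and stroma sample columns must be identical and identically ordered")
  }
  structure(list(tumor = tumor, stroma = stroma), class = "paired_expression")
}

validate_expression <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (!nrow(expr) || ncol(expr) < 2) abort("expression matrix is empty")
  if (names(expr)[[1]] != "gene") names(expr)[[1]] <- "gene"
  expr$gene <- as.character(expr$gene)
  if (anyDuplicated(expr$gene)) {
    dup <- which(duplicated(expr$gene))[[1]]
    abort(sprintf("duplicate gene id '%s' at row %d", expr$gene[[dup]], dup))
  }
  vals <- expr[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, TRUE))) abort("non-numeric expression column")
  if (anyNA(vals)) abort("missing values in expression matrix")
  expr
}

#' Median-match normalization between tissues
#'
#' Applies a single global offset to the stroma matrix so that the median over
#' all stroma entries equals the median over all tumor entries. A pure shift
#' (scale fixed at 1) changes neither the rank order within each matrix nor
#' any linear relationship between gene profiles; it only aligns the two
#' separately normalized tissues on a common intensity scale. Idempotent.
#'
#' @param paired a [paired_expression()] dataset.
#' @return The dataset with stroma shifted; tumor is untouched.
#' @export
median_match_normalize <- function(paired) {
  stopifnot(inherits(paired, "paired_expression"))
  tv <- expr_values(paired$tumor)
  sv <- expr_values(paired$stroma)
  shift <- median(tv) - median(sv)
  paired_expression(paired$tumor, as_expression_tibble(sv + shift))
}

#' Remove genes with low expression variation
#'
#' Low-variation profiles bias correlation estimates and are removed before
#' network construction. Two readings of a "< 20% variation" filter are
#' supported: `mode = "cv"` removes genes whose coefficient of variation
#' (sd / |mean|) is below `threshold` (genes with zero mean count as
#' zero-variation); `mode = "quantile"` removes the bottom `threshold`
#' fraction of genes ranked by variance.
#'
#' @param expr an expression tibble.
#' @param threshold filter level in (0, 1); default 0.2.
#' @param mode `"cv"` (default) or `"quantile"`.
#' @return The filtered expression tibble (sample order unchanged).
#' @export
filter_low_variation <- function(expr, threshold = 0.2,
                                 mode = c("cv", "quantile")) {
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold < 1)) abort("threshold must be in (0, 1)")
  expr <- validate_expression(expr)
  vals <- expr_values(expr)
  keep <- if (mode == "cv") {
    mu <- rowMeans(vals)
    s <- apply(vals, 1, sd)
    cv <- ifelse(mu == 0, 0, s / abs(mu))
    cv >= threshold
  } else {
    v <- apply(vals, 1, var)
    n_drop <- floor(threshold * nrow(vals))
    rank(v, ties.method = "first") > n_drop
  }
  if (!any(keep)) {
    warn("all genes removed by the low-variation filter; returning empty matrix")
  }
  expr[keep, , drop = FALSE]
}

#' Pearson correlation between two expression profiles
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be constant
#'   (constant profiles make the correlation undefined and should have been
#'   removed by [filter_low_variation()]).
#' @return The sample Pearson correlation, in [-1, 1].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant profile")
  }
  cor(x, y)
}

#' Build the tumor-stroma co-expression bipartite graph
#'
#' Computes the Pearson correlation \eqn{\rho_{i,j}} between every tumor gene
#' profile and every stroma gene profile across the matched samples, and keeps
#' an edge wherever the (signed, by default) correlation is at least
#' `min_weight`, with the correlation as edge weight. Correlations below the
#' threshold are absent edges and contribute 0 to all downstream density
#' sums. With `absolute = TRUE` the weight is \eqn{|\rho|} (exploratory; the
#' density bound presupposes nonnegative weights either way).
#'
#' Correlations are computed blockwise over tumor genes to bound memory; the
#' result is identical to the naive all-pairs computation.
#'
#' @param paired a normalized, variance-filtered [paired_expression()].
#' @param min_weight edge-inclusion threshold, in (0, 1); default 0.6.
#' @param absolute use `|rho|` as the weight.
#' @param prune drop vertices with no retained edges from the vertex lists.
#' @param block_size tumor genes per correlation block.
#' @return A [bipartite_graph()]; `x` = tumor genes, `y` = stroma genes.
#'   Attribute `meta` records the thresholds and counts used.
#' @export
build_coexpression_graph <- function(paired, min_weight = 0.6,
                                     absolute = FALSE, prune = FALSE,
                                     block_size = 512L) {
  stopifnot(inherits(paired, "paired_expression"))
  if (!(min_weight > 0 && min_weight < 1)) abort("min_weight must be in (0, 1)")
  tv <- expr_values(paired$tumor)
  sv <- expr_values(paired$stroma)
  if (ncol(tv) < 3) abort("need at least 3 matched samples")
  if (any(apply(tv, 1, sd) == 0) || any(apply(sv, 1, sd) == 0)) {
    abort("constant gene profile found; run filter_low_variation() first")
  }
  st <- t(sv)
  blocks <- split(seq_len(nrow(tv)), ceiling(seq_len(nrow(tv)) / block_size))
  edges <- purrr::map_dfr(blocks, function(rows) {
    r <- cor(t(tv[rows, , drop = FALSE]), st)
    w <- if (absolute) abs(r) else r
    hit <- which(w >= min_weight, arr.ind = TRUE)
    tibble::tibble(
      x = rownames(tv)[rows][hit[, 1]],
      y = rownames(sv)[hit[, 2]],
      weight = pmin(w[hit], 1) # guard against correlation rounding above 1
    )
  })
  if (!nrow(edges)) {
    warn("no correlations at or above min_weight; graph has no edges")
  }
  xv <- if (prune) unique(edges$x) else rownames(tv)
  yv <- if (prune) unique(edges$y) else rownames(sv)
  g <- bipartite_graph(edges, x_vertices = xv, y_vertices = yv)
  attr(g, "meta") <- list(
    min_weight = min_weight, absolute = absolute, prune = prune,
    n_samples = ncol(tv), n_tumor_genes = nrow(tv), n_stroma_genes = nrow(sv),
    n_edges = nrow(g)
  )
  g
}
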