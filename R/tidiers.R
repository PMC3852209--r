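#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a BCM mining result
#'
#' @param x a `bcm_result`.
#' @param ... unused.
#' @return One row per BiNet with scalar columns only (members and traces
#'   dropped).
#' @exportS3Method generics::tidy
tidy.bcm_result <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "binet_id", "seed_x", "seed_y", "seed_weight", "n_x", "n_y", "n_genes",
    "density"
  )]
}

#' @rdname tidy.bcm_result
#' @exportS3Method generics::glance
glance.bcm_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_binets = nrow(x),
    w_max = attr(x, "w_max"),
    n_selected_edges = attr(x, "n_selected_edges"),
    C = p$C, tau = p$tau, beta = p$beta,
    density_bound = density_bound(p$C, p$tau),
    mean_density = if (nrow(x)) mean(x$density) else NA_real_
  )
}

#' Tidy a log-rank test result
#'
#' @param x a `logrank_result`.
#' @param ... unused.
#' @return One row per group: size, observed and expected event counts.
#' @exportS3Method generics::tidy
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(
    group = seq_along(x$group_sizes),
    n = x$group_sizes,
    observed = x$observed,
    expected = x$expected
  )
}

#' @rdname tidy.logrank_result
#' @exportS3Method generics::glance
glance.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = 1L, p.value = x$p_value)
}

#' Tidy a BiNet merge
#'
#' @param x a `binet_merge`.
#' @param ... unused.
#' @return One row per macro network with scalar columns only.
#' @exportS3Method generics::tidy
tidy.binet_merge <- function(x, ...) {
  x$macro[, c("macro_id", "n_binets", "n_x", "n_y", "density")]
}

#' @rdname tidy.binet_merge
#' @exportS3Method generics::glance
glance.binet_merge <- function(x, ...) {
  tibble::tibble(
    n_macro = nrow(x$macro),
    n_binets = sum(x$macro$n_binets),
    threshold = x$threshold,
    min_multi_density = if (any(x$macro$n_binets > 1)) {
      min(x$macro$density[x$macro$n_binets > 1])
    } else {
      NA_real_
    }
  )
}

#' Summaries of a BiNet evaluation
#'
#' @param x a `binet_evaluation`.
#' @param ... unused.
#' @return `glance()`: one row per cohort with the count of significant
#'   BiNets, plus the count significant in at least one cohort.
#' @exportS3Method generics::glance
glance.binet_evaluation <- function(x, ...) {
  dplyr::mutate(
    attr(x, "by_cohort"),
    n_significant_any = attr(x, "n_significant_any"),
    alpha = attr(x, "alpha")
  )
}
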