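#' Analytic lower bound on the final-density / seed-weight ratio
#'
#' For a BiNet grown under the schedule of [bcm_alpha()] the ratio of final
#' density to seed-edge weight, \eqn{F = f(s,t)/f(1,1)}, is bounded below by
#' a closed-form constant depending only on `C` and `tau`. Telescoping the
#' per-step ratio bounds over each side gives, with \eqn{s = \sqrt C} and
#' \eqn{k = \max(0, \lceil s - \tau - 1 \rceil - 1)} the number of growth
#' steps taken while the schedule is in its \eqn{\lambda > 1} regime,
#' \deqn{F \ge \left(\frac{2C - \tau - 2}{2C}\right)^{2k}
#'   \left(\frac{s - \tau - 1}{s - \tau}\right)^2.}
#' The two factors come from the pre-crossover product of per-step ratios
#' (each at least \eqn{(2C - \tau - 2)/(2C)}) and the telescoped tail of the
#' post-crossover product, squared because both sides grow.
#'
#' Non-perfect-square `C` is handled through the real square root and the
#' ceiling in `k`.
#'
#' @param C,tau schedule parameters; `C > (tau + 2)^2` required.
#' @return The bound, a real in (0, 1).
#' @export
#' @examples
#' density_bound(100, 1) # ~ 0.64
#' density_bound(36, 2) # defaults used for the tumor-stroma analysis
density_bound <- function(C, tau) {
  if (tau < 0 || tau != round(tau)) abort("tau must be a nonnegative integer")
  if (C <= (tau + 2)^2) abort("C must be larger than (tau + 2)^2")
  s <- sqrt(C)
  k <- max(0, ceiling(s - tau - 1) - 1)
  ((2 * C - tau - 2) / (2 * C))^(2 * k) * ((s - tau - 1) / (s - tau))^2
}

#' Verify the density guarantee of a mining result
#'
#' Recomputes every BiNet's density from the graph, forms the ratio to its
#' seed-edge weight, and compares against [density_bound()] for the
#' parameters the result was mined with.
#'
#' @param result a `bcm_result` from [bcm_mine()].
#' @param graph the [bipartite_graph()] it was mined from.
#' @param tol numerical slack on the bound comparison.
#' @return A tibble with per-BiNet `density`, `seed_weight`, `ratio`, `bound`
#'   and `pass`; attribute `overall_pass` is `TRUE` iff every ratio is at
#'   least the bound (within `tol`).
#' @export
verify_density_bound <- function(result, graph, tol = 1e-9) {
  stopifnot(inherits(result, "bcm_result"), inherits(graph, "bipartite_graph"))
  params <- attr(result, "params")
  bound <- density_bound(params$C, params$tau)
  dens <- purrr::map2_dbl(
    result$x_members, result$y_members,
    ~ binet_density(graph, .x, .y)
  )
  if (nrow(result) && max(abs(dens - result$density)) > 1e-6) {
    abort("stored densities do not match this graph; wrong graph/result pair?")
  }
  out <- tibble::tibble(
    binet_id = result$binet_id,
    density = dens,
    seed_weight = result$seed_weight,
    ratio = dens / result$seed_weight,
    bound = bound,
    pass = dens / result$seed_weight >= bound - tol
  )
  attr(out, "overall_pass") <- all(out$pass)
  out
}
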