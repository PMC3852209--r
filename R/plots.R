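#' Plot a BCM mining result
#'
#' Scatter of BiNet size (distinct genes) against final density, with the
#' analytic density floor `bound * seed_weight` implied range shaded by the
#' seed weight colour scale.
#'
#' @param object a `bcm_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bcm_result <- function(object, ...) {
  p <- attr(object, "params")
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$n_genes, y = .data$density, colour = .data$seed_weight)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(
      yintercept = density_bound(p$C, p$tau) * p$beta * attr(object, "w_max"),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "distinct genes in BiNet", y = "density",
      colour = "seed weight",
      title = sprintf("BiNets mined at C = %d, tau = %d, beta = %g",
                      p$C, p$tau, p$beta),
      subtitle = "dashed: analytic density floor for the lightest admissible seed"
    )
}

#' Plot a BiNet evaluation
#'
#' Histogram of log-rank p-values per cohort; the significance level is drawn
#' as a dashed line.
#'
#' @param object a `binet_evaluation`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.binet_evaluation <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "alpha"), linetype = "dashed") +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "log-rank p-value", y = "BiNets")
}

#' Plot macro-network densities
#'
#' @param object a `binet_merge`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.binet_merge <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = factor(.data$macro_id), y = .data$density,
                 fill = factor(.data$n_binets))
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "macro network", y = "density", fill = "BiNets merged",
      subtitle = "dashed: merge density threshold"
    )
}

#' Kaplan-Meier curves for a two-group split
#'
#' @param cohort a [survival_cohort()].
#' @param labels group labels (e.g. from [two_group_split()]).
#' @return A ggplot object with one survival step curve per group.
#' @export
plot_km_curves <- function(cohort, labels) {
  stopifnot(inherits(cohort, "survival_cohort"))
  fit <- survival::survfit(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = cohort$time, event = cohort$event,
                      g = factor(labels))
  )
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(
    time = fit$time, surv = fit$surv,
    group = sub("^g=", "", strata)
  ) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival fraction", colour = "group")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
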