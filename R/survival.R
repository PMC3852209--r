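#' Survival cohort container
#'
#' Bundles per-sample follow-up (`sample_id`, nonnegative `time`, binary
#' `event`; 1 = event observed, 0 = censored) with a samples-by-genes feature
#' matrix used for patient stratification.
#'
#' @param data data frame with columns `sample_id`, `time`, `event`.
#' @param features numeric matrix, rows named by `sample_id` in the same
#'   order, columns named by unique gene ids.
#' @return A `survival_cohort` tibble with the feature matrix attached as the
#'   `features` attribute.
#' @export
survival_cohort <- function(data, features) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("sample_id", "time", "event") %in% names(data)))
  if (any(data$time < 0)) abort("survival times must be nonnegative")
  if (!all(data$event %in% c(0, 1))) abort("event must be 0 or 1")
  stopifnot(is.matrix(features), nrow(features) == nrow(data))
  if (!identical(rownames(features), as.character(data$sample_id))) {
    abort("feature matrix rows must match sample_id order")
  }
  if (anyDuplicated(colnames(features))) {
    abort("feature column (gene) ids must be unique")
  }
  data$event <- as.integer(data$event)
  structure(data,
    features = features,
    class = c("survival_cohort", class(tibble::tibble()))
  )
}

#' @rdname survival_cohort
#' @param cohort a `survival_cohort`.
#' @export
cohort_features <- function(cohort) attr(cohort, "features")

#' Per-patient feature matrix for one BiNet
#'
#' Restricts the cohort's feature matrix to the BiNet's combined gene set
#' (union of tumor and stroma sides). Genes absent from the cohort are
#' dropped with a message; if none overlap, a `binetminer_no_overlap` error
#' is raised (callers evaluating many BiNets catch it and record a skip).
#'
#' @param x_members,y_members the BiNet's member gene sets.
#' @param cohort a [survival_cohort()].
#' @return Samples-by-genes matrix with attribute `n_missing`.
#' @export
binet_features <- function(x_members, y_members, cohort) {
  genes <- union(x_members, y_members)
  present <- intersect(genes, colnames(cohort_features(cohort)))
  n_missing <- length(genes) - length(present)
  if (!length(present)) {
    abort(
      "no BiNet genes present among cohort features",
      class = "binetminer_no_overlap"
    )
  }
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "%d of %d BiNet genes absent from cohort; dropped", n_missing,
      length(genes)
    ))
  }
  out <- cohort_features(cohort)[, present, drop = FALSE]
  attr(out, "n_missing") <- n_missing
  out
}

#' Two-group patient split by city-block K-means
#'
#' K = 2 clustering under the city-block (L1) distance with component-wise
#' median centroid update (the L1-optimal centroid), repeated from
#' `n_restarts` random initializations; the restart with the lowest total
#' within-cluster L1 cost wins (ties to the first found). Deterministic given
#' `seed`. If all feature rows are identical the split is degenerate and no
#' survival comparison should be made.
#'
#' @param features samples-by-features numeric matrix (>= 2 samples).
#' @param n_restarts random restarts; default 100.
#' @param seed integer seed.
#' @param max_iter iteration cap per restart.
#' @return A `two_group_split` list: `labels` (1/2 per sample), `inertia`
#'   (total within-cluster L1 cost), `n_restarts`, `degenerate`, `seed`.
#' @export
two_group_split <- function(features, n_restarts = 100, seed = NULL,
                            max_iter = 100) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) abort("need at least 2 samples to split")
  if (all(features == rep(features[1, ], each = n))) {
    return(structure(
      list(labels = rep(1L, n), inertia = 0, n_restarts = 0L,
           degenerate = TRUE, seed = seed),
      class = "two_group_split"
    ))
  }
  l1 <- function(centroid) rowSums(abs(sweep(features, 2, centroid)))
  run_once <- function() {
    init <- sample.int(n, 2)
    c1 <- features[init[[1]], ]
    c2 <- features[init[[2]], ]
    labels <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d1 <- l1(c1)
      d2 <- l1(c2)
      new_labels <- ifelse(d1 <= d2, 1L, 2L)
      for (g in 1:2) { # re-seed an emptied cluster with the worst-fit sample
        if (!any(new_labels == g)) {
          far <- which.max(pmin(d1, d2))
          new_labels[[far]] <- g
        }
      }
      if (identical(new_labels, labels) && it > 1) break
      labels <- new_labels
      c1 <- apply(features[labels == 1L, , drop = FALSE], 2, median)
      c2 <- apply(features[labels == 2L, , drop = FALSE], 2, median)
    }
    cost <- sum(pmin(l1(c1), l1(c2)))
    list(labels = labels, cost = cost)
  }
  best <- with_seed_if(seed, {
    runs <- purrr::map(seq_len(n_restarts), ~ run_once())
    runs[[which.min(purrr::map_dbl(runs, "cost"))]]
  })
  structure(
    list(
      labels = best$labels, inertia = best$cost,
      n_restarts = as.integer(n_restarts), degenerate = FALSE, seed = seed
    ),
    class = "two_group_split"
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of censored survival between two groups:
#' chi-square statistic \eqn{(\sum (O_1 - E_1))^2 / \sum V} over distinct
#' event times (censored samples leave the risk set at their censoring time)
#' with its upper-tail p-value on 1 df. Computed via [survival::survdiff()].
#'
#' @param time nonnegative follow-up times.
#' @param event binary event indicators (1 = event).
#' @param labels group labels with exactly 2 distinct values, both non-empty.
#' @return A `logrank_result` list: `statistic`, `p_value`, `group_sizes`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, labels) {
  stopifnot(length(time) == length(event), length(time) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("labels must define exactly 2 non-empty groups")
  sizes <- table(factor(labels, levels = groups))
  if (sum(event) == 0) {
    return(structure(
      list(
        statistic = 0, p_value = 1, group_sizes = as.integer(sizes),
        observed = c(0, 0), expected = c(0, 0)
      ),
      class = "logrank_result"
    ))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ g,
    data = data.frame(time = time, event = event, g = factor(labels))
  )
  structure(
    list(
      statistic = unname(fit$chisq),
      p_value = unname(pchisq(fit$chisq, df = 1, lower.tail = FALSE)),
      group_sizes = as.integer(sizes),
      observed = unname(fit$obs),
      expected = unname(fit$exp)
    ),
    class = "logrank_result"
  )
}

#' Evaluate BiNets as prognostic biomarkers across cohorts
#'
#' For every (BiNet, cohort) pair: restrict the cohort's features to the
#' BiNet's combined gene set, split the patients in two by
#' [two_group_split()], and test the survival difference with
#' [logrank_test()]. Group 1 is oriented as the better-outcome group (lower
#' event rate); orientation affects reporting only, not the statistic. Raw
#' p-values are reported by default — matching how per-BiNet significance
#' counts are usually quoted — with Benjamini-Hochberg adjustment available
#' via `p_adjust = "BH"`.
#'
#' @param result a `bcm_result` (typically after [filter_min_genes()]).
#' @param cohorts a named list of [survival_cohort()] objects (a bare cohort
#'   is treated as list(cohort = ...)).
#' @param n_restarts K-means restarts per evaluation.
#' @param seed integer seed; each (BiNet, cohort) evaluation gets a distinct
#'   seed derived from it.
#' @param standardize z-score each feature column before clustering.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha significance level for the summary counts; default 0.05.
#' @return A `binet_evaluation` tibble: one row per (BiNet, cohort) with
#'   group sizes, statistic, `p_value`, `significant` and `status`
#'   (`"ok"`, `"degenerate"` or `"no_overlap"`). Attributes: `by_cohort`
#'   (significant count per cohort) and `n_significant_any` (BiNets
#'   significant in at least one cohort).
#' @export
evaluate_binets <- function(result, cohorts, n_restarts = 100, seed = NULL,
                            standardize = FALSE, p_adjust = c("none", "BH"),
                            alpha = 0.05) {
  stopifnot(inherits(result, "bcm_result"))
  p_adjust <- match.arg(p_adjust)
  if (inherits(cohorts, "survival_cohort")) cohorts <- list(cohort = cohorts)
  stopifnot(length(cohorts) > 0, !is.null(names(cohorts)))

  if (!nrow(result)) {
    empty <- tibble::tibble(
      binet_id = integer(), cohort = character(), n_genes_used = integer(),
      n_missing = integer(), n1 = integer(), n2 = integer(),
      statistic = double(), p_value = double(), status = character(),
      significant = logical()
    )
    return(structure(empty,
      by_cohort = tibble::tibble(
        cohort = character(), n_evaluated = integer(), n_significant = integer()
      ),
      n_significant_any = 0L, alpha = alpha,
      class = c("binet_evaluation", class(tibble::tibble()))
    ))
  }
  grid <- tidyr::expand_grid(
    row = seq_len(nrow(result)), cohort = names(cohorts)
  )
  rows <- purrr::pmap(grid, function(row, cohort) {
    co <- cohorts[[cohort]]
    id <- result$binet_id[[row]]
    eval_seed <- if (is.null(seed)) NULL else {
      seed + (row - 1L) * length(cohorts) + match(cohort, names(cohorts))
    }
    feats <- tryCatch(
      suppressMessages(
        binet_features(result$x_members[[row]], result$y_members[[row]], co)
      ),
      binetminer_no_overlap = function(e) NULL
    )
    base <- tibble::tibble(
      binet_id = id, cohort = cohort,
      n_genes_used = NA_integer_, n_missing = NA_integer_,
      n1 = NA_integer_, n2 = NA_integer_,
      statistic = NA_real_, p_value = NA_real_, status = "no_overlap"
    )
    if (is.null(feats)) {
      return(base)
    }
    if (standardize) {
      keep <- apply(feats, 2, sd) > 0
      feats <- scale(feats[, keep, drop = FALSE])
    }
    base$n_genes_used <- ncol(feats)
    base$n_missing <- attr(feats, "n_missing") %||% 0L
    split <- two_group_split(feats, n_restarts = n_restarts, seed = eval_seed)
    if (split$degenerate) {
      base$status <- "degenerate"
      return(base)
    }
    lr <- logrank_test(co$time, co$event, split$labels)
    # orient group 1 = better outcome (lower event rate); reporting only
    rates <- vapply(1:2, function(g) mean(co$event[split$labels == g]), 0)
    ord <- order(rates)
    base$n1 <- lr$group_sizes[[ord[[1]]]]
    base$n2 <- lr$group_sizes[[ord[[2]]]]
    base$statistic <- lr$statistic
    base$p_value <- lr$p_value
    base$status <- "ok"
    base
  })
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "BH") {
    out <- dplyr::mutate(out,
      p_value = stats::p.adjust(.data$p_value, method = "BH"),
      .by = "cohort"
    )
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  by_cohort <- dplyr::summarise(out,
    n_evaluated = sum(!is.na(.data$p_value)),
    n_significant = sum(.data$significant),
    .by = "cohort"
  )
  n_any <- out |>
    dplyr::summarise(any_sig = any(.data$significant), .by = "binet_id") |>
    dplyr::pull("any_sig") |>
    sum()
  structure(out,
    by_cohort = by_cohort, n_significant_any = n_any, alpha = alpha,
    class = c("binet_evaluation", class(tibble::tibble()))
  )
}
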