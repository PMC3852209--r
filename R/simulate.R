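#' Specify a planted cross-tissue module
#'
#' @param tumor_size,stroma_size number of member genes on each side.
#' @param cross_cor target Pearson correlation, strictly in (0, 1), between any
#'   tumor member and any stroma member of the module.
#' @return A `module_spec` list.
#' @export
module_spec <- function(tumor_size, stroma_size, cross_cor) {
  stopifnot(tumor_size >= 1, stroma_size >= 1)
  if (!(cross_cor > 0 && cross_cor < 1)) {
    abort("cross_cor must be strictly between 0 and 1")
  }
  structure(
    list(
      tumor_size = as.integer(tumor_size),
      stroma_size = as.integer(stroma_size),
      cross_cor = cross_cor
    ),
    class = "module_spec"
  )
}

#' Simulate paired tumor/stroma expression with planted cross-tissue modules
#'
#' Generates two genes-by-samples matrices for matched specimens. Each planted
#' module shares one standard-normal latent factor \eqn{z_m} per sample across
#' both tissues; member gene profiles are \eqn{L z_m + \epsilon} with noise
#' \eqn{\epsilon \sim N(0, \sigma^2)} and loading \eqn{L} solving
#' \eqn{L^2/(L^2+\sigma^2) = \rho^*}, so the expected Pearson correlation
#' between any tumor member and any stroma member equals the module's target
#' `cross_cor`. Non-member genes are independent \eqn{N(0, \sigma^2)} noise.
#'
#' If `prognostic_module` is set, samples are split into good/poor outcome
#' groups at the median of that module's latent factor; the labels (and the
#' `hazard_ratio` / `censoring_fraction` settings) drive [simulate_survival()].
#'
#' @param n_tumor_genes,n_stroma_genes total gene counts per side.
#' @param n_samples number of matched sample pairs.
#' @param modules list of [module_spec()] objects (may be empty).
#' @param noise_sd background noise standard deviation (> 0).
#' @param prognostic_module index into `modules` whose latent factor carries
#'   prognostic signal, or `NULL` for a null cohort.
#' @param hazard_ratio hazard multiplier (>= 1) for the poor-outcome group.
#' @param censoring_fraction target fraction of censored samples, in [0, 1).
#' @param stroma_loading_scale multiplier on the stroma-side loading
#'   (1 = symmetric loadings; an exploratory extension).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A `paired_simulation` list with elements `tumor` and `stroma`
#'   (tibbles: `gene` column plus one column per sample), `truth` (module
#'   memberships, per-sample group labels, latent factors, seed) and `config`.
#' @export
#' @examples
#' sim <- simulate_paired_expression(
#'   n_tumor_genes = 30, n_stroma_genes = 30, n_samples = 40,
#'   modules = list(module_spec(5, 5, 0.8)), seed = 1
#' )
#' sim$truth$modules[[1]]$tumor_genes
simulate_paired_expression <- function(n_tumor_genes, n_stroma_genes, n_samples,
                                       modules = list(),
                                       noise_sd = 1,
                                       prognostic_module = NULL,
                                       hazard_ratio = 1,
                                       censoring_fraction = 0,
                                       stroma_loading_scale = 1,
                                       seed = NULL) {
  stopifnot(n_tumor_genes >= 1, n_stroma_genes >= 1, n_samples >= 2)
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  if (hazard_ratio < 1) abort("hazard_ratio must be >= 1")
  if (censoring_fraction < 0 || censoring_fraction >= 1) {
    abort("censoring_fraction must be in [0, 1)")
  }
  if (inherits(modules, "module_spec")) modules <- list(modules)
  if (sum(vapply(modules, `[[`, 1L, "tumor_size")) > n_tumor_genes ||
    sum(vapply(modules, `[[`, 1L, "stroma_size")) > n_stroma_genes) {
    abort("module gene counts exceed the corresponding side's total gene count")
  }
  if (!is.null(prognostic_module) &&
    (prognostic_module < 1 || prognostic_module > length(modules))) {
    abort("prognostic_module must index an entry of `modules`")
  }

  tumor_genes <- sprintf("TG%04d", seq_len(n_tumor_genes))
  stroma_genes <- sprintf("SG%04d", seq_len(n_stroma_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  out <- with_seed_if(seed, {
    tumor_mat <- matrix(rnorm(n_tumor_genes * n_samples, sd = noise_sd),
      n_tumor_genes, n_samples,
      dimnames = list(tumor_genes, sample_ids)
    )
    stroma_mat <- matrix(rnorm(n_stroma_genes * n_samples, sd = noise_sd),
      n_stroma_genes, n_samples,
      dimnames = list(stroma_genes, sample_ids)
    )
    latent <- matrix(0, length(modules), n_samples)
    next_t <- 1L
    next_s <- 1L
    memberships <- vector("list", length(modules))
    for (m in seq_along(modules)) {
      spec <- modules[[m]]
      z <- rnorm(n_samples)
      latent[m, ] <- z
      loading <- noise_sd * sqrt(spec$cross_cor / (1 - spec$cross_cor))
      tg <- tumor_genes[seq.int(next_t, length.out = spec$tumor_size)]
      sg <- stroma_genes[seq.int(next_s, length.out = spec$stroma_size)]
      next_t <- next_t + spec$tumor_size
      next_s <- next_s + spec$stroma_size
      tumor_mat[tg, ] <- tumor_mat[tg, , drop = FALSE] +
        loading * matrix(z, spec$tumor_size, n_samples, byrow = TRUE)
      stroma_mat[sg, ] <- stroma_mat[sg, , drop = FALSE] +
        stroma_loading_scale * loading *
          matrix(z, spec$stroma_size, n_samples, byrow = TRUE)
      memberships[[m]] <- list(
        tumor_genes = tg, stroma_genes = sg, cross_cor = spec$cross_cor
      )
    }
    list(tumor = tumor_mat, stroma = stroma_mat, latent = latent,
         memberships = memberships)
  })

  group_labels <- NULL
  if (!is.null(prognostic_module)) {
    z <- out$latent[prognostic_module, ]
    # poor outcome = 1 for samples above the median latent activity
    group_labels <- as.integer(z > median(z))
    names(group_labels) <- sample_ids
  }

  structure(
    list(
      tumor = as_expression_tibble(out$tumor),
      stroma = as_expression_tibble(out$stroma),
      truth = list(
        modules = out$memberships,
        group_labels = group_labels,
        latent = out$latent,
        generator_seed = seed
      ),
      config = list(
        n_tumor_genes = n_tumor_genes, n_stroma_genes = n_stroma_genes,
        n_samples = n_samples, noise_sd = noise_sd,
        prognostic_module = prognostic_module, hazard_ratio = hazard_ratio,
        censoring_fraction = censoring_fraction,
        stroma_loading_scale = stroma_loading_scale, seed = seed
      )
    ),
    class = "paired_simulation"
  )
}

#' Simulate a random weighted bipartite graph
#'
#' Each of the `n_x * n_y` potential edges is present independently with
#' probability `edge_prob`; weights are uniform on `weight_range`.
#'
#' @param n_x,n_y vertex counts on each side.
#' @param edge_prob edge probability, in (0, 1].
#' @param weight_range length-2 numeric, `0 < low <= high <= 1`.
#' @param seed integer seed.
#' @return A [bipartite_graph()].
#' @export
simulate_bipartite_graph <- function(n_x, n_y, edge_prob,
                                     weight_range = c(0.5, 1), seed = NULL) {
  stopifnot(n_x >= 1, n_y >= 1, length(weight_range) == 2)
  lo <- weight_range[[1]]
  hi <- weight_range[[2]]
  if (!(lo > 0 && lo <= hi && hi <= 1)) {
    abort("weight_range must satisfy 0 < low <= high <= 1")
  }
  if (!(edge_prob > 0 && edge_prob <= 1)) {
    abort("edge_prob must be in (0, 1]")
  }
  xv <- sprintf("x%03d", seq_len(n_x))
  yv <- sprintf("y%03d", seq_len(n_y))
  with_seed_if(seed, {
    present <- runif(n_x * n_y) < edge_prob
    w <- runif(n_x * n_y, lo, hi)
    idx <- which(present)
    edges <- tibble::tibble(
      x = xv[((idx - 1L) %% n_x) + 1L],
      y = yv[((idx - 1L) %/% n_x) + 1L],
      weight = w[idx]
    )
    bipartite_graph(edges, x_vertices = xv, y_vertices = yv)
  })
}

#' Simulate survival outcomes for a paired-expression simulation
#'
#' Event times are exponential with rate `baseline_hazard`, multiplied by the
#' simulation's `hazard_ratio` for poor-outcome samples (the median split of
#' the prognostic module's latent factor). Censoring is independent uniform on
#' `[0, T_max]`, with `T_max` solved numerically so the expected censored
#' fraction equals the configured `censoring_fraction`. Without a prognostic
#' module all samples share one hazard (a null cohort).
#'
#' @param sim a `paired_simulation` from [simulate_paired_expression()].
#' @param baseline_hazard exponential event rate of the good-outcome group.
#' @param seed integer seed.
#' @return A [survival_cohort()] whose feature matrix holds every simulated
#'   tumor and stroma gene (samples in rows, genes in columns).
#' @export
simulate_survival <- function(sim, baseline_hazard = 0.1, seed = NULL) {
  stopifnot(inherits(sim, "paired_simulation"), baseline_hazard > 0)
  cfg <- sim$config
  n <- cfg$n_samples
  labels <- sim$truth$group_labels %||% rep(0L, n)
  rates <- baseline_hazard * ifelse(labels == 1L, cfg$hazard_ratio, 1)

  surv <- with_seed_if(seed, {
    t_event <- rexp(n, rate = rates)
    if (cfg$censoring_fraction > 0) {
      t_max <- censoring_horizon(rates, cfg$censoring_fraction)
      t_cens <- runif(n, 0, t_max)
      tibble::tibble(
        time = pmin(t_event, t_cens),
        event = as.integer(t_event <= t_cens)
      )
    } else {
      tibble::tibble(time = t_event, event = 1L)
    }
  })

  tumor <- expr_values(sim$tumor)
  stroma <- expr_values(sim$stroma)
  features <- t(rbind(tumor, stroma))
  survival_cohort(
    tibble::tibble(
      sample_id = colnames(tumor),
      time = surv$time, event = surv$event
    ),
    features
  )
}

# internal: uniform-censoring horizon T_max such that the expected censored
# fraction over samples with exponential rates `rates` equals `target`.
# P(censored | rate r) = (1 - exp(-r * T)) / (r * T), decreasing in T from 1 to 0.
censoring_horizon <- function(rates, target) {
  frac <- function(t_max) mean((1 - exp(-rates * t_max)) / (rates * t_max)) - target
  hi <- 1 / min(rates)
  while (frac(hi) > 0) hi <- hi * 2
  uniroot(frac, lower = 1e-8, upper = hi, tol = 1e-10)$root
}
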