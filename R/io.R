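#' Read and write expression matrices as TSV
#'
#' Format: tab-delimited, header row of sample ids, first column `gene`
#' holding unique gene ids, remaining cells numeric. Readers reject rather
#' than coerce: duplicate gene ids, ragged rows and non-numeric cells fail
#' with the offending line.
#'
#' @param path file path.
#' @return `read_expression_tsv()`: an expression tibble.
#' @export
read_expression_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (!ncol(raw) || nrow(readr::problems(raw))) {
    abort(paste0("malformed expression TSV: ", path))
  }
  names(raw)[[1]] <- "gene"
  if (anyDuplicated(raw$gene)) {
    line <- which(duplicated(raw$gene))[[1]] + 1L # +1 for the header line
    abort(sprintf("duplicate gene id '%s' at line %d of %s",
                  raw$gene[[line - 1L]], line, path))
  }
  for (col in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) || anyNA(raw[[col]])) {
      at <- c(bad, which(is.na(raw[[col]])))[[1]]
      abort(sprintf("non-numeric or missing cell in column '%s' at line %d of %s",
                    col, at + 1L, path))
    }
    raw[[col]] <- v
  }
  validate_expression(raw)
}

#' @rdname read_expression_tsv
#' @param expr an expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(validate_expression(expr), path)
  invisible(path)
}

#' Read and write bipartite edge lists as TSV
#'
#' Columns: `tumor_gene`, `stroma_gene`, `weight`. A metadata JSON sidecar
#' (written by [write_graph_meta_json()]) carries the full vertex lists and
#' construction thresholds; without it, vertices are reconstructed from the
#' edges alone.
#'
#' @param path file path.
#' @param meta_path optional metadata JSON path.
#' @return `read_edges_tsv()`: a [bipartite_graph()].
#' @export
read_edges_tsv <- function(path, meta_path = NULL) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    tumor_gene = readr::col_character(),
    stroma_gene = readr::col_character(),
    weight = readr::col_double()
  ))
  if (nrow(readr::problems(edges)) || anyNA(edges)) {
    bad <- if (anyNA(edges)) which(!stats::complete.cases(edges))[[1]] + 1L else NA
    abort(sprintf("malformed edge TSV %s (line %s)", path, bad))
  }
  xv <- yv <- NULL
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    xv <- meta$x_vertices
    yv <- meta$y_vertices
  }
  g <- bipartite_graph(
    dplyr::rename(edges, x = "tumor_gene", y = "stroma_gene"),
    x_vertices = xv, y_vertices = yv
  )
  attr(g, "meta") <- meta$meta
  g
}

#' @rdname read_edges_tsv
#' @param graph a [bipartite_graph()].
#' @export
write_edges_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "bipartite_graph"))
  readr::write_tsv(
    tibble::tibble(
      tumor_gene = graph$x, stroma_gene = graph$y, weight = graph$weight
    ),
    path
  )
  invisible(path)
}

#' @rdname read_edges_tsv
#' @export
write_graph_meta_json <- function(graph, path) {
  stopifnot(inherits(graph, "bipartite_graph"))
  meta <- attr(graph, "meta")
  payload <- list(
    x_vertices = attr(graph, "x_vertices"),
    y_vertices = attr(graph, "y_vertices"),
    n_edges = nrow(graph),
    meta = meta,
    config_hash = rlang::hash(list(meta, nrow(graph)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write mining results as JSON
#'
#' Serializes every BiNet (seed edge, member sets, density, growth trace)
#' together with the mining parameters; `read_binets_json()` restores an
#' identical `bcm_result`.
#'
#' @param result a `bcm_result`.
#' @param path file path.
#' @export
write_binets_json <- function(result, path) {
  stopifnot(inherits(result, "bcm_result"))
  p <- attr(result, "params")
  payload <- list(
    params = list(C = p$C, tau = p$tau, beta = p$beta,
                  min_seed_weight = p$min_seed_weight),
    w_max = attr(result, "w_max"),
    n_selected_edges = attr(result, "n_selected_edges"),
    binets = purrr::pmap(
      result,
      function(binet_id, seed_x, seed_y, seed_weight, x_members, y_members,
               n_x, n_y, n_genes, density, trace) {
        list(
          binet_id = binet_id,
          seed = list(x = seed_x, y = seed_y, weight = seed_weight),
          x_members = x_members, y_members = y_members, density = density,
          trace = trace
        )
      }
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_binets_json
#' @export
read_binets_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- obj$params
  msw <- p$min_seed_weight
  if (!length(msw)) msw <- NULL # JSON null reads back as empty list
  params <- bcm_params(p$C, p$tau, p$beta, msw)
  binets <- purrr::map(obj$binets, function(b) {
    tr <- b$trace
    trace <- if (length(tr)) {
      purrr::map_dfr(tr, tibble::as_tibble)
    } else {
      steps_to_tibble(list())
    }
    list(
      seed_x = b$seed$x, seed_y = b$seed$y, seed_weight = b$seed$weight,
      x_members = as.character(unlist(b$x_members)),
      y_members = as.character(unlist(b$y_members)),
      density = b$density, trace = trace
    )
  })
  new_bcm_result(binets, params, obj$w_max, obj$n_selected_edges)
}

#' Write BiNets as GMT gene-set lines
#'
#' One line per BiNet: `binet_<id>` TAB description (density and the two
#' side memberships) TAB one gene per field (union of both sides).
#'
#' @param result a `bcm_result`.
#' @param path file path.
#' @export
write_gmt <- function(result, path) {
  stopifnot(inherits(result, "bcm_result"))
  lines <- purrr::pmap_chr(
    result[, c("binet_id", "x_members", "y_members", "density")],
    function(binet_id, x_members, y_members, density) {
      desc <- sprintf(
        "density=%s;tumor=%s;stroma=%s", format(density, digits = 10),
        paste(x_members, collapse = "|"), paste(y_members, collapse = "|")
      )
      paste(c(paste0("binet_", binet_id), desc, union(x_members, y_members)),
            collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the merge dendrogram as Newick
#'
#' @param merge a `binet_merge` from [merge_binets()].
#' @param path file path; one Newick line per macro network.
#' @export
write_dendrogram_newick <- function(merge, path) {
  writeLines(dendrogram_newick(merge), path)
  invisible(path)
}

#' Read and write survival tables as CSV
#'
#' Columns: `sample_id`, `time`, `event`.
#'
#' @param path file path.
#' @return `read_survival_csv()`: a tibble (attach features with
#'   [survival_cohort()]).
#' @export
read_survival_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer()
  ))
  if (nrow(readr::problems(tbl)) || anyNA(tbl)) {
    abort(paste0("malformed survival CSV: ", path))
  }
  if (!all(tbl$event %in% c(0L, 1L))) abort("event must be 0 or 1")
  tbl
}

#' @rdname read_survival_csv
#' @param cohort a [survival_cohort()] or plain survival tibble.
#' @export
write_survival_csv <- function(cohort, path) {
  readr::write_csv(
    tibble::tibble(
      sample_id = cohort$sample_id, time = cohort$time, event = cohort$event
    ),
    path
  )
  invisible(path)
}

#' Write a BiNet evaluation table as CSV
#'
#' @param evaluation a `binet_evaluation` from [evaluate_binets()].
#' @param path file path.
#' @export
write_evaluation_csv <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "binet_evaluation"))
  readr::write_csv(tibble::as_tibble(evaluation), path)
  invisible(path)
}
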