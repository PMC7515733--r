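#' transitr: transition cells and intermediate states from single-cell data
#'
#' End-to-end workflow: [filter_cells()] / [filter_genes()] /
#' [select_informative_genes()] -> [build_consensus()] -> [estimate_k()] ->
#' [soft_cluster()] -> [pre_embedding()] -> [build_transition_graph()] /
#' [infer_trajectories()] / [trajectory_pseudotime()] ->
#' [fit_gene_cluster()] / [marker_genes()] / [transition_genes()], wrapped by
#' [quantify_transitions()]. Ground-truth generators:
#' [run_emt_simulation()] (agent-based 18-species EMT circuit) and
#' [simulate_population()] / [simulate_population_sde()] (intermediate-state
#' population model).
#'
#' @keywords internal
#' @aliases transitr-package
#' @importFrom rlang .data
#' @importFrom mclust mclustBIC
"_PACKAGE"

#' Run the full transition-cell analysis
#'
#' Applies the cell/gene filters and (for large panels) the mixture-model
#' feature selection, builds the consensus matrix, estimates or accepts the
#' cluster count, soft-clusters, embeds, infers transition trajectories with
#' pseudotime, and extracts cluster markers and transition genes per
#' trajectory.
#'
#' @param x genes x cells expression matrix.
#' @param k number of clusters; `NULL` estimates it from the Laplacian
#'   eigengap.
#' @param seed master seed; each stage derives its own stream.
#' @param select_genes run mixture-model feature selection; `NULL` (default)
#'   enables it only when more than 100 genes survive the filters (small
#'   targeted panels are used as-is).
#' @param n_top_genes genes kept by feature selection.
#' @param min_gene_fraction,min_cell_fraction,min_variance filter thresholds,
#'   see [filter_cells()] and [filter_genes()].
#' @param dims,k_range,n_restarts_consensus consensus ensemble, see
#'   [build_consensus()].
#' @param k_max eigengap search bound.
#' @param n_restarts_nmf,tol,max_iter factorization controls, see
#'   [sym_nmf()].
#' @param tc_threshold CPI cutoff or `"auto"`.
#' @param lambda1 embedding repulsion weight.
#' @param initial_cluster starting cluster index (`NULL`: auto).
#' @param lambda2,min_gap,rho_threshold gene-stage controls, see
#'   [fit_gene_cluster()], [marker_genes()], [transition_genes()].
#' @param n_gene_trajectories number of top trajectories analyzed for genes.
#' @return Object of class `transition_analysis` bundling every stage result
#'   plus a run manifest.
#' @export
quantify_transitions <- function(x, k = NULL, seed = 1L,
                                 select_genes = NULL, n_top_genes = 3000,
                                 min_gene_fraction = 0.05,
                                 min_cell_fraction = 0.10,
                                 min_variance = 0.005,
                                 dims = c(5, 10, 15, 20, 30),
                                 k_range = NULL,
                                 n_restarts_consensus = 3,
                                 k_max = 10,
                                 n_restarts_nmf = 10, tol = 1e-6,
                                 max_iter = 500,
                                 tc_threshold = "auto", lambda1 = 0.3,
                                 initial_cluster = NULL, lambda2 = 10,
                                 min_gap = 0.03, rho_threshold = 0.64,
                                 n_gene_trajectories = 2) {
  seed <- as.integer(seed)
  stage_seed <- function(i) (seed * 127L + i * 9973L) %% 2147483647L
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  xf <- filter_cells(x, min_gene_fraction)
  xf <- filter_genes(xf, min_cell_fraction, min_variance)
  done("filter")

  if (is.null(select_genes)) select_genes <- nrow(xf) > 100
  selection <- NULL
  if (select_genes) {
    selection <- select_informative_genes(xf, n_top = n_top_genes,
                                          seed = stage_seed(1L))
    xf <- xf[selection$selected_genes, , drop = FALSE]
  }
  done("feature_selection")

  M <- build_consensus(xf, dims = dims, k_range = k_range,
                       n_restarts = n_restarts_consensus,
                       seed = stage_seed(2L))
  done("consensus")

  sc <- soft_cluster(M, k = k, seed = stage_seed(3L),
                     n_restarts = n_restarts_nmf, tol = tol,
                     max_iter = max_iter, tc_threshold = tc_threshold,
                     k_max = k_max)
  done("soft_clustering")

  emb <- pre_embedding(sc, lambda1 = lambda1)
  done("embedding")

  graph <- build_transition_graph(sc$P, sc$tc_mask)
  trajs <- infer_trajectories(graph, initial_cluster, sc$P, sc$cpi)
  pt <- trajectory_pseudotime(emb, trajs)
  done("trajectory")

  gene_results <- list()
  top_trajs <- utils::head(trajs$trajectories,
                           min(n_gene_trajectories,
                               length(trajs$trajectories)))
  for (ti in seq_along(top_trajs)) {
    tr <- top_trajs[[ti]]
    if (length(tr$cells) < 3 || length(tr$cluster_path) < 2) next
    fit <- fit_gene_cluster(xf[, tr$cells, drop = FALSE],
                            sc$H[tr$cells, , drop = FALSE],
                            lambda2 = lambda2, seed = stage_seed(4L + ti),
                            tol = tol, max_iter = max_iter)
    mk <- marker_genes(fit, min_gap = min_gap)
    tg <- list()
    path <- tr$cluster_path
    for (s in seq_len(length(path) - 1)) {
      seg_cells <- tr$ordering$cell[tr$ordering$segment == s]
      if (length(seg_cells) < 3) next
      cand <- mk$gene[mk$cluster %in% paste0("C", path[c(s, s + 1)])]
      if (length(cand) == 0) next
      tg[[paste0("C", path[s], "-C", path[s + 1])]] <-
        transition_genes(xf, seg_cells, cand, rho_threshold)
    }
    gene_results[[paste0("C", paste(path, collapse = "-C"))]] <-
      list(fit = fit, markers = mk, transition_genes = tg)
  }
  done("genes")

  manifest <- list(
    package_version = as.character(utils::packageVersion("transitr")),
    seed = seed, stages = stages,
    parameters = list(k = sc$k, n_top_genes = n_top_genes,
                      lambda1 = lambda1, lambda2 = lambda2,
                      tc_threshold = sc$tc_threshold,
                      rho_threshold = rho_threshold, min_gap = min_gap,
                      initial_cluster = trajs$initial_cluster),
    n_cells = ncol(xf), n_genes = nrow(xf))

  structure(list(expression = xf, selection = selection, consensus = M,
                 clustering = sc, embedding = emb, graph = graph,
                 trajectories = trajs, pseudotime = pt,
                 genes = gene_results, manifest = manifest),
            class = "transition_analysis")
}

#' @export
print.transition_analysis <- function(x, ...) {
  cat("<transition_analysis> ", ncol(x$expression), " cells, ",
      nrow(x$expression), " genes, k = ", x$clustering$k, ", ",
      sum(x$clustering$tc_mask), " transition cells\n", sep = "")
  print(x$trajectories)
  invisible(x)
}

#' Per-cell results of a transition analysis
#'
#' @param x a `transition_analysis`.
#' @param ... unused.
#' @return Tibble with cell, cluster, CPI, TC flag, embedding coordinates,
#'   pseudotime and membership probabilities.
#' @method tidy transition_analysis
#' @export
tidy.transition_analysis <- function(x, ...) {
  tidy(x$clustering) |>
    dplyr::left_join(dplyr::select(tidy(x$embedding), "cell", "x", "y"),
                     by = "cell") |>
    dplyr::left_join(x$pseudotime, by = "cell")
}

#' One-row summary of a transition analysis
#'
#' @param x a `transition_analysis`.
#' @param ... unused.
#' @return Tibble with sizes, k, TC count and top-trajectory probability.
#' @method glance transition_analysis
#' @export
glance.transition_analysis <- function(x, ...) {
  top <- if (length(x$trajectories$trajectories)) {
    x$trajectories$trajectories[[1]]
  } else NULL
  tibble::tibble(
    n_cells = ncol(x$expression), n_genes = nrow(x$expression),
    k = x$clustering$k, n_tc = sum(x$clustering$tc_mask),
    tc_threshold = x$clustering$tc_threshold,
    top_path = if (is.null(top)) NA_character_ else
      paste0("C", top$cluster_path, collapse = "-"),
    top_probability = if (is.null(top)) NA_real_ else top$probability)
}

#' @method autoplot transition_analysis
#' @export
autoplot.transition_analysis <- function(object, ...) {
  autoplot(object$embedding, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write analysis results to disk
#'
#' Emits the per-cell table, transition-graph edge list, trajectory summary,
#' marker and transition genes as TSV and the run manifest as JSON.
#'
#' @param x a `transition_analysis`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "transition_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(x), file.path(dir, "cells.tsv"))
  readr::write_tsv(tidy(x$graph), file.path(dir, "transition_graph.tsv"))
  readr::write_tsv(glance(x$trajectories),
                   file.path(dir, "trajectories.tsv"))
  mk <- purrr::imap_dfr(x$genes, function(g, nm) {
    dplyr::mutate(g$markers, trajectory = nm, .before = 1)
  })
  if (nrow(mk)) readr::write_tsv(mk, file.path(dir, "marker_genes.tsv"))
  tg <- purrr::imap_dfr(x$genes, function(g, nm) {
    purrr::imap_dfr(g$transition_genes, function(tab, pair) {
      dplyr::mutate(tab, trajectory = nm, pair = pair, .before = 1)
    })
  })
  if (nrow(tg)) readr::write_tsv(tg, file.path(dir, "transition_genes.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
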