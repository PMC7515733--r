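#' Regularized NMF linking genes to clusters
#'
#' Factorizes the expression submatrix of the cells on one trajectory as
#' D_s' ~ H_bar W with H_bar, W >= 0, while a proximity penalty
#' (lambda2/2) ||H_bar - H_s||_F^2 keeps the cell factor close to the
#' soft-clustering memberships H_s of the same cells. A bare linear coupling
#' -lambda2 Tr(H_bar' H_s) expresses the same pull but is unbounded below
#' under the scaling (H_bar, W) -> (c H_bar, W/c); completing the square
#' adds the ridge that pins the scale without changing the intent.
#' Alternating multiplicative updates keep both factors nonnegative and the
#' objective non-increasing.
#'
#' @param D_s genes x cells expression submatrix (cells of one trajectory).
#' @param H_s cells x k membership factor for the same cells (rows of H).
#' @param lambda2 coupling strength (default 10).
#' @param seed integer seed (initialization of W).
#' @param tol relative objective-change tolerance.
#' @param max_iter maximum alternating updates.
#' @return List of class `gene_cluster_fit`: `W` (k x genes), `H_bar`
#'   (cells x k), `lambda2`, `objective_trace`.
#' @export
fit_gene_cluster <- function(D_s, H_s, lambda2 = 10, seed = 1L,
                             tol = 1e-6, max_iter = 500) {
  stopifnot(is.matrix(D_s), is.matrix(H_s), lambda2 >= 0)
  if (ncol(D_s) != nrow(H_s)) {
    stop("D_s has ", ncol(D_s), " cells but H_s has ", nrow(H_s), " rows")
  }
  set.seed(as.integer(seed))
  X <- t(D_s)                      # cells x genes
  k <- ncol(H_s)
  m <- ncol(X)
  eps <- .Machine$double.eps
  H_bar <- pmax(H_s, eps)
  W <- matrix(stats::runif(k * m, 0, max(X) / max(1, k)), k, m)
  objective <- function() {
    norm(X - H_bar %*% W, "F")^2 + (lambda2 / 2) * norm(H_bar - H_s, "F")^2
  }
  obj <- numeric(max_iter + 1)
  obj[1] <- objective()
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- W * crossprod(H_bar, X) / pmax(crossprod(H_bar) %*% W, eps)
    num <- 2 * (X %*% t(W)) + lambda2 * H_s
    den <- 2 * (H_bar %*% tcrossprod(W)) + lambda2 * H_bar
    H_bar <- H_bar * num / pmax(den, eps)
    obj[it + 1] <- objective()
    if (abs(obj[it + 1] - obj[it]) <= tol * max(abs(obj[it]), eps)) break
  }
  rownames(W) <- colnames(H_s)
  colnames(W) <- rownames(D_s)
  structure(list(W = W, H_bar = H_bar, lambda2 = lambda2,
                 objective_trace = obj[seq_len(it + 1)]),
            class = "gene_cluster_fit")
}

#' @export
print.gene_cluster_fit <- function(x, ...) {
  cat("<gene_cluster_fit> ", ncol(x$W), " genes x ", nrow(x$W),
      " clusters, lambda2 = ", x$lambda2, "\n", sep = "")
  invisible(x)
}

normalize_gene_columns <- function(W) {
  cs <- colSums(W)
  cs[cs == 0] <- 1
  sweep(W, 2, cs, "/")
}

#' Cluster marker genes from the gene-cluster matrix
#'
#' Column-normalizes W so that each gene carries a distribution over
#' clusters. A gene marks the cluster holding its largest entry provided the
#' margin over the runner-up exceeds `min_gap`; genes spread evenly over
#' clusters mark nothing (the typical behavior of intermediate states, which
#' tend to lack clean markers). Markers are ranked within each cluster by
#' their normalized entry.
#'
#' @param fit a [fit_gene_cluster()] result (or a k x genes matrix W).
#' @param min_gap required margin between the two largest normalized entries.
#' @param n_top optional cap per cluster.
#' @return Tibble with `gene`, `cluster`, `score`, `gap`.
#' @export
marker_genes <- function(fit, min_gap = 0.03, n_top = Inf) {
  W <- if (inherits(fit, "gene_cluster_fit")) fit$W else fit
  stopifnot(is.matrix(W), min_gap >= 0)
  Wn <- normalize_gene_columns(W)
  k <- nrow(Wn)
  top <- apply(Wn, 2, function(v) order(-v, seq_along(v))[1:2])
  score <- Wn[cbind(top[1, ], seq_len(ncol(Wn)))]
  second <- Wn[cbind(top[2, ], seq_len(ncol(Wn)))]
  gap <- score - second
  genes <- colnames(Wn)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(Wn)))
  out <- tibble::tibble(gene = genes,
                        cluster = rownames(Wn)[top[1, ]] %||%
                          paste0("C", top[1, ]),
                        score = score, gap = gap) |>
    dplyr::filter(.data$gap > min_gap) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$score)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::ungroup()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transition genes along an aligned cell ordering
#'
#' Computes the Spearman rank correlation between each candidate gene's
#' expression and the position of the cells in the aligned ordering between
#' two clusters. Genes with |rho| at or above the threshold are transition
#' genes; the sign gives the direction (expression rising or falling along
#' the transition). Genes constant over the ordering are skipped.
#'
#' @param D genes x cells expression matrix.
#' @param cell_order cell indices (or names) in transition order.
#' @param candidate_genes genes to screen (default: all rows of D; the usual
#'   choice is the markers of the two flanking clusters).
#' @param rho_threshold minimum |Spearman rho| (default 0.64).
#' @return Tibble with `gene`, `rho`, `direction` (`"up"`/`"down"`).
#' @export
transition_genes <- function(D, cell_order, candidate_genes = NULL,
                             rho_threshold = 0.64) {
  stopifnot(is.matrix(D), length(cell_order) >= 3,
            rho_threshold >= 0, rho_threshold <= 1)
  if (is.null(candidate_genes)) candidate_genes <- rownames(D)
  candidate_genes <- intersect(candidate_genes, rownames(D))
  expr <- D[candidate_genes, cell_order, drop = FALSE]
  pos <- seq_along(cell_order)
  const <- apply(expr, 1, function(v) max(v) == min(v))
  if (any(const)) {
    warning(sum(const), " candidate gene(s) constant over the ordering; ",
            "skipped")
  }
  keep <- candidate_genes[!const]
  rho <- vapply(keep, function(g) {
    stats::cor(expr[g, ], pos, method = "spearman")
  }, numeric(1))
  tibble::tibble(gene = keep, rho = unname(rho)) |>
    dplyr::filter(abs(.data$rho) >= rho_threshold) |>
    dplyr::mutate(direction = dplyr::if_else(.data$rho > 0, "up", "down")) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)))
}
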