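#' Build the cell-cell consensus matrix
#'
#' Runs an ensemble of base clusterings (k-means on the leading principal
#' components, over a grid of dimensionalities, cluster counts and seeded
#' restarts), forms for each the binary co-membership matrix (1 when two
#' cells share a cluster), and averages them. The result is a symmetric
#' matrix in \[0, 1\] with unit diagonal measuring how often each pair of
#' cells is co-clustered.
#'
#' @param x genes x cells matrix (typically after feature selection).
#' @param dims principal-component depths to use (capped at what the data
#'   supports).
#' @param k_range cluster counts of the base k-means runs; default
#'   `2:min(10, n - 1)`.
#' @param n_restarts seeded k-means restarts per (depth, k) pair.
#' @param seed integer seed.
#' @return Matrix of class `consensus_matrix` with attribute `n_runs`.
#' @export
build_consensus <- function(x, dims = c(5, 10, 15, 20, 30), k_range = NULL,
                            n_restarts = 3, seed = 1L) {
  validate_expression(x)
  n <- ncol(x)
  if (n < 2) stop("need at least 2 cells")
  if (is.null(k_range)) k_range <- 2:max(2, min(10, n - 1))
  stopifnot(all(k_range >= 2), all(k_range < n), n_restarts >= 1)
  set.seed(as.integer(seed))
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  d_avail <- ncol(pc$x)
  dims <- unique(pmin(dims, d_avail))
  grid <- expand.grid(d = dims, k = k_range, r = seq_len(n_restarts))
  if (nrow(grid) < 2) stop("run specification defines fewer than 2 clusterings")
  acc <- matrix(0, n, n)
  n_ok <- 0L
  for (i in seq_len(nrow(grid))) {
    cl <- tryCatch(
      stats::kmeans(pc$x[, seq_len(grid$d[i]), drop = FALSE],
                    centers = grid$k[i], nstart = 1,
                    iter.max = 50)$cluster,
      error = function(e) NULL)
    if (is.null(cl)) {
      warning("base clustering (d=", grid$d[i], ", k=", grid$k[i],
              ") failed; skipped")
      next
    }
    B <- outer(cl, cl, `==`)
    acc <- acc + B
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stop("all base clusterings failed")
  M <- acc / n_ok
  dimnames(M) <- list(colnames(x), colnames(x))
  structure(M, n_runs = n_ok, class = c("consensus_matrix", "matrix", "array"))
}

validate_consensus <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be square")
  if (max(abs(M - t(M))) > 1e-12) stop("M must be symmetric")
  if (min(M) < 0 || max(M) > 1 + 1e-12) stop("M entries must lie in [0, 1]")
  invisible(M)
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("<consensus_matrix> ", nrow(x), " cells, ",
      attr(x, "n_runs"), " base clusterings\n", sep = "")
  invisible(x)
}

#' Estimate the number of clusters from the consensus matrix
#'
#' Forms the symmetric normalized graph Laplacian
#' L = I - D^(-1/2) M D^(-1/2) of the consensus matrix, sorts its eigenvalues
#' in ascending order and returns the position of the largest gap between
#' consecutive eigenvalues, searched over 2..k_max (a transition analysis
#' needs at least two states; ties resolve toward smaller k).
#'
#' @param M a consensus (or any symmetric nonnegative similarity) matrix.
#' @param k_max largest cluster count considered.
#' @return List of class `k_estimate`: `k`, `eigenvalues` (ascending),
#'   `gap_index`, `k_max`.
#' @export
estimate_k <- function(M, k_max = 10) {
  validate_consensus(M)
  n <- nrow(M)
  if (n <= k_max) stop("need more cells than k_max")
  deg <- rowSums(M)
  if (any(deg <= 0)) {
    bad <- rownames(M)[deg <= 0]
    if (is.null(bad)) bad <- which(deg <= 0)
    stop("cell(s) with zero similarity to all others: ",
         paste(bad, collapse = ", "))
  }
  inv_sq <- 1 / sqrt(deg)
  L <- diag(n) - (inv_sq * M) %*% diag(inv_sq)
  lam <- sort(eigen((L + t(L)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  lam <- pmin(pmax(lam, 0), 2)
  js <- 2:k_max
  gaps <- lam[js + 1L] - lam[js]
  k <- js[which.max(gaps)]
  structure(list(k = k, eigenvalues = lam, gap_index = k, k_max = k_max),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat("<k_estimate> k = ", x$k, " (largest Laplacian eigengap in 2..",
      x$k_max, ")\n", sep = "")
  invisible(x)
}
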