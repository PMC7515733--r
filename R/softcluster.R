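#' Symmetric nonnegative matrix factorization of the consensus matrix
#'
#' Finds H >= 0 (n x k) minimizing ||M - H H'||_F^2 by damped multiplicative
#' updates (damping 1/2, which keeps the objective non-increasing), from a
#' spectral initialization (absolute values of the top-k eigenvectors,
#' perturbed per restart), followed by a projected-gradient polish with
#' Barzilai-Borwein steps under an Armijo decrease safeguard (multiplicative
#' updates slow down near a stationary point; the polish drives exactly
#' factorable problems to machine precision while preserving the monotone
#' objective trace). The best of `n_restarts` runs by final objective is
#' returned. Columns are ordered by the index of their highest-membership
#' cell so that repeated runs agree up to numerical noise.
#'
#' @param M consensus (symmetric, nonnegative) matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_restarts independent restarts.
#' @param tol relative objective-change tolerance for convergence.
#' @param max_iter maximum multiplicative updates per run.
#' @return List of class `sym_nmf`: `H`, `k`, `objective_value`,
#'   `objective_trace` (best run), `converged`.
#' @export
sym_nmf <- function(M, k, seed = 1L, n_restarts = 10, tol = 1e-6,
                    max_iter = 500) {
  validate_consensus(M)
  stopifnot(k >= 2, k <= nrow(M))
  set.seed(as.integer(seed))
  n <- nrow(M)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  H_base <- abs(eg$vectors[, seq_len(k), drop = FALSE]) %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    H <- H_base
    if (r > 1) {
      H <- H * matrix(stats::runif(n * k, 0.8, 1.2), n, k) +
        mean(H) * 0.01 * matrix(stats::runif(n * k), n, k)
    }
    H[H < eps] <- eps
    obj <- numeric(max_iter + 1)
    obj[1] <- norm(M - tcrossprod(H), "F")^2
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      MH <- M %*% H
      HHtH <- H %*% crossprod(H)
      H <- H * (0.5 + 0.5 * MH / pmax(HHtH, eps))
      obj[it + 1] <- norm(M - tcrossprod(H), "F")^2
      if (abs(obj[it + 1] - obj[it]) <= tol * max(obj[it], eps)) {
        converged <- TRUE
        break
      }
    }
    trace <- obj[seq_len(it + 1)]
    polish <- symnmf_polish(M, H, max_iter = max(200L, max_iter %/% 2),
                            tol = tol * 1e-6)
    H <- polish$H
    trace <- c(trace, polish$trace[-1])
    cand <- list(H = H, objective_value = trace[length(trace)],
                 objective_trace = trace, converged = converged)
    if (is.null(best) || cand$objective_value < best$objective_value) {
      best <- cand
    }
  }
  ord <- order(apply(best$H, 2, which.max))
  H <- best$H[, ord, drop = FALSE]
  rownames(H) <- rownames(M)
  colnames(H) <- paste0("C", seq_len(k))
  structure(list(H = H, k = as.integer(k),
                 objective_value = best$objective_value,
                 objective_trace = best$objective_trace,
                 converged = best$converged),
            class = "sym_nmf")
}

# monotone projected-gradient refinement of the symmetric factorization
symnmf_polish <- function(M, H, max_iter = 200L, tol = 1e-14) {
  obj <- function(H) norm(M - tcrossprod(H), "F")^2
  grad <- function(H) 4 * (tcrossprod(H) - M) %*% H
  f <- obj(H)
  g <- grad(H)
  step <- 1e-3
  trace <- f
  for (it in seq_len(max_iter)) {
    H_old <- H
    g_old <- g
    repeat {
      H_new <- pmax(H - step * g, 0)
      f_new <- obj(H_new)
      if (f_new <= f - 1e-4 * sum(g * (H - H_new)) || step < 1e-16) break
      step <- step / 2
    }
    if (f_new > f) break                 # no descent direction left
    H <- H_new
    converged <- f - f_new <= tol * max(f, .Machine$double.xmin)
    f <- f_new
    trace <- c(trace, f)
    if (converged) break
    g <- grad(H)
    sH <- H - H_old
    sg <- g - g_old
    denom <- sum(sH * sg)
    step <- if (denom > 0) sum(sH * sH) / denom else 1e-3
  }
  list(H = H, trace = trace)
}

#' @export
print.sym_nmf <- function(x, ...) {
  cat("<sym_nmf> k = ", x$k, ", objective ",
      signif(x$objective_value, 5),
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

#' Row-normalize memberships to probabilities
#'
#' @param H nonnegative membership matrix (cells x clusters).
#' @return Row-stochastic matrix P with P_ij = H_ij / sum_j H_ij.
#' @export
membership_probabilities <- function(H) {
  if (inherits(H, "sym_nmf")) H <- H$H
  stopifnot(is.matrix(H), all(H >= 0))
  rs <- rowSums(H)
  if (any(rs <= 0)) {
    bad <- rownames(H)[rs <= 0]
    if (is.null(bad)) bad <- which(rs <= 0)
    stop("zero membership row for cell(s): ", paste(bad, collapse = ", "))
  }
  H / rs
}

#' Cell plasticity index
#'
#' CPI_i = -(1/log k) * sum_j P_ij log P_ij: the normalized entropy of a
#' cell's cluster-membership probabilities. 0 marks a cell committed to one
#' cluster, 1 a maximally plastic cell spread evenly over all clusters.
#'
#' @param P row-stochastic membership matrix (cells x clusters, k >= 2).
#' @return Numeric vector in \[0, 1\], named by cell.
#' @export
cell_plasticity_index <- function(P) {
  stopifnot(is.matrix(P), ncol(P) >= 2)
  if (max(abs(rowSums(P) - 1)) > 1e-6) stop("P rows must sum to 1")
  if (min(P) < 0) stop("P must be nonnegative")
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  cpi <- -rowSums(plogp) / log(ncol(P))
  pmin(pmax(cpi, 0), 1)
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes the between-class variance of the histogram split, the standard
#' automatic threshold for a bimodal sample.
#'
#' @param x numeric vector.
#' @param n_breaks histogram resolution.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  stopifnot(length(x) >= 2)
  h <- graphics::hist(x, breaks = seq(min(x), max(x),
                                      length.out = n_breaks + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Flag transition cells by their plasticity
#'
#' Cells with CPI above the threshold are transition cells. `"auto"` picks
#' the threshold by Otsu's method on the CPI distribution; datasets with a
#' known cutoff can pass it directly.
#'
#' @param cpi CPI vector in \[0, 1\].
#' @param threshold numeric cutoff in \[0, 1\], or `"auto"`.
#' @return Logical mask with attribute `threshold`.
#' @export
identify_tc <- function(cpi, threshold = "auto") {
  stopifnot(all(cpi >= 0), all(cpi <= 1))
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(cpi)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(cpi > threshold, threshold = threshold)
}

#' Soft-cluster a consensus matrix
#'
#' Convenience wrapper: factorizes M by [sym_nmf()], converts memberships to
#' probabilities, computes the cell plasticity index, assigns hard labels by
#' maximum probability and flags transition cells.
#'
#' @param M consensus matrix.
#' @param k number of clusters; `NULL` estimates it via [estimate_k()].
#' @param tc_threshold CPI cutoff or `"auto"` ([identify_tc()]).
#' @param k_max passed to [estimate_k()] when `k` is `NULL`.
#' @inheritParams sym_nmf
#' @return Object of class `soft_clustering` with fields `H`, `P`, `k`,
#'   `cpi`, `hard_labels`, `tc_mask`, `objective_value`, `k_estimate`.
#' @export
soft_cluster <- function(M, k = NULL, seed = 1L, n_restarts = 10,
                         tol = 1e-6, max_iter = 500, tc_threshold = "auto",
                         k_max = 10) {
  ke <- NULL
  if (is.null(k)) {
    ke <- estimate_k(M, k_max = min(k_max, nrow(M) - 1))
    k <- ke$k
  }
  fit <- sym_nmf(M, k, seed = seed, n_restarts = n_restarts, tol = tol,
                 max_iter = max_iter)
  P <- membership_probabilities(fit$H)
  cpi <- cell_plasticity_index(P)
  tc <- identify_tc(cpi, tc_threshold)
  structure(list(H = fit$H, P = P, k = fit$k, cpi = cpi,
                 hard_labels = max.col(P, ties.method = "first"),
                 tc_mask = as.logical(tc),
                 tc_threshold = attr(tc, "threshold"),
                 objective_value = fit$objective_value,
                 objective_trace = fit$objective_trace,
                 k_estimate = ke),
            class = "soft_clustering")
}

#' @export
print.soft_clustering <- function(x, ...) {
  cat("<soft_clustering> ", nrow(x$P), " cells in ", x$k, " clusters; ",
      sum(x$tc_mask), " transition cells (CPI > ",
      signif(x$tc_threshold, 3), ")\n", sep = "")
  invisible(x)
}

#' Per-cell soft-clustering table
#'
#' @param x a `soft_clustering`.
#' @param ... unused.
#' @return Tibble with cell, hard cluster, CPI, TC flag and the membership
#'   probabilities.
#' @method tidy soft_clustering
#' @export
tidy.soft_clustering <- function(x, ...) {
  cells <- rownames(x$P)
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(x$P)))
  dplyr::bind_cols(
    tibble::tibble(cell = cells,
                   cluster = paste0("C", x$hard_labels),
                   cpi = unname(x$cpi),
                   is_tc = x$tc_mask),
    tibble::as_tibble(x$P)
  )
}

#' One-row soft-clustering summary
#'
#' @param x a `soft_clustering`.
#' @param ... unused.
#' @return Tibble with k, objective, TC count and threshold.
#' @method glance soft_clustering
#' @export
glance.soft_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = nrow(x$P),
                 objective = x$objective_value,
                 n_tc = sum(x$tc_mask), tc_threshold = x$tc_threshold)
}
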