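#' Two-dimensional cluster centers from the cluster-cluster relationship
#'
#' Derives cluster-cluster similarity from H'H, rescales it to a correlation-
#' like matrix, converts to distances d_ij = sqrt(2 - 2 s_ij) and lays the
#' clusters out in the plane by classical multidimensional scaling. The
#' configuration is made deterministic by fixing the orientation: the first
#' cluster sits at the origin, the second on the positive x-axis, and the
#' third (when present) in the upper half-plane.
#'
#' @param H nonnegative membership matrix (cells x clusters) or `sym_nmf`.
#' @return k x 2 matrix of cluster-center coordinates.
#' @export
cluster_centers <- function(H) {
  if (inherits(H, "sym_nmf")) H <- H$H
  stopifnot(is.matrix(H), all(H >= 0))
  k <- ncol(H)
  if (k == 1) return(matrix(0, 1, 2))
  S <- crossprod(H)
  nrm <- sqrt(diag(S))
  nrm[nrm == 0] <- 1
  Sc <- S / outer(nrm, nrm)
  D <- sqrt(pmax(2 - 2 * Sc, 0))
  centers <- stats::cmdscale(stats::as.dist(D), k = min(2, k - 1))
  if (ncol(centers) < 2) {
    centers <- cbind(centers, matrix(0, nrow(centers), 2 - ncol(centers)))
  }
  orient_centers(centers)
}

orient_centers <- function(centers) {
  k <- nrow(centers)
  centers <- sweep(centers, 2, centers[1, ])
  if (k >= 2) {
    v <- centers[2, ]
    len <- sqrt(sum(v^2))
    if (len > 1e-12) {
      ct <- v[1] / len
      st <- v[2] / len
      R <- matrix(c(ct, -st, st, ct), 2, 2)  # rotates v onto +x
      centers <- centers %*% R
    }
    if (k >= 3 && centers[3, 2] < 0) centers[, 2] <- -centers[, 2]
  }
  rownames(centers) <- paste0("C", seq_len(k))
  colnames(centers) <- c("x", "y")
  centers
}

#' Probabilistic regularized embedding of cells
#'
#' Places each cell by membership-weighted attraction to the cluster centers
#' while a pairwise repulsion term (weight `lambda1`) keeps cells spread out:
#' minimize sum_ij p_ij ||x_i - a_j||^2 - (lambda1/n) sum_il ||x_i - x_l||^2.
#' The objective is quadratic, so the exact stationary point is returned:
#' x_i = (c_i - 2 lambda1 mean(c)) / (1 - 2 lambda1) with c = P a. The
#' objective is bounded below only for lambda1 < 1/2.
#'
#' @param P row-stochastic membership matrix (cells x clusters).
#' @param centers k x 2 center matrix from [cluster_centers()].
#' @param lambda1 repulsion weight in \[0, 0.5).
#' @return n x 2 matrix of cell coordinates.
#' @export
embed_cells <- function(P, centers, lambda1 = 0.3) {
  stopifnot(is.matrix(P), is.matrix(centers), ncol(P) == nrow(centers))
  if (lambda1 < 0 || lambda1 >= 0.5) {
    stop("lambda1 must lie in [0, 0.5); at or above 0.5 the embedding ",
         "objective is unbounded below")
  }
  cc <- P %*% centers
  cbar <- colMeans(cc)
  coords <- sweep(cc, 2, 2 * lambda1 * cbar) / (1 - 2 * lambda1)
  colnames(coords) <- c("x", "y")
  coords
}

#' Probabilistic regularized embedding of a soft clustering
#'
#' @param sc a `soft_clustering`.
#' @param lambda1 repulsion weight, see [embed_cells()].
#' @return Object of class `pre_embedding` with `centers`, `coords`,
#'   `lambda1` and the parent clustering.
#' @export
pre_embedding <- function(sc, lambda1 = 0.3) {
  stopifnot(inherits(sc, "soft_clustering"))
  centers <- cluster_centers(sc$H)
  coords <- embed_cells(sc$P, centers, lambda1)
  structure(list(centers = centers, coords = coords, lambda1 = lambda1,
                 clustering = sc),
            class = "pre_embedding")
}

#' @export
print.pre_embedding <- function(x, ...) {
  cat("<pre_embedding> ", nrow(x$coords), " cells, ", nrow(x$centers),
      " cluster centers, lambda1 = ", x$lambda1, "\n", sep = "")
  invisible(x)
}

#' Cell coordinates of an embedding
#'
#' @param x a `pre_embedding`.
#' @param ... unused.
#' @return Tibble with cell, x, y, cluster, CPI and TC flag.
#' @method tidy pre_embedding
#' @export
tidy.pre_embedding <- function(x, ...) {
  sc <- x$clustering
  xy <- x$coords
  cells <- rownames(sc$P)
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(sc$P)))
  tibble::tibble(cell = cells,
                 x = xy[, 1], y = xy[, 2],
                 cluster = paste0("C", sc$hard_labels),
                 cpi = unname(sc$cpi), is_tc = sc$tc_mask)
}

#' Plot the embedding colored by plasticity
#'
#' @param object a `pre_embedding`.
#' @param colour_by `"cpi"` or `"cluster"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pre_embedding
#' @export
autoplot.pre_embedding <- function(object, colour_by = c("cpi", "cluster"),
                                   ...) {
  colour_by <- match.arg(colour_by)
  df <- tidy(object)
  ctr <- tibble::as_tibble(object$centers, rownames = "cluster")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                        size = 1.2, alpha = 0.8) +
    ggplot2::geom_point(data = ctr, shape = 21, size = 6, fill = NA,
                        colour = "grey30") +
    ggplot2::geom_text(data = ctr, ggplot2::aes(label = .data$cluster),
                       vjust = -1.2, size = 3.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (colour_by == "cpi") p <- p + ggplot2::scale_colour_viridis_c()
  p
}
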