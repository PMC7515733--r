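top_two_clusters <- function(P) {
  t(apply(P, 1, function(p) order(-p, seq_along(p))[1:2]))
}

#' Cluster-to-cluster transition graph
#'
#' Assigns every transition cell to the unordered pair of clusters holding
#' its two largest membership probabilities (ties resolve toward the smaller
#' cluster index) and tabulates the counts. Two clusters are neighbors when
#' at least one transition cell lies between them. Clusters with transition
#' cells toward every other cluster are candidates for intermediate cell
#' states (ICS).
#'
#' @param P row-stochastic membership matrix (cells x clusters).
#' @param tc_mask logical transition-cell mask, same length as rows of P.
#' @return List of class `transition_graph`: `tc_counts` (k x k symmetric),
#'   `tc_fraction` (counts / number of cells), `neighbors` (logical
#'   adjacency), `ics_candidates` (cluster indices), `n_cells`.
#' @export
build_transition_graph <- function(P, tc_mask) {
  stopifnot(is.matrix(P), length(tc_mask) == nrow(P))
  k <- ncol(P)
  n <- nrow(P)
  counts <- matrix(0L, k, k)
  tc_idx <- which(tc_mask)
  if (length(tc_idx) == 0) {
    warning("no transition cells; the transition graph is empty")
  }
  if (length(tc_idx) > 0) {
    tt <- top_two_clusters(P[tc_idx, , drop = FALSE])
    ties <- abs(P[cbind(tc_idx, tt[, 1])] - P[cbind(tc_idx, tt[, 2])]) < 1e-12
    if (any(ties)) {
      message(sum(ties), " transition cell(s) had tied memberships; ",
              "assigned toward the smaller cluster index")
    }
    for (r in seq_along(tc_idx)) {
      a <- min(tt[r, ]); b <- max(tt[r, ])
      counts[a, b] <- counts[a, b] + 1L
      counts[b, a] <- counts[a, b]
    }
  }
  dimnames(counts) <- list(paste0("C", 1:k), paste0("C", 1:k))
  neighbors <- counts > 0
  ics <- which(vapply(seq_len(k), function(j) all(counts[j, -j] > 0),
                      logical(1)))
  structure(list(tc_counts = counts, tc_fraction = counts / n,
                 neighbors = neighbors, ics_candidates = ics,
                 n_cells = n),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  k <- nrow(x$tc_counts)
  cat("<transition_graph> ", k, " clusters, ",
      sum(x$tc_counts[upper.tri(x$tc_counts)]), " transition cells on ",
      sum(x$neighbors[upper.tri(x$neighbors)]), " edges; ICS candidates: ",
      if (length(x$ics_candidates)) {
        paste0("C", x$ics_candidates, collapse = ", ")
      } else "none", "\n", sep = "")
  invisible(x)
}

#' Edge list of a transition graph
#'
#' @param x a `transition_graph`.
#' @param ... unused.
#' @return Tibble with cluster pair, TC count and fraction.
#' @method tidy transition_graph
#' @export
tidy.transition_graph <- function(x, ...) {
  k <- nrow(x$tc_counts)
  pairs <- which(upper.tri(x$tc_counts), arr.ind = TRUE)
  tibble::tibble(from = paste0("C", pairs[, 1]),
                 to = paste0("C", pairs[, 2]),
                 tc_count = x$tc_counts[pairs],
                 tc_fraction = x$tc_fraction[pairs]) |>
    dplyr::filter(.data$tc_count > 0) |>
    dplyr::arrange(dplyr::desc(.data$tc_count))
}

#' Order cells along a cluster path
#'
#' For each consecutive cluster pair (k -> j) on the path, cells assigned to
#' cluster k (largest membership) are laid out in ascending CPI — committed
#' cells first, plastic cells toward the boundary — followed by the cells
#' aligned between k and j (two largest memberships exactly at k and j) whose
#' largest membership is already j, in descending CPI. Cells of the final
#' cluster not yet placed are appended in descending CPI. The starting cell —
#' the cell with the largest probability of belonging to the initial
#' cluster — is moved to the front.
#'
#' @param P row-stochastic membership matrix.
#' @param cpi CPI vector.
#' @param cluster_path integer vector of cluster indices along the path.
#' @param cells integer indices of the cells to order (default: all).
#' @return Tibble with `cell` (row index of P), `segment` (which leg of the
#'   path the cell sits on) in path order.
#' @export
align_cells <- function(P, cpi, cluster_path, cells = NULL) {
  stopifnot(length(cluster_path) >= 1)
  if (is.null(cells)) cells <- seq_len(nrow(P))
  am <- max.col(P, ties.method = "first")
  tt <- top_two_clusters(P)
  placed <- logical(nrow(P))
  placed[-cells] <- TRUE   # everything outside the set counts as placed
  m <- length(cluster_path)
  out_cell <- integer(0)
  out_seg <- integer(0)
  add <- function(idx, seg) {
    placed[idx] <<- TRUE
    out_cell <<- c(out_cell, idx)
    out_seg <<- c(out_seg, rep(seg, length(idx)))
  }
  if (m == 1) {
    idx <- cells[am[cells] == cluster_path[1]]
    add(idx[order(cpi[idx], idx)], 1L)
  } else {
    for (t in seq_len(m - 1)) {
      k_t <- cluster_path[t]; j_t <- cluster_path[t + 1]
      a_idx <- which(!placed & am == k_t)
      add(a_idx[order(cpi[a_idx], a_idx)], t)
      b_idx <- which(!placed & am == j_t &
                       pmin(tt[, 1], tt[, 2]) == min(k_t, j_t) &
                       pmax(tt[, 1], tt[, 2]) == max(k_t, j_t))
      add(b_idx[order(-cpi[b_idx], b_idx)], t)
    }
    last <- cluster_path[m]
    rest <- which(!placed & am == last)
    add(rest[order(-cpi[rest], rest)], m - 1L)
  }
  # starting cell first
  if (length(out_cell) > 1) {
    start <- out_cell[which.max(P[out_cell, cluster_path[1]])]
    pos <- match(start, out_cell)
    out_cell <- c(start, out_cell[-pos])
    out_seg <- c(out_seg[pos], out_seg[-pos])
    # keep segment labels nondecreasing after the move
    out_seg[1] <- min(out_seg)
  }
  tibble::tibble(cell = unname(out_cell), segment = unname(out_seg))
}

#' Infer transition trajectories
#'
#' Enumerates simple paths from the initial cluster over the neighbor graph
#' (capped at `max_length` clusters). A trajectory collects the cells whose
#' largest membership lies on the path plus the transition cells aligned
#' between consecutive path clusters; its occurrence probability is the
#' fraction of all cells it collects. Cells on each trajectory are ordered
#' with [align_cells()]. Trajectories are reported in descending probability.
#'
#' @param graph a [build_transition_graph()] result.
#' @param initial_cluster index of the starting cluster; `NULL` picks the
#'   non-ICS cluster with the fewest surrounding transition cells (a cluster
#'   where little transition takes place marks the start or end of the
#'   process).
#' @param P,cpi membership matrix and CPI vector.
#' @param max_length maximum clusters per path (default k).
#' @return List of class `trajectory_set`; each element has `cluster_path`,
#'   `cells`, `ordering` (tibble from [align_cells()]), `probability`,
#'   `start_cell`.
#' @export
infer_trajectories <- function(graph, initial_cluster = NULL, P, cpi,
                               max_length = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  k <- ncol(P)
  n <- nrow(P)
  if (is.null(max_length)) max_length <- k
  if (is.null(initial_cluster)) {
    ring <- rowSums(graph$tc_counts)
    cand <- setdiff(seq_len(k), graph$ics_candidates)
    if (length(cand) == 0) cand <- seq_len(k)
    initial_cluster <- cand[which.min(ring[cand])]
  }
  stopifnot(initial_cluster >= 1, initial_cluster <= k)
  am <- max.col(P, ties.method = "first")
  tt <- top_two_clusters(P)
  g <- igraph::graph_from_adjacency_matrix(graph$neighbors,
                                           mode = "undirected")
  paths <- list()
  if (igraph::degree(g)[initial_cluster] == 0) {
    warning("initial cluster C", initial_cluster,
            " has no neighbors; returning a single-cluster trajectory")
    paths <- list(initial_cluster)
  } else {
    sp <- igraph::all_simple_paths(g, from = initial_cluster,
                                   cutoff = max_length - 1)
    paths <- lapply(sp, as.integer)
  }
  tc_mask <- rep(FALSE, n)
  tc_pairs <- graph$tc_counts
  trajs <- lapply(paths, function(path) {
    on_path <- am %in% path
    aligned <- rep(FALSE, n)
    if (length(path) >= 2) {
      for (t in seq_len(length(path) - 1)) {
        a <- min(path[t], path[t + 1]); b <- max(path[t], path[t + 1])
        aligned <- aligned | (pmin(tt[, 1], tt[, 2]) == a &
                                pmax(tt[, 1], tt[, 2]) == b)
      }
    }
    cells <- which(on_path | aligned)
    ordering <- align_cells(P, cpi, path, cells)
    list(cluster_path = path, cells = cells, ordering = ordering,
         probability = length(cells) / n,
         start_cell = if (nrow(ordering)) ordering$cell[1] else NA_integer_)
  })
  ord <- order(-vapply(trajs, `[[`, numeric(1), "probability"),
               -lengths(lapply(trajs, `[[`, "cluster_path")),
               vapply(trajs, function(t) paste(t$cluster_path,
                                               collapse = "-"),
                      character(1)))
  structure(list(trajectories = trajs[ord],
                 initial_cluster = initial_cluster, n_cells = n),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$trajectories),
      " trajectories from C", x$initial_cluster, "\n", sep = "")
  for (tr in utils::head(x$trajectories, 8)) {
    cat("  ", paste0("C", tr$cluster_path, collapse = "-"), ": ",
        round(100 * tr$probability, 1), "% of cells\n", sep = "")
  }
  invisible(x)
}

#' Trajectory summary table
#'
#' @param x a `trajectory_set`.
#' @param ... unused.
#' @return Tibble with path, number of cells and occurrence probability.
#' @method glance trajectory_set
#' @export
glance.trajectory_set <- function(x, ...) {
  purrr::map_dfr(x$trajectories, function(tr) {
    tibble::tibble(path = paste0("C", tr$cluster_path, collapse = "-"),
                   n_clusters = length(tr$cluster_path),
                   n_cells = length(tr$cells),
                   probability = tr$probability)
  })
}

#' Pseudotime along transition trajectories
#'
#' The raw pseudotime of a cell is the cumulative Euclidean distance in the
#' embedding along the ordered cells from the starting cell. To make values
#' comparable across trajectories, the raw values of each leg between
#' neighboring clusters are min-max scaled onto consecutive unit windows
#' (\[0, 1\], \[1, 2\], ...). Each cell's global pseudotime is the minimum of
#' its scaled values over all trajectories containing it; cells on no
#' trajectory get `NA`.
#'
#' @param embedding a [pre_embedding()].
#' @param trajectories a [infer_trajectories()] result.
#' @param mode `"cumulative"` (path length along the ordering, default) or
#'   `"direct"` (straight-line distance to the starting cell).
#' @return Tibble with `cell` (name), `pseudotime` and per-cell trajectory
#'   membership count.
#' @export
trajectory_pseudotime <- function(embedding, trajectories,
                                  mode = c("cumulative", "direct")) {
  mode <- match.arg(mode)
  stopifnot(inherits(embedding, "pre_embedding"),
            inherits(trajectories, "trajectory_set"))
  coords <- embedding$coords
  n <- nrow(coords)
  best <- rep(NA_real_, n)
  n_traj <- integer(n)
  for (tr in trajectories$trajectories) {
    o <- tr$ordering
    if (nrow(o) == 0) next
    xy <- coords[o$cell, , drop = FALSE]
    if (mode == "cumulative") {
      steps <- sqrt(rowSums((xy - xy[c(1, seq_len(nrow(xy) - 1)), ,
                                     drop = FALSE])^2))
      raw <- cumsum(steps)
    } else {
      raw <- sqrt(rowSums((xy - matrix(xy[1, ], nrow(xy), 2,
                                       byrow = TRUE))^2))
    }
    scaled <- numeric(length(raw))
    for (s in unique(o$segment)) {
      idx <- which(o$segment == s)
      v <- raw[idx]
      rng <- max(v) - min(v)
      scaled[idx] <- if (rng > 0) (v - min(v)) / rng + (s - 1) else s - 1
    }
    upd <- is.na(best[o$cell]) | scaled < best[o$cell]
    best[o$cell[upd]] <- scaled[upd]
    n_traj[o$cell] <- n_traj[o$cell] + 1L
  }
  cells <- rownames(coords)
  if (is.null(cells)) cells <- paste0("cell", seq_len(n))
  if (any(is.na(best))) {
    warning(sum(is.na(best)), " cell(s) lie on no trajectory; ",
            "their pseudotime is NA")
  }
  tibble::tibble(cell = cells, pseudotime = best, n_trajectories = n_traj)
}
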