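make_p <- function(rows) {
  P <- do.call(rbind, rows)
  P / rowSums(P)
}

test_that("transition cells are tallied by their top membership pair", {
  P <- make_p(list(c(0.45, 0.40, 0.15),
                   c(0.50, 0.35, 0.15),
                   c(0.40, 0.38, 0.22),
                   c(0.90, 0.05, 0.05)))
  g <- build_transition_graph(P, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(g$tc_counts[1, 2], 3L)
  expect_equal(sum(g$tc_counts[upper.tri(g$tc_counts)]), 3L)
  expect_equal(diag(g$tc_counts), rep(0L, 3), ignore_attr = TRUE)
  expect_equal(g$tc_fraction[1, 2], 3 / 4)
})

test_that("clusters linked to every other cluster become ICS candidates", {
  # TC between C2-C1 and C2-C3 only: C2 touches all, C1 and C3 do not
  P <- make_p(list(c(0.5, 0.45, 0.05),
                   c(0.05, 0.45, 0.5),
                   c(0.9, 0.05, 0.05),
                   c(0.05, 0.9, 0.05),
                   c(0.05, 0.05, 0.9)))
  g <- build_transition_graph(P, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(g$ics_candidates, 2L)
})

test_that("an empty transition-cell set warns and yields no edges", {
  P <- make_p(list(c(0.9, 0.1), c(0.1, 0.9)))
  expect_warning(g <- build_transition_graph(P, c(FALSE, FALSE)),
                 "no transition cells")
  expect_equal(sum(g$tc_counts), 0L)
  expect_length(g$ics_candidates, 0)
})

test_that("cells are ordered ascending then descending in plasticity", {
  P <- make_p(list(A = c(0.90, 0.10),
                   B = c(0.60, 0.40),
                   C = c(0.30, 0.70),
                   D = c(0.05, 0.95)))
  cpi <- c(0.15, 0.45, 0.40, 0.10)
  o <- align_cells(P, cpi, c(1, 2))
  expect_equal(o$cell, 1:4)          # A, B, C, D
  # the starting cell has the largest initial-cluster probability
  expect_equal(o$cell[1], unname(which.max(P[, 1])))
  # one-hot cells in a single cluster: stable ascending-CPI order
  P1 <- make_p(list(c(1, 0), c(1, 0), c(1, 0)))
  o1 <- align_cells(P1, c(0, 0, 0), 1)
  expect_equal(o1$cell, 1:3)
})

test_that("branching neighbor graphs enumerate the expected paths", {
  # four states: E(1)-I1(2), I1-I2(3), I1-QM(4), I2-QM; start at E
  anchors <- lapply(1:4, function(j) {
    v <- rep(0.04, 4); v[j] <- 0.88; v
  })
  tcs <- list(c(0.47, 0.43, 0.05, 0.05),   # E-I1
              c(0.05, 0.47, 0.43, 0.05),   # I1-I2
              c(0.05, 0.47, 0.05, 0.43),   # I1-QM
              c(0.05, 0.05, 0.47, 0.43))   # I2-QM
  P <- make_p(c(rep(anchors, each = 5), tcs))
  tc_mask <- c(rep(FALSE, 20), rep(TRUE, 4))
  g <- build_transition_graph(P, tc_mask)
  ts <- infer_trajectories(g, initial_cluster = 1, P,
                           cell_plasticity_index(P))
  paths <- vapply(ts$trajectories,
                  function(tr) paste(tr$cluster_path, collapse = "-"),
                  character(1))
  expect_true("1-2-3-4" %in% paths)
  expect_true("1-2-4" %in% paths)
  # probabilities are fractions of all cells; full path collects everything
  full <- ts$trajectories[[match("1-2-3-4", paths)]]
  expect_equal(full$probability, 1)
  probs <- vapply(ts$trajectories, `[[`, numeric(1), "probability")
  expect_true(all(diff(probs) <= 0))
  expect_true(all(probs <= 1))
})

test_that("trajectory probability counts the collected fraction of cells", {
  # 90 cells on a two-cluster path, 10 committed to an off-path cluster
  rows <- c(replicate(45, c(0.9, 0.05, 0.05), simplify = FALSE),
            replicate(45, c(0.05, 0.9, 0.05), simplify = FALSE),
            replicate(10, c(0.05, 0.05, 0.9), simplify = FALSE))
  P <- make_p(rows)
  tc_mask <- rep(FALSE, 100)
  tc_mask[1] <- TRUE   # one TC between C1 and C2 keeps them neighbors
  P[1, ] <- c(0.46, 0.44, 0.10)
  suppressWarnings(g <- build_transition_graph(P, tc_mask))
  ts <- infer_trajectories(g, 1, P, cell_plasticity_index(P),
                           max_length = 2)
  expect_equal(ts$trajectories[[1]]$probability, 0.9)
})

test_that("pseudotime accumulates distance and scales segments to unit windows", {
  coords <- cbind(c(0, 1, 3), c(0, 0, 0))
  rownames(coords) <- paste0("c", 1:3)
  emb <- structure(list(coords = coords), class = "pre_embedding")
  ts <- structure(list(trajectories = list(list(
    cluster_path = c(1, 2), cells = 1:3,
    ordering = tibble::tibble(cell = 1:3, segment = 1L))),
    initial_cluster = 1, n_cells = 3), class = "trajectory_set")
  pt <- trajectory_pseudotime(emb, ts)
  # raw distances 0, 1, 3 min-max scaled onto [0, 1]
  expect_equal(pt$pseudotime, c(0, 1 / 3, 1))

  # a cell on two trajectories takes the smaller scaled value
  coords2 <- cbind(c(0, 1, 3, 0.5), 0)
  rownames(coords2) <- paste0("c", 1:4)
  emb2 <- structure(list(coords = coords2), class = "pre_embedding")
  ts2 <- structure(list(trajectories = list(
    list(cluster_path = c(1, 2), cells = 1:3,
         ordering = tibble::tibble(cell = 1:3, segment = 1L)),
    list(cluster_path = c(1, 3), cells = c(1L, 4L, 2L),
         ordering = tibble::tibble(cell = c(1L, 4L, 2L), segment = 1L))),
    initial_cluster = 1, n_cells = 4), class = "trajectory_set")
  pt2 <- suppressWarnings(trajectory_pseudotime(emb2, ts2))
  # cell 2: 1/3 on the first trajectory, 1.0 on the second -> 1/3
  expect_equal(pt2$pseudotime[2], 1 / 3)
})

test_that("pseudotime is nondecreasing along a trajectory ordering", {
  fx <- analysis_fixture()
  ta <- fx$analysis
  tr <- ta$trajectories$trajectories[[1]]
  single <- structure(list(trajectories = list(tr),
                           initial_cluster = ta$trajectories$initial_cluster,
                           n_cells = ta$trajectories$n_cells),
                      class = "trajectory_set")
  pt <- suppressWarnings(trajectory_pseudotime(ta$embedding, single))
  along <- pt$pseudotime[tr$ordering$cell]
  expect_true(all(diff(along) >= -1e-12))
})

test_that("simulated EMT data recovers the E-I1-I2-M axis", {
  fx <- analysis_fixture()
  ta <- fx$analysis
  truth <- fx$truth
  lab <- ta$clustering$hard_labels
  # map clusters to dominant true phenotype (settled cells only)
  settled <- truth != "TC"
  mapping <- vapply(seq_len(ta$clustering$k), function(j) {
    names(which.max(table(truth[settled & lab == j])))
  }, character(1))
  # starting from the epithelial cluster (the user-chosen initial state,
  # as when day-0 or marker-identified cells anchor the trajectory)
  e_cluster <- which(mapping == "E")
  ts <- infer_trajectories(ta$graph, e_cluster, ta$clustering$P,
                           ta$clustering$cpi)
  top_path <- ts$trajectories[[1]]$cluster_path
  expect_equal(unname(mapping[top_path]), c("E", "I1", "I2", "M"))
})
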