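planted_fit <- function(lambda2 = 10, seed = 4, double_gene = NULL) {
  set.seed(99)
  n <- 30; k <- 3; m <- 12
  H_s <- matrix(0, n, k)
  H_s[cbind(seq_len(n), rep(1:3, each = 10))] <- 1
  H_s <- H_s + matrix(runif(n * k, 0, 0.05), n, k)
  W0 <- matrix(0.02, k, m)
  W0[1, 1:4] <- 1; W0[2, 5:8] <- 1; W0[3, 9:12] <- 1
  D_s <- t(H_s %*% W0)
  rownames(D_s) <- paste0("g", 1:m)
  colnames(D_s) <- paste0("c", 1:n)
  if (!is.null(double_gene)) D_s[double_gene, ] <- 2 * D_s[double_gene, ]
  list(fit = fit_gene_cluster(D_s, H_s, lambda2 = lambda2, seed = seed),
       W0 = W0, D_s = D_s, H_s = H_s)
}

test_that("planted gene-cluster structure is recovered", {
  pf <- planted_fit(lambda2 = 20)
  # objective trace is non-increasing
  expect_true(all(diff(pf$fit$objective_trace) <= 1e-8))
  # argmax cluster per gene matches the planted block pattern
  expect_equal(unname(apply(pf$fit$W, 2, which.max)),
               unname(apply(pf$W0, 2, which.max)))
  # zero data with no coupling leaves W at zero
  fit0 <- fit_gene_cluster(matrix(0, 4, 6,
                                  dimnames = list(paste0("g", 1:4),
                                                  paste0("c", 1:6))),
                           matrix(0.5, 6, 2), lambda2 = 0, seed = 1)
  expect_lt(max(fit0$W), 1e-6)
  # dimension mismatch is refused
  expect_error(fit_gene_cluster(matrix(1, 3, 5), matrix(1, 4, 2)),
               "5 cells")
})

test_that("doubling a gene's expression doubles its loading column", {
  f1 <- planted_fit(lambda2 = 20)
  f2 <- planted_fit(lambda2 = 20, double_gene = "g3")
  ratio <- f2$fit$W[, "g3"] / pmax(f1$fit$W[, "g3"], 1e-12)
  expect_equal(unname(ratio[which.max(f1$fit$W[, "g3"])]), 2,
               tolerance = 0.05)
})

test_that("marker calls follow the normalized top-two gap rule", {
  W <- cbind(clear = c(0.6, 0.3, 0.1),
             tied = c(0.34, 0.33, 0.33),
             uniform = c(1, 1, 1) / 3)
  rownames(W) <- paste0("C", 1:3)
  mk <- marker_genes(W, min_gap = 0.03)
  expect_equal(mk$gene, "clear")
  expect_equal(mk$cluster, "C1")
  expect_equal(mk$gap, 0.3, tolerance = 1e-12)
})

test_that("marker structure is stable over the coupling range and relabeling", {
  arg5 <- apply(planted_fit(lambda2 = 5)$fit$W, 2, which.max)
  arg20 <- apply(planted_fit(lambda2 = 20)$fit$W, 2, which.max)
  expect_equal(arg5, arg20)
  # permuting cluster columns of H_s permutes rows of W accordingly
  pf <- planted_fit(lambda2 = 10)
  perm <- c(2, 3, 1)
  fit_p <- fit_gene_cluster(pf$D_s, pf$H_s[, perm], lambda2 = 10, seed = 4)
  expect_equal(unname(perm[apply(fit_p$W, 2, which.max)]),
               unname(apply(pf$fit$W, 2, which.max)))
})

test_that("transition genes are screened by rank correlation and direction", {
  set.seed(7)
  n <- 10
  D <- rbind(up = seq_len(n),
             down = rev(seq_len(n)),
             weak = c(3, 1, 6, 2, 9, 4, 10, 5, 7, 8) * 0.5,
             flat = rep(2, n))
  colnames(D) <- paste0("c", 1:n)
  expect_warning(tg <- transition_genes(D, 1:n, rho_threshold = 0.64),
                 "constant")
  expect_equal(tg$gene[tg$direction == "up"], "up")
  expect_equal(tg$rho[tg$gene == "up"], 1)
  expect_equal(tg$rho[tg$gene == "down"], -1)
  # |rho| below the cutoff is not reported
  rho_weak <- stats::cor(D["weak", ], 1:n, method = "spearman")
  expect_lt(abs(rho_weak), 0.64)
  expect_gte(abs(rho_weak), 0.5)
  expect_false("weak" %in% tg$gene)
  tg_loose <- suppressWarnings(transition_genes(D, 1:n, rho_threshold = 0.5))
  expect_true("weak" %in% tg_loose$gene)
})

test_that("epithelial and mesenchymal readouts mark their states on simulated data", {
  fx <- analysis_fixture()
  ta <- fx$analysis
  truth <- fx$truth
  lab <- ta$clustering$hard_labels
  settled <- truth != "TC"
  mapping <- vapply(seq_len(ta$clustering$k), function(j) {
    names(which.max(table(truth[settled & lab == j])))
  }, character(1))
  mk <- ta$genes[[1]]$markers
  e_cluster <- paste0("C", which(mapping == "E"))
  m_cluster <- paste0("C", which(mapping == "M"))
  expect_equal(mk$cluster[mk$gene == "ECAD"], e_cluster)
  expect_equal(mk$cluster[mk$gene == "VIM"], m_cluster)
})
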