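# shared fixtures, computed once per test run

.fixtures <- new.env(parent = emptyenv())

emt_fixture <- function() {
  if (is.null(.fixtures$sim)) {
    net <- emt_network()
    att <- steady_states(net, n_grid = 200, seed = 1)
    sim <- run_emt_simulation(emt_sim_config(n_cycles = 1, seed = 7),
                              net, att)
    .fixtures$net <- net
    .fixtures$att <- att
    .fixtures$sim <- sim
  }
  list(net = .fixtures$net, att = .fixtures$att, sim = .fixtures$sim)
}

analysis_fixture <- function() {
  if (is.null(.fixtures$analysis)) {
    fx <- emt_fixture()
    snap <- fx$sim$snapshots[[1]]
    .fixtures$analysis <- quantify_transitions(snap$expression, seed = 11)
    .fixtures$truth <- snap$cells$phenotype
  }
  list(analysis = .fixtures$analysis, truth = .fixtures$truth)
}

# exact block-structured consensus matrix
block_consensus <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  M <- matrix(between, n, n)
  M[outer(lab, lab, `==`)] <- within
  diag(M) <- 1
  dimnames(M) <- list(paste0("c", 1:n), paste0("c", 1:n))
  M
}

# small named expression matrix
toy_expression <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
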