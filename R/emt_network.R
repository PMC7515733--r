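#' @importFrom rlang .data
NULL

# Hill activation / repression, vectorized.
hill_act <- function(x, K, n) {
  xn <- (x / K)^n
  xn / (1 + xn)
}
hill_rep <- function(x, K, n) 1 / (1 + (x / K)^n)

#' Species of the default EMT regulatory circuit
#' @return Character vector of the 18 species names.
#' @export
emt_species <- function() {
  c("tgfb_m", "TGFB", "SMAD",
    "snail_m", "SNAIL", "mir34",
    "zeb_m", "ZEB", "mir200", "mir1199",
    "ovol2_m", "OVOL2", "grhl2_m", "GRHL2",
    "ecad_m", "ECAD", "vim_m", "VIM")
}

#' Default parameters of the EMT circuit
#'
#' The circuit is organized as a cascade of three positive-feedback switches:
#' a SNAIL/miR-34 module, a ZEB/miR-200/miR-1199 module whose self-activation
#' is licensed by high SNAIL, and an autocrine TGF-beta/SMAD loop licensed by
#' high ZEB. Epithelial guards (OVOL2, GRHL2) are repressed by ZEB and damp
#' the ZEB module; E-cadherin and Vimentin are readouts. Successive switch
#' states give exactly four stable phenotypes (E, I1, I2, M) at these
#' defaults. `timescale` converts the dimensionless kinetics to per-hour
#' rates; relaxation to an attractor takes a few tens of hours, fast relative
#' to the ~700 h cell cycle.
#'
#' @return Named list of rate parameters.
#' @export
emt_default_parameters <- function() {
  list(
    timescale = 0.1,     # 1/h; sets absolute kinetic rates
    basal = 0.12,        # basal mRNA production of switch modules
    self_act = 3,        # fold self-activation of switch modules
    hill_self = 4,       # Hill coefficient of self-activation
    gate_K = 1.5,        # threshold for licensing the next switch
    gate_n = 4,
    smad_gain = 0.5,     # SMAD activation by TGFB + external signal
    smad_snail = 0.4,    # SMAD -> snail transcription
    mir_floor = 0.1,     # basal microRNA production
    mir_act = 0.9,
    tl_floor_snail = 0.4, # translation floor under full miR-34 repression
    tl_floor_zeb = 0.3,
    mir34_K = 0.6, mir200_K = 0.5, mir1199_K = 1,
    guard_floor = 0.6,   # OVOL2/GRHL2 damping floor on zeb transcription
    ecad_max = 3.3,
    ecad_snail_floor = 0.35,
    ecad_zeb_floor = 0.25,
    ecad_smad_floor = 0.6,
    vim_basal = 0.05,
    vim_snail = 1.0, vim_zeb = 1.6, vim_smad = 0.8
  )
}

#' Construct an EMT regulatory network
#'
#' @param parameters named parameter list, see [emt_default_parameters()].
#' @param signal external TGF-beta input level (0 = no induction).
#' @return An object of class `emt_network`.
#' @export
emt_network <- function(parameters = emt_default_parameters(), signal = 0) {
  defaults <- emt_default_parameters()
  missing <- setdiff(names(defaults), names(parameters))
  parameters[missing] <- defaults[missing]
  stopifnot(signal >= 0)
  structure(list(species = emt_species(), parameters = parameters,
                 signal = signal),
            class = "emt_network")
}

#' Deterministic rates of the EMT circuit
#'
#' Evaluates d(state)/dt for one or many cells at once.
#'
#' @param state numeric matrix (18 species x n cells) or vector of length 18,
#'   nonnegative.
#' @param net an [emt_network()].
#' @return Object of the same shape as `state`.
#' @export
emt_rates <- function(state, net) {
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, ncol = 1)
  stopifnot(nrow(state) == 18)
  p <- net$parameters
  s <- function(nm) state[match(nm, emt_species()), , drop = TRUE]
  tgfb_m <- s("tgfb_m"); TGFB <- s("TGFB"); SMAD <- s("SMAD")
  snail_m <- s("snail_m"); SNAIL <- s("SNAIL"); mir34 <- s("mir34")
  zeb_m <- s("zeb_m"); ZEB <- s("ZEB")
  mir200 <- s("mir200"); mir1199 <- s("mir1199")
  ovol2_m <- s("ovol2_m"); OVOL2 <- s("OVOL2")
  grhl2_m <- s("grhl2_m"); GRHL2 <- s("GRHL2")
  ecad_m <- s("ecad_m"); ECAD <- s("ECAD")
  vim_m <- s("vim_m"); VIM <- s("VIM")

  gate_snail <- hill_act(SNAIL, p$gate_K, p$gate_n)
  gate_zeb <- hill_act(ZEB, p$gate_K, p$gate_n)

  d <- rbind(
    # autocrine TGF-beta loop, licensed by high ZEB
    tgfb_m = gate_zeb * (p$basal + p$self_act * hill_act(TGFB, 1, p$hill_self)) - tgfb_m,
    TGFB = tgfb_m - TGFB,
    SMAD = p$smad_gain * (net$signal + TGFB) - SMAD,
    # SNAIL switch, pushed by SMAD, translationally damped by miR-34
    snail_m = p$basal + p$self_act * hill_act(SNAIL, 1, p$hill_self) +
      p$smad_snail * hill_act(SMAD, 1, 2) - snail_m,
    SNAIL = snail_m * (p$tl_floor_snail +
                         (1 - p$tl_floor_snail) * hill_rep(mir34, p$mir34_K, 2)) - SNAIL,
    mir34 = p$mir_floor + p$mir_act * hill_rep(SNAIL, 1, 2) - mir34,
    # ZEB switch, licensed by SNAIL, damped by epithelial guards and microRNAs
    zeb_m = gate_snail * (p$basal + p$self_act * hill_act(ZEB, 1, p$hill_self)) *
      (p$guard_floor + (1 - p$guard_floor) * hill_rep(OVOL2 + GRHL2, 2, 2)) *
      (0.7 + 0.3 * hill_rep(mir1199, p$mir1199_K, 2)) - zeb_m,
    ZEB = zeb_m * (p$tl_floor_zeb +
                     (1 - p$tl_floor_zeb) * hill_rep(mir200, p$mir200_K, 2)) - ZEB,
    mir200 = p$mir_floor + p$mir_act * hill_rep(ZEB, 1, 2) - mir200,
    mir1199 = p$mir_floor + p$mir_act * hill_rep(ZEB, 1, 2) - mir1199,
    # epithelial guards
    ovol2_m = p$mir_floor + p$mir_act * hill_rep(ZEB, 1.5, 2) - ovol2_m,
    OVOL2 = ovol2_m - OVOL2,
    grhl2_m = p$mir_floor + p$mir_act * hill_rep(ZEB, 1.5, 2) - grhl2_m,
    GRHL2 = grhl2_m - GRHL2,
    # readouts
    ecad_m = 0.05 + p$ecad_max *
      (p$ecad_snail_floor + (1 - p$ecad_snail_floor) * hill_rep(SNAIL, 1.5, 2)) *
      (p$ecad_zeb_floor + (1 - p$ecad_zeb_floor) * hill_rep(ZEB, 1.2, 2)) *
      (p$ecad_smad_floor + (1 - p$ecad_smad_floor) * hill_rep(SMAD, 1.5, 2)) - ecad_m,
    ECAD = ecad_m - ECAD,
    vim_m = p$vim_basal + p$vim_snail * hill_act(SNAIL, 2.5, 2) +
      p$vim_zeb * hill_act(ZEB, 1.2, 2) +
      p$vim_smad * hill_act(SMAD, 1.5, 2) - vim_m,
    VIM = vim_m - VIM
  )
  d <- d * p$timescale
  rownames(d) <- emt_species()
  if (vec) d[, 1] else d
}

#' Find the stable steady states of the circuit
#'
#' Integrates the deterministic system from a grid of random initial
#' conditions until convergence, clusters the endpoints into distinct
#' attractors, confirms local stability through the Jacobian spectrum, and
#' labels attractors by their E-cadherin/Vimentin levels: E has the highest
#' ECAD, M the highest VIM, and the intermediate states I1/I2 are ordered by
#' decreasing ECAD dominance.
#'
#' @param net an [emt_network()].
#' @param n_grid number of random initial conditions.
#' @param tol endpoint clustering tolerance (Euclidean).
#' @param t_max integration horizon in hours.
#' @param seed seed for the initial-condition draw.
#' @return Tibble-flavoured list of class `emt_attractors` with fields
#'   `states` (attractor x species matrix), `phenotype`, `n_converged`.
#' @export
steady_states <- function(net, n_grid = 1000, tol = 0.05, t_max = 2000,
                          seed = 1L) {
  stopifnot(inherits(net, "emt_network"))
  set.seed(as.integer(seed))
  n_sp <- 18L
  # initial conditions spanning the physiological range, plus near-zero states
  x <- matrix(stats::runif(n_sp * n_grid, 0, 6), n_sp, n_grid)
  dt <- 1           # h; deterministic relaxation, rates ~0.1/h
  n_steps <- ceiling(t_max / dt)
  for (i in seq_len(n_steps)) {
    x <- x + emt_rates(x, net) * dt
    x[x < 0] <- 0
  }
  rate_norm <- sqrt(colSums(emt_rates(x, net)^2))
  converged <- rate_norm < 1e-6
  if (!all(converged)) {
    warning(sum(!converged), " of ", n_grid,
            " trajectories had not converged and were excluded")
  }
  x <- x[, converged, drop = FALSE]
  if (ncol(x) == 0) stop("no converged trajectories")
  # cluster endpoints into attractors
  reps <- x[, 1, drop = FALSE]
  counts <- 1L
  for (j in seq_len(ncol(x))[-1]) {
    dists <- sqrt(colSums((reps - x[, j])^2))
    hit <- which(dists < tol)
    if (length(hit) > 0) {
      counts[hit[1]] <- counts[hit[1]] + 1L
    } else {
      reps <- cbind(reps, x[, j])
      counts <- c(counts, 1L)
    }
  }
  # polish each representative and check stability
  keep <- logical(ncol(reps))
  for (j in seq_len(ncol(reps))) {
    y <- reps[, j]
    for (i in 1:2000) {
      y <- pmax(y + emt_rates(y, net) * dt, 0)
    }
    reps[, j] <- y
    J <- emt_jacobian(y, net)
    keep[j] <- all(Re(eigen(J, only.values = TRUE)$values) < 1e-8)
  }
  reps <- reps[, keep, drop = FALSE]
  counts <- counts[keep]
  rownames(reps) <- emt_species()
  states <- t(reps)
  phenotype <- label_attractors(states)
  ord <- order(match(phenotype, c("E", "I1", "I2", "M")))
  structure(list(states = states[ord, , drop = FALSE],
                 phenotype = phenotype[ord],
                 basin_counts = counts[ord],
                 n_converged = sum(converged)),
            class = "emt_attractors")
}

# numeric Jacobian by central differences
emt_jacobian <- function(y, net, h = 1e-5) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    yp <- y; ym <- y
    yp[i] <- yp[i] + h
    ym[i] <- max(ym[i] - h, 0)
    J[, i] <- (emt_rates(yp, net) - emt_rates(ym, net)) / (yp[i] - ym[i])
  }
  J
}

# label attractor rows by ECAD/VIM dominance
label_attractors <- function(states) {
  k <- nrow(states)
  ecad <- states[, "ECAD"]
  vim <- states[, "VIM"]
  lab <- rep(NA_character_, k)
  if (k == 1) return("E")
  lab[which.max(ecad)] <- "E"
  lab[which.max(vim)] <- "M"
  rest <- which(is.na(lab))
  if (length(rest) > 0) {
    # intermediates ordered by ECAD dominance: I1 is the ECAD-stronger one
    rest <- rest[order(ecad[rest] - vim[rest], decreasing = TRUE)]
    lab[rest] <- paste0("I", seq_along(rest))
  }
  lab
}

#' @export
print.emt_attractors <- function(x, ...) {
  cat("<emt_attractors> ", nrow(x$states), " stable states: ",
      paste(x$phenotype, collapse = ", "), "\n", sep = "")
  m <- round(x$states[, c("ECAD", "VIM", "SNAIL", "ZEB", "TGFB")], 2)
  rownames(m) <- x$phenotype
  print(m)
  invisible(x)
}

#' Classify cell states against the attractors
#'
#' A cell is assigned the phenotype of the nearest attractor if it lies
#' within `radius_frac` of the minimum inter-attractor distance; otherwise it
#' is a transition cell (`"TC"`).
#'
#' @param state 18 x n matrix (or length-18 vector) of cell states.
#' @param attractors an `emt_attractors` object.
#' @param radius_frac capture radius as a fraction of the minimum
#'   inter-attractor distance.
#' @return Character vector of phenotypes.
#' @export
classify_phenotype <- function(state, attractors, radius_frac = 0.1) {
  if (is.null(dim(state))) state <- matrix(state, ncol = 1)
  A <- attractors$states
  dmat <- apply(A, 1, function(a) sqrt(colSums((state - a)^2)))
  dmat <- matrix(dmat, ncol = nrow(A))
  r <- radius_frac * min(stats::dist(A))
  nearest <- max.col(-dmat, ties.method = "first")
  out <- attractors$phenotype[nearest]
  out[dmat[cbind(seq_len(nrow(dmat)), nearest)] > r] <- "TC"
  out
}
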