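#' Configuration of the multiscale EMT simulation
#'
#' Agents carry the 18-species circuit state. Cells divide with
#' normally-distributed waiting times, pass perturbed expression to their
#' daughters, carry a finite division budget, and die on a normal clock once
#' the budget is exhausted. Between events every cell's expression follows
#' the stochastic circuit dynamics (multiplicative noise, Euler-Maruyama).
#'
#' @param n_initial named integer vector of initial cells per phenotype.
#' @param division_mean,division_sd division waiting time ~ Normal(700, 200) h
#'   (negative draws resampled).
#' @param budget_min,budget_max division budget ~ discrete uniform on
#'   `{budget_min, ..., budget_max}`.
#' @param death_mean,death_sd post-budget survival ~ Normal(1000, 100) h.
#' @param sde_sigma multiplicative expression-noise amplitude.
#' @param division_noise_sd standard deviation of the per-species division
#'   perturbation (daughters receive mother +/- mother * Normal(0, sd)).
#' @param dt Euler-Maruyama step in hours (must be <= 1).
#' @param n_cycles number of cell cycles simulated.
#' @param cycle_length snapshot interval in hours (one mean cell cycle).
#' @param proliferate_i1 if `FALSE`, cells in the I1 state do not divide
#'   (division is deferred until the cell leaves I1).
#' @param radius_frac phenotype capture radius, see [classify_phenotype()].
#' @param seed integer seed.
#' @return List of class `emt_sim_config`.
#' @export
emt_sim_config <- function(n_initial = c(E = 50, I1 = 50, I2 = 50, M = 50),
                           division_mean = 700, division_sd = 200,
                           budget_min = 2, budget_max = 7,
                           death_mean = 1000, death_sd = 100,
                           sde_sigma = 0.01, division_noise_sd = 0.7,
                           dt = 0.1, n_cycles = 5, cycle_length = 700,
                           proliferate_i1 = TRUE, radius_frac = 0.1,
                           seed = 1L) {
  stopifnot(dt > 0, dt <= 1, n_cycles >= 1, all(n_initial >= 0),
            division_mean > 0, death_mean > 0, sde_sigma >= 0,
            division_noise_sd >= 0, budget_min >= 0,
            budget_max >= budget_min)
  structure(as.list(environment()), class = "emt_sim_config")
}

rtrunc_norm <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Integrate cell expression under multiplicative noise
#'
#' Euler-Maruyama steps of dI = f(I) dt + sigma I dW, clamping negative
#' excursions at zero. Columns are cells and evolve independently.
#'
#' @param state 18 x n matrix (or length-18 vector) of nonnegative states.
#' @param net an [emt_network()].
#' @param dt step in hours.
#' @param sigma multiplicative noise amplitude.
#' @param duration total time in hours (takes `round(duration/dt)` steps).
#' @return Matrix (or vector) of the same shape.
#' @export
integrate_cells <- function(state, net, dt = 0.1, sigma = 0.01,
                            duration = dt) {
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, ncol = 1)
  if (any(!is.finite(state))) {
    stop("non-finite state in cell(s) ",
         paste(which(colSums(!is.finite(state)) > 0), collapse = ", "))
  }
  n_steps <- max(1L, round(duration / dt))
  sqdt <- sqrt(dt)
  for (i in seq_len(n_steps)) {
    drift <- emt_rates(state, net) * dt
    if (sigma > 0) {
      state <- state + drift + sigma * state * sqdt *
        matrix(stats::rnorm(length(state)), nrow(state), ncol(state))
    } else {
      state <- state + drift
    }
    state[state < 0] <- 0
  }
  if (vec) state[, 1] else state
}

#' Divide a cell into two daughters
#'
#' The mother state is perturbed per species by `state * Normal(0, sd)`; one
#' daughter receives the mother state plus the perturbation and the other the
#' mother state minus it, both clamped at zero.
#'
#' @param state length-18 mother state.
#' @param noise_sd division perturbation standard deviation.
#' @return List with `daughter1`, `daughter2`, `noise`.
#' @export
divide_cell <- function(state, noise_sd = 0.7) {
  noise <- state * stats::rnorm(length(state), 0, noise_sd)
  list(daughter1 = pmax(state + noise, 0),
       daughter2 = pmax(state - noise, 0),
       noise = noise)
}

#' Run the multiscale EMT simulation
#'
#' Event-driven population simulation: expression integrates between events;
#' division replaces the mother by two daughters with perturbed expression,
#' decremented budgets and fresh clocks; cells with spent budgets die on
#' their death clock. At the end of every cycle a snapshot of the living
#' population is recorded.
#'
#' @param config an [emt_sim_config()].
#' @param net an [emt_network()]; default network at zero external signal.
#' @param attractors precomputed [steady_states()] (computed if `NULL`).
#' @return Object of class `emt_simulation`: list with `snapshots` (one per
#'   cycle end; each holds `expression` 18 x n, `cells` tibble with id,
#'   parent, birth time, phenotype), `lineage` tibble over all cells ever
#'   created, `attractors`, `config`.
#' @export
run_emt_simulation <- function(config = emt_sim_config(),
                               net = emt_network(), attractors = NULL) {
  stopifnot(inherits(config, "emt_sim_config"))
  set.seed(as.integer(config$seed))
  if (is.null(attractors)) attractors <- steady_states(net)
  ph_init <- rep(names(config$n_initial), config$n_initial)
  n0 <- length(ph_init)
  if (n0 == 0) stop("no initial cells")
  idx <- match(ph_init, attractors$phenotype)
  if (any(is.na(idx))) stop("initial phenotypes not among the attractors")
  cap <- max(64L, 4L * n0)
  state <- matrix(0, 18, cap)
  state[, seq_len(n0)] <- t(attractors$states[idx, , drop = FALSE])

  id <- integer(cap); parent <- integer(cap); birth <- numeric(cap)
  budget <- integer(cap); next_div <- numeric(cap); death_at <- numeric(cap)
  alive <- logical(cap)
  sl <- seq_len(n0)
  id[sl] <- sl; parent[sl] <- NA_integer_; birth[sl] <- 0
  budget[sl] <- sample(seq(config$budget_min, config$budget_max), n0,
                       replace = TRUE)
  next_div[sl] <- rtrunc_norm(n0, config$division_mean, config$division_sd)
  death_at[sl] <- Inf
  alive[sl] <- TRUE
  n_cells <- n0
  next_id <- n0 + 1L
  died_at <- rep(NA_real_, cap)

  grow <- function() {
    extra <- ncol(state)
    state <<- cbind(state, matrix(0, 18, extra))
    id <<- c(id, integer(extra)); parent <<- c(parent, integer(extra))
    birth <<- c(birth, numeric(extra)); budget <<- c(budget, integer(extra))
    next_div <<- c(next_div, numeric(extra))
    death_at <<- c(death_at, numeric(extra))
    alive <<- c(alive, logical(extra))
    died_at <<- c(died_at, rep(NA_real_, extra))
  }

  ev_time <- numeric(0); ev_id <- integer(0); ev_ph <- character(0)
  t_end <- config$n_cycles * config$cycle_length
  snap_times <- seq_len(config$n_cycles) * config$cycle_length
  snapshots <- vector("list", config$n_cycles)
  t <- 0
  dt <- config$dt
  snap_i <- 1L
  while (t < t_end - 1e-9) {
    live <- which(alive)
    if (length(live) == 0) {
      warning("population extinct at t = ", t, " h")
      break
    }
    state[, live] <- integrate_cells(state[, live, drop = FALSE], net,
                                     dt = dt, sigma = config$sde_sigma)
    t <- t + dt
    # deaths
    dead <- live[budget[live] == 0L & death_at[live] <= t]
    if (length(dead) > 0) {
      alive[dead] <- FALSE
      died_at[dead] <- t
    }
    # divisions
    due <- which(alive & budget > 0L & next_div <= t)
    for (i in due) {
      ph <- classify_phenotype(state[, i], attractors, config$radius_frac)
      if (!config$proliferate_i1 && ph == "I1") {
        next_div[i] <- t + rtrunc_norm(1, config$division_mean,
                                       config$division_sd)
        next
      }
      ev_time <- c(ev_time, t)
      ev_id <- c(ev_id, id[i])
      ev_ph <- c(ev_ph, ph)
      while (n_cells + 2L > length(alive)) grow()
      dg <- divide_cell(state[, i], config$division_noise_sd)
      b <- budget[i] - 1L
      for (which_d in 1:2) {
        j <- n_cells + which_d
        state[, j] <- if (which_d == 1) dg$daughter1 else dg$daughter2
        id[j] <- next_id; next_id <- next_id + 1L
        parent[j] <- id[i]; birth[j] <- t
        budget[j] <- b
        if (b > 0L) {
          next_div[j] <- t + rtrunc_norm(1, config$division_mean,
                                         config$division_sd)
          death_at[j] <- Inf
        } else {
          next_div[j] <- Inf
          death_at[j] <- t + rtrunc_norm(1, config$death_mean,
                                         config$death_sd)
        }
        alive[j] <- TRUE
      }
      n_cells <- n_cells + 2L
      alive[i] <- FALSE
      died_at[i] <- t
    }
    # snapshot
    if (snap_i <= length(snap_times) && t >= snap_times[snap_i] - 1e-9) {
      live <- which(alive)
      expr <- state[, live, drop = FALSE]
      rownames(expr) <- emt_species()
      colnames(expr) <- paste0("cell", id[live])
      snapshots[[snap_i]] <- list(
        time = snap_times[snap_i],
        expression = expr,
        cells = tibble::tibble(
          id = id[live], parent_id = parent[live], birth_time = birth[live],
          divisions_remaining = budget[live],
          phenotype = classify_phenotype(expr, attractors,
                                         config$radius_frac)
        )
      )
      snap_i <- snap_i + 1L
    }
  }
  used <- seq_len(n_cells)
  lineage <- tibble::tibble(id = id[used], parent_id = parent[used],
                            birth_time = birth[used],
                            death_time = died_at[used],
                            final_budget = budget[used])
  structure(list(snapshots = snapshots[!vapply(snapshots, is.null, TRUE)],
                 lineage = lineage,
                 division_events = tibble::tibble(
                   time = ev_time, mother_id = ev_id,
                   mother_phenotype = ev_ph),
                 attractors = attractors,
                 config = config, net = net),
            class = "emt_simulation")
}

#' @export
print.emt_simulation <- function(x, ...) {
  sizes <- vapply(x$snapshots, function(s) ncol(s$expression), integer(1))
  cat("<emt_simulation> ", length(x$snapshots), " snapshots, sizes: ",
      paste(sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-cell table of a simulation snapshot
#'
#' @param x an `emt_simulation`.
#' @param cycle which snapshot (default: first).
#' @param ... unused.
#' @return Tibble with cell metadata and one column per species.
#' @method tidy emt_simulation
#' @export
tidy.emt_simulation <- function(x, cycle = 1, ...) {
  s <- x$snapshots[[cycle]]
  dplyr::bind_cols(s$cells,
                   tibble::as_tibble(t(s$expression)))
}

#' Summary counts per snapshot
#'
#' @param x an `emt_simulation`.
#' @param ... unused.
#' @return Tibble with one row per snapshot: time, n_cells, phenotype counts.
#' @method glance emt_simulation
#' @export
glance.emt_simulation <- function(x, ...) {
  purrr::map_dfr(x$snapshots, function(s) {
    tab <- table(factor(s$cells$phenotype,
                        levels = c("E", "I1", "I2", "M", "TC")))
    dplyr::bind_cols(tibble::tibble(time = s$time,
                                    n_cells = nrow(s$cells)),
                     tibble::as_tibble(as.list(tab)))
  })
}
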