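#' Parameters of the intermediate-state population model
#'
#' Defines the dimensionless population model of epithelial-to-mesenchymal
#' transition through `n_ics` intermediate cell states (ICS). The direct E->M
#' transition rate is the unit of time (fixed to 1); `alpha` is the reverse
#' direct rate M->E, `gamma` the forward rate along the indirect route through
#' the ICS chain (the indirect transition rate, ITR), and `beta * gamma` the
#' reverse rate along that chain. The model tracks population fractions
#' E(t), I_1(t), ..., I_N(t), M(t) starting from a pure epithelial population.
#'
#' @param alpha reverse direct transition rate M->E; must exceed 1 so that the
#'   epithelial state dominates at equilibrium without induction.
#' @param beta reverse factor along the indirect route (dimensionless,
#'   typically much smaller than 1).
#' @param gamma forward indirect transition rate between adjacent states on
#'   the E -> I1 -> ... -> IN -> M chain (typically much larger than 1).
#' @param n_ics number of intermediate cell states N (>= 0). With `n_ics = 0`
#'   the model collapses to the two-state system dE/dt = alpha M - E,
#'   dM/dt = E - alpha M.
#' @param sigma amplitude of the additive white noise applied to the epithelial
#'   equation in the stochastic variant.
#' @param t_max time horizon; `NULL` picks 50 / min(1, slowest nonzero decay
#'   rate of the system), long enough for the fractions to settle.
#' @param dt output (and Euler-Maruyama) time step.
#'
#' @return A list of class `pop_params`.
#' @export
pop_params <- function(alpha = 8, beta = 0.01, gamma = 20, n_ics = 2,
                       sigma = 1, t_max = NULL, dt = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 1)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  stopifnot(is.numeric(n_ics), length(n_ics) == 1, n_ics >= 0,
            n_ics == round(n_ics))
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  p <- structure(
    list(alpha = alpha, beta = beta, gamma = gamma, n_ics = as.integer(n_ics),
         sigma = sigma, t_max = t_max, dt = dt),
    class = "pop_params"
  )
  if (is.null(p$t_max)) {
    lam <- eigen(pop_rate_matrix(p), only.values = TRUE)$values
    decay <- abs(Re(lam))
    decay <- decay[decay > 1e-12]
    p$t_max <- 50 / min(1, min(decay))
  }
  stopifnot(p$t_max > 0)
  p
}

#' Rate matrix of the population model
#'
#' Returns the (N+2) x (N+2) linear rate matrix A such that
#' d/dt (E, I_1, ..., I_N, M) = A (E, I_1, ..., I_N, M). Its columns sum to
#' zero, so the total fraction is conserved.
#'
#' @param params a [pop_params()] object.
#' @return Numeric matrix with dimnames `c("E", "I1", ..., "M")`.
#' @export
pop_rate_matrix <- function(params) {
  a <- params$alpha; b <- params$beta; g <- params$gamma
  n <- params$n_ics
  d <- n + 2L
  nm <- c("E", if (n > 0) paste0("I", seq_len(n)), "M")
  A <- matrix(0, d, d, dimnames = list(nm, nm))
  if (n == 0L) {
    A["E", "E"] <- -1; A["E", "M"] <- a
    A["M", "E"] <- 1;  A["M", "M"] <- -a
    return(A)
  }
  # epithelial: alpha M + beta gamma I1 - (1 + gamma) E
  A["E", "E"] <- -(1 + g); A["E", "I1"] <- b * g; A["E", "M"] <- a
  # chain
  for (k in seq_len(n)) {
    row <- paste0("I", k)
    upstream <- if (k == 1L) "E" else paste0("I", k - 1L)
    downstream <- if (k == n) "M" else paste0("I", k + 1L)
    A[row, upstream] <- g
    A[row, downstream] <- A[row, downstream] + b * g
    A[row, row] <- -g * (1 + b)
  }
  # mesenchymal: E + gamma I_N - (alpha + beta gamma) M
  A["M", "E"] <- 1
  A["M", paste0("I", n)] <- A["M", paste0("I", n)] + g
  A["M", "M"] <- -(a + b * g)
  A
}

new_pop_trajectory <- function(times, states, params, stochastic,
                               m_paths = NULL) {
  structure(
    list(times = times, states = states, params = params,
         stochastic = stochastic, m_paths = m_paths),
    class = "pop_trajectory"
  )
}

#' Deterministic solve of the population model
#'
#' Integrates the linear system from the pure-epithelial initial condition
#' E(0) = 1 on a regular time grid using a stiff-capable solver (large `gamma`
#' or `n_ics` make the system stiff).
#'
#' @param params a [pop_params()] object.
#' @param rtol,atol solver tolerances.
#' @return A `pop_trajectory` with fields `times` (grid) and `states`
#'   (grid x (N+2) matrix with columns E, I1..IN, M).
#' @export
simulate_population <- function(params, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "pop_params"))
  A <- pop_rate_matrix(params)
  y0 <- c(1, rep(0, nrow(A) - 1L))
  names(y0) <- rownames(A)
  times <- seq(0, params$t_max, by = params$t_max / 2000)
  deriv <- function(t, y, p) list(as.vector(A %*% y))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      jacfunc = function(t, y, p) A, jactype = "fullusr")
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  colnames(states) <- rownames(A)
  new_pop_trajectory(times = sol[, 1], states = states, params = params,
                     stochastic = FALSE)
}

#' Stochastic solve of the population model
#'
#' Replaces the epithelial equation by its stochastic counterpart with an
#' additive white-noise term of amplitude `sigma` (Euler-Maruyama with step
#' `dt`); the other equations keep their deterministic right-hand sides.
#' Negative epithelial excursions are reflected at zero. An ensemble of
#' independent paths is integrated simultaneously.
#'
#' @param params a [pop_params()] object (`sigma`, `dt`, `t_max` are used).
#' @param seed integer seed.
#' @param n_paths number of independent sample paths.
#' @param keep_every store every `keep_every`-th time point (thin the output).
#' @return A `pop_trajectory`; `states` holds the ensemble mean and `m_paths`
#'   the stored time x path matrix of mesenchymal fractions.
#' @export
simulate_population_sde <- function(params, seed = 1L, n_paths = 1L,
                                    keep_every = 5L) {
  stopifnot(inherits(params, "pop_params"), n_paths >= 1)
  set.seed(as.integer(seed))
  A <- pop_rate_matrix(params)
  d <- nrow(A)
  dt <- params$dt
  n_steps <- ceiling(params$t_max / dt)
  keep_idx <- unique(c(seq(0L, n_steps, by = as.integer(keep_every)), n_steps))
  y <- matrix(0, d, n_paths)
  y[1, ] <- 1
  sqdt <- sqrt(dt)
  m_store <- matrix(NA_real_, length(keep_idx), n_paths)
  mean_store <- matrix(NA_real_, length(keep_idx), d)
  ki <- 1L
  m_store[1L, ] <- y[d, ]
  mean_store[1L, ] <- rowMeans(y)
  for (s in seq_len(n_steps)) {
    y <- y + (A %*% y) * dt
    y[1, ] <- y[1, ] + params$sigma * sqdt * stats::rnorm(n_paths)
    y[1, ] <- abs(y[1, ])   # reflect E at zero
    if (s == keep_idx[ki + 1L]) {
      ki <- ki + 1L
      m_store[ki, ] <- y[d, ]
      mean_store[ki, ] <- rowMeans(y)
    }
  }
  colnames(mean_store) <- rownames(A)
  new_pop_trajectory(times = keep_idx * dt, states = mean_store,
                     params = params, stochastic = TRUE, m_paths = m_store)
}

mes_fraction <- function(traj) traj$states[, ncol(traj$states)]

check_settled <- function(traj, rel_tol = 1e-6) {
  m <- mes_fraction(traj)
  tail_idx <- traj$times >= 0.9 * max(traj$times)
  m_end <- m[length(m)]
  drift <- max(abs(m[tail_idx] - m_end)) / max(abs(m_end), 1e-12)
  if (drift > rel_tol) {
    stop("trajectory has not settled (relative drift ", signif(drift, 3),
         " over the final 10%); increase t_max", call. = FALSE)
  }
  invisible(TRUE)
}

#' Adaptation sensitivity
#'
#' AS = (max_t M(t) - M(inf)) / max_t M(t): the relative overshoot of the
#' mesenchymal fraction above its settled level. Zero for monotone responses
#' (in particular for the two-state model without intermediate states, whose
#' closed-form M(t) is monotone); positive when the trajectory peaks and
#' adapts back down.
#'
#' @param traj a deterministic `pop_trajectory`.
#' @return A number in \[0, 1\].
#' @export
adaptation_sensitivity <- function(traj) {
  stopifnot(inherits(traj, "pop_trajectory"), !isTRUE(traj$stochastic))
  check_settled(traj)
  m <- mes_fraction(traj)
  m_max <- max(m)
  m_inf <- m[length(m)]
  max(0, (m_max - m_inf) / m_max)
}

#' Transition efficiency
#'
#' TE = M(inf): the settled mesenchymal fraction reached from a pure
#' epithelial population.
#'
#' @param traj a deterministic `pop_trajectory`.
#' @return A number in \[0, 1\].
#' @export
transition_efficiency <- function(traj) {
  stopifnot(inherits(traj, "pop_trajectory"), !isTRUE(traj$stochastic))
  check_settled(traj)
  m <- mes_fraction(traj)
  m[length(m)]
}

#' Noise attenuation
#'
#' NA_N = std(M~(t)) / mean(M~(t)): the coefficient of variation of the
#' stochastic mesenchymal fraction, computed per path and averaged over the
#' ensemble. Smaller values mean stronger attenuation of the injected
#' epithelial noise. The default window covers the whole path, i.e. the full
#' response to the onset of induction including its adaptation phase; pass
#' `window = 0.5` to restrict the CV to the settled final half instead.
#'
#' @param traj a stochastic `pop_trajectory` from [simulate_population_sde()].
#' @param window fraction of the horizon (from the end) over which the CV is
#'   taken; 1 = the whole path.
#' @return Mean coefficient of variation (a nonnegative number).
#' @export
noise_attenuation <- function(traj, window = 1) {
  stopifnot(inherits(traj, "pop_trajectory"), isTRUE(traj$stochastic))
  stopifnot(window > 0, window <= 1)
  idx <- traj$times >= (1 - window) * max(traj$times)
  m <- traj$m_paths[idx, , drop = FALSE]
  mu <- colMeans(m)
  if (any(mu <= 0)) stop("mean mesenchymal fraction not positive over window")
  cv <- apply(m, 2, stats::sd) / mu
  mean(cv)
}

#' Steady state of the deterministic model
#'
#' Exact settled fractions, computed from the null space of the rate matrix
#' normalized to sum to one (the columns of the rate matrix sum to zero, so
#' the total fraction is conserved and the kernel is one-dimensional).
#'
#' @param params a [pop_params()] object.
#' @return Named vector of settled fractions (E, I1..IN, M).
#' @export
pop_steady_state <- function(params) {
  A <- pop_rate_matrix(params)
  d <- nrow(A)
  # solve A x = 0, sum(x) = 1 by replacing the last row
  B <- rbind(A[-d, , drop = FALSE], rep(1, d))
  x <- solve(B, c(rep(0, d - 1L), 1))
  names(x) <- rownames(A)
  x
}

#' Sweep the population-model metrics over a parameter grid
#'
#' Computes adaptation sensitivity (AS) and transition efficiency (TE) from
#' deterministic solves and noise attenuation (NA) from seeded stochastic
#' ensembles, for every combination of the supplied parameter values.
#'
#' The stochastic ensembles share one seed across grid points (common random
#' numbers), the standard variance-reduction design when the quantity of
#' interest is the comparison between grid points rather than any single
#' value. The noise-attenuation CV is measured over a response-scale horizon
#' `t_sde` covering induction, adaptation and settling.
#'
#' @param gamma,n_ics,alpha,beta vectors of parameter values (full factorial).
#' @param sigma noise amplitude for the stochastic ensemble.
#' @param n_paths ensemble size per grid point.
#' @param seed integer seed, reused at every grid point (common random
#'   numbers).
#' @param dt Euler-Maruyama step for the ensembles.
#' @param t_sde horizon of the stochastic solves used for noise attenuation.
#' @return A tibble with one row per grid point and columns
#'   `alpha, beta, gamma, n_ics, as, na, te`.
#' @export
sweep_population_metrics <- function(gamma = c(5, 20, 80), n_ics = 2,
                                     alpha = 8, beta = 0.01, sigma = 1,
                                     n_paths = 100, seed = 1L, dt = 0.01,
                                     t_sde = 20) {
  grid <- tidyr::expand_grid(alpha = alpha, beta = beta,
                             gamma = gamma, n_ics = n_ics)
  res <- purrr::pmap(grid, function(alpha, beta, gamma, n_ics) {
    out <- c(as = NA_real_, na = NA_real_, te = NA_real_)
    tryCatch({
      p <- pop_params(alpha = alpha, beta = beta, gamma = gamma,
                      n_ics = n_ics, sigma = sigma, dt = dt)
      det <- simulate_population(p)
      out["as"] <- adaptation_sensitivity(det)
      out["te"] <- transition_efficiency(det)
      p_sde <- pop_params(alpha = alpha, beta = beta, gamma = gamma,
                          n_ics = n_ics, sigma = sigma, dt = dt,
                          t_max = t_sde)
      sto <- simulate_population_sde(p_sde, seed = seed, n_paths = n_paths)
      out["na"] <- noise_attenuation(sto)
    }, error = function(e) {
      warning("grid point (gamma=", gamma, ", n_ics=", n_ics, ") failed: ",
              conditionMessage(e), call. = FALSE)
    })
    tibble::tibble(as = out[["as"]], na = out[["na"]], te = out[["te"]])
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' @export
print.pop_trajectory <- function(x, ...) {
  cat("<pop_trajectory> ", if (x$stochastic) "stochastic" else "deterministic",
      ", N = ", x$params$n_ics, " ICS, t in [0, ",
      signif(max(x$times), 4), "], ", length(x$times), " points\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population trajectory into a long tibble
#'
#' @param x a `pop_trajectory`.
#' @param ... unused.
#' @return Tibble with columns `time`, `state`, `fraction` (ensemble mean for
#'   stochastic trajectories).
#' @method tidy pop_trajectory
#' @export
tidy.pop_trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$states)) |>
    dplyr::mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "fraction") |>
    dplyr::mutate(state = factor(.data$state, levels = colnames(x$states)))
}

#' One-row summary of a population trajectory
#'
#' @param x a `pop_trajectory`.
#' @param ... unused.
#' @return Tibble with `n_ics`, `gamma`, and (deterministic case) `as`, `te`.
#' @method glance pop_trajectory
#' @export
glance.pop_trajectory <- function(x, ...) {
  out <- tibble::tibble(n_ics = x$params$n_ics, alpha = x$params$alpha,
                        beta = x$params$beta, gamma = x$params$gamma,
                        stochastic = x$stochastic)
  if (!x$stochastic) {
    out$as <- adaptation_sensitivity(x)
    out$te <- transition_efficiency(x)
  }
  out
}

#' Plot population fractions over time
#'
#' @param object a `pop_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pop_trajectory
#' @export
autoplot.pop_trajectory <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$fraction,
                                 colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (units of the direct E-M transition)",
                  y = "population fraction") +
    ggplot2::theme_minimal()
}
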