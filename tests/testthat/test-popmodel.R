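test_that("the two-state model matches its closed form", {
  p <- pop_params(alpha = 2, n_ics = 0)
  traj <- simulate_population(p)
  m_exact <- (1 / 3) * (1 - exp(-3 * traj$times))
  expect_lt(max(abs(traj$states[, "M"] - m_exact)), 1e-6)
  expect_equal(adaptation_sensitivity(traj), 0)
  expect_equal(transition_efficiency(traj), 1 / 3, tolerance = 1e-6)
  expect_equal(unname(traj$states[1, ]), c(1, 0))
})

test_that("deterministic solves conserve the total fraction", {
  set.seed(14)
  for (i in 1:10) {
    p <- pop_params(alpha = runif(1, 1.1, 20), beta = runif(1, 0, 0.3),
                    gamma = runif(1, 1, 80), n_ics = sample(0:6, 1))
    traj <- simulate_population(p)
    expect_lt(max(abs(rowSums(traj$states) - 1)), 1e-7)
    expect_gt(min(traj$states), -1e-9)
  }
})

test_that("the trajectory end agrees with the exact null-space steady state", {
  for (n in c(0, 1, 3)) {
    p <- pop_params(alpha = 5, beta = 0.05, gamma = 15, n_ics = n)
    traj <- simulate_population(p)
    ss <- pop_steady_state(p)
    expect_equal(unname(traj$states[nrow(traj$states), ]), unname(ss),
                 tolerance = 1e-6)
    expect_equal(sum(ss), 1, tolerance = 1e-12)
  }
})

test_that("solutions superpose linearly in the initial condition", {
  p <- pop_params(alpha = 4, beta = 0.02, gamma = 10, n_ics = 2, t_max = 5)
  A <- pop_rate_matrix(p)
  d <- nrow(A)
  prop <- function(y0) {
    deSolve::ode(y = y0, times = c(0, 2),
                 func = function(t, y, parms) list(as.vector(A %*% y)),
                 rtol = 1e-10, atol = 1e-12)[2, -1]
  }
  y1 <- c(1, rep(0, d - 1)); y2 <- c(rep(0, d - 1), 1)
  lhs <- prop(0.3 * y1 + 0.7 * y2)
  rhs <- 0.3 * prop(y1) + 0.7 * prop(y2)
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-8)
})

test_that("the stochastic solver reduces to the deterministic one without noise", {
  p <- pop_params(alpha = 8, gamma = 20, n_ics = 2, sigma = 0, t_max = 10)
  sto <- simulate_population_sde(p, seed = 1, n_paths = 1)
  det <- simulate_population(p)
  m_det <- stats::approx(det$times, det$states[, "M"], sto$times)$y
  expect_lt(max(abs(sto$m_paths[, 1] - m_det)), 0.03)  # Euler vs lsoda
  # away from the onset transient the Euler path tracks closely
  late <- sto$times >= 2
  expect_lt(max(abs(sto$m_paths[late, 1] - m_det[late])), 2e-3)
  # over the settled half the noise-free CV vanishes
  expect_equal(noise_attenuation(sto, window = 0.5), 0, tolerance = 1e-4)
})

test_that("stochastic paths are seed-reproducible and unbiased in the mean", {
  p <- pop_params(alpha = 8, gamma = 20, n_ics = 2, t_max = 10)
  a <- simulate_population_sde(p, seed = 5, n_paths = 3)
  b <- simulate_population_sde(p, seed = 5, n_paths = 3)
  expect_identical(a$m_paths, b$m_paths)
  # in the near-linear regime (mild noise, reflection rarely active) the
  # ensemble mean of the mesenchymal fraction is unbiased
  p_mild <- pop_params(alpha = 8, gamma = 20, n_ics = 2, sigma = 0.1,
                       t_max = 10)
  ens <- simulate_population_sde(p_mild, seed = 6, n_paths = 200)
  det <- simulate_population(p_mild)
  m_T <- ens$m_paths[nrow(ens$m_paths), ]
  se <- stats::sd(m_T) / sqrt(length(m_T))
  expect_lt(abs(mean(m_T) - det$states[nrow(det$states), "M"]),
            3 * se + 2e-3)
})

test_that("adaptation requires intermediate states and grows with their number", {
  as_of <- function(n) {
    adaptation_sensitivity(simulate_population(
      pop_params(alpha = 8, beta = 0.01, gamma = 80, n_ics = n)))
  }
  expect_equal(as_of(0), 0)
  expect_gt(as_of(2), as_of(1))
  # monotone-increasing M keeps AS at zero by construction
  p0 <- pop_params(alpha = 2, n_ics = 0)
  expect_equal(adaptation_sensitivity(simulate_population(p0)), 0)
})

test_that("many intermediate states produce oscillatory adaptation", {
  p <- pop_params(alpha = 8, beta = 0.01, gamma = 40, n_ics = 12)
  m <- simulate_population(p)$states[, "M"]
  dm <- diff(m)
  peaks <- sum(dm[-length(dm)] > 1e-9 & dm[-1] < -1e-9)
  expect_gte(peaks, 2)
})

test_that("an unsettled horizon is reported as an error", {
  p <- pop_params(alpha = 1.05, n_ics = 0, t_max = 0.5)
  traj <- simulate_population(p)
  expect_error(adaptation_sensitivity(traj), "settled")
})

test_that("a degenerate sweep grid gives a single coherent row", {
  sw <- sweep_population_metrics(gamma = 20, n_ics = 2, alpha = 8,
                                 beta = 0.01, n_paths = 20, seed = 1,
                                 t_sde = 10)
  expect_equal(nrow(sw), 1)
  expect_true(all(c("as", "na", "te") %in% names(sw)))
  expect_true(all(is.finite(c(sw$as, sw$na, sw$te))))
  expect_gte(sw$as, 0)
  expect_gt(sw$te, 0); expect_lt(sw$te, 1)
})
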