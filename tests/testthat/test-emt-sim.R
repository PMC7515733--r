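test_that("the default circuit has four stable states with the right readouts", {
  fx <- emt_fixture()
  att <- fx$att
  expect_equal(nrow(att$states), 4)
  expect_setequal(att$phenotype, c("E", "I1", "I2", "M"))
  ecad <- att$states[, "ECAD"]; vim <- att$states[, "VIM"]
  expect_equal(att$phenotype[which.max(ecad)], "E")
  expect_equal(att$phenotype[which.max(vim)], "M")
  i1 <- att$states[att$phenotype == "I1", ]
  i2 <- att$states[att$phenotype == "I2", ]
  expect_gt(i1["ECAD"] - i1["VIM"], i2["ECAD"] - i2["VIM"])
})

test_that("attractors are genuine fixed points of the deterministic flow", {
  fx <- emt_fixture()
  for (j in seq_len(nrow(fx$att$states))) {
    a <- fx$att$states[j, ]
    expect_lt(sqrt(sum(emt_rates(a, fx$net)^2)), 1e-6)
    # starting at an attractor stays there
    out <- integrate_cells(a, fx$net, dt = 0.5, sigma = 0, duration = 100)
    expect_lt(sqrt(sum((out - a)^2)), 1e-4)
  }
})

test_that("noise-free integration converges at first order in the step size", {
  fx <- emt_fixture()
  start <- fx$att$states[1, ] * 0.5 + fx$att$states[2, ] * 0.5
  ref <- deSolve::ode(y = start, times = c(0, 20),
                      func = function(t, y, p) list(emt_rates(y, fx$net)),
                      rtol = 1e-10, atol = 1e-12)[2, -1]
  err <- function(dt) {
    max(abs(integrate_cells(start, fx$net, dt = dt, sigma = 0,
                            duration = 20) - ref))
  }
  e1 <- err(0.4); e2 <- err(0.2)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("stochastic integration is reproducible under a fixed seed", {
  fx <- emt_fixture()
  start <- fx$att$states[2, ]
  set.seed(31)
  a <- integrate_cells(start, fx$net, dt = 0.1, sigma = 0.05, duration = 5)
  set.seed(31)
  b <- integrate_cells(start, fx$net, dt = 0.1, sigma = 0.05, duration = 5)
  expect_identical(a, b)
})

test_that("division perturbs daughters symmetrically around the mother", {
  state <- c(1:18) / 3
  set.seed(8)
  dg <- divide_cell(state, 0.7)
  # the +/- symmetry holds wherever the zero clamp is inactive
  free <- state + dg$noise >= 0 & state - dg$noise >= 0
  expect_true(any(free))
  expect_equal((dg$daughter1 + dg$daughter2)[free], (2 * state)[free],
               tolerance = 1e-12)
  # zero noise gives identical daughters
  dg0 <- divide_cell(state, 0)
  expect_identical(dg0$daughter1, dg0$daughter2)
  # perturbation scale: noise/state ratio has sd ~ 0.7
  set.seed(9)
  draws <- replicate(600, divide_cell(rep(1, 18), 0.7)$noise)
  expect_equal(stats::sd(draws), 0.7, tolerance = 0.03)
})

test_that("phenotype classification tightens monotonically with the radius", {
  fx <- emt_fixture()
  expect_equal(classify_phenotype(fx$att$states[3, ], fx$att),
               fx$att$phenotype[3])
  mid <- colMeans(fx$att$states[c(1, 4), ])
  expect_equal(classify_phenotype(mid, fx$att), "TC")
  expr <- fx$sim$snapshots[[1]]$expression
  tc_counts <- vapply(c(0.3, 0.2, 0.1, 0.05), function(r) {
    sum(classify_phenotype(expr, fx$att, radius_frac = r) == "TC")
  }, numeric(1))
  expect_true(all(diff(tc_counts) >= 0))
})

test_that("lineage links every cell to a recorded ancestor", {
  fx <- emt_fixture()
  lin <- fx$sim$lineage
  non_initial <- lin[!is.na(lin$parent_id), ]
  expect_true(all(non_initial$parent_id %in% lin$id))
  # parents are born before their daughters
  parent_birth <- lin$birth_time[match(non_initial$parent_id, lin$id)]
  expect_true(all(parent_birth < non_initial$birth_time))
  # budgets stay within the configured range
  expect_true(all(lin$final_budget >= 0 & lin$final_budget <= 7))
})

test_that("a zero-noise, zero-budget population is a fixed snapshot", {
  fx <- emt_fixture()
  cfg <- emt_sim_config(n_initial = c(E = 3, M = 3), budget_min = 0,
                        budget_max = 0, sde_sigma = 0, n_cycles = 1,
                        cycle_length = 50, dt = 0.5, seed = 2)
  sim <- run_emt_simulation(cfg, fx$net, fx$att)
  snap <- sim$snapshots[[1]]
  init <- t(fx$att$states[match(c("E", "E", "E", "M", "M", "M"),
                                fx$att$phenotype), ])
  expect_equal(unname(snap$expression), unname(init), tolerance = 1e-6)
})

test_that("the non-proliferative-I1 variant never divides I1 cells", {
  fx <- emt_fixture()
  cfg <- emt_sim_config(n_initial = c(E = 5, I1 = 10, I2 = 5, M = 5),
                        n_cycles = 1, dt = 0.5, seed = 3,
                        proliferate_i1 = FALSE)
  sim <- run_emt_simulation(cfg, fx$net, fx$att)
  expect_gt(nrow(sim$division_events), 0)
  expect_false(any(sim$division_events$mother_phenotype == "I1"))
})
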