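test_that("derivatives match a term-by-term arithmetic oracle", {
  # single self-seeding reef at (M, C) = (0.2, 0.3), F = 0.5:
  # dM = 0.1*0.2*0.3 - 0.3*0.2/0.7 + 0.8*1*0.5*0.2
  # dC = 1*1*0.5*0.3 - 0.1*0.2*0.3 - 0.05*0.3
  sys <- make_system(g = 0.3, d = 0.05, K = matrix(1, 1, 1))
  rates <- reef_derivatives(tibble::tibble(M = 0.2, C = 0.3), sys)
  expect_equal(rates$dM, 0.006 - 0.06 / 0.7 + 0.08, tolerance = 1e-12)
  expect_equal(rates$dC, 0.15 - 0.006 - 0.015, tolerance = 1e-12)
  expect_equal(rates$dF, -(rates$dM + rates$dC))
})

test_that("the bare state is absorbing and rates close the simplex", {
  sim <- random_system(4, seed = 2)
  zero <- tibble::tibble(M = rep(0, 4), C = rep(0, 4))
  rates <- reef_derivatives(zero, sim$system)
  expect_equal(rates$dM, rep(0, 4))
  expect_equal(rates$dC, rep(0, 4))

  # dM + dC + dF = 0 identically, on arbitrary valid states
  rates2 <- reef_derivatives(sim$init, sim$system)
  expect_equal(rates2$dM + rates2$dC + rates2$dF, rep(0, 4))
})

test_that("integration from the bare state stays at the fixed point", {
  sim <- random_system(3, seed = 5)
  init <- tibble::tibble(reef_id = 1:3, M = rep(0, 3), C = rep(0, 3))
  traj <- simulate_reefs(sim$system, init, t_end = 100, step_out = 10)
  expect_equal(max(abs(traj$M)), 0)
  expect_equal(max(abs(traj$C)), 0)
  expect_true(check_equilibrium(traj))
})

test_that("exchangeable reefs follow identical trajectories", {
  K <- matrix(0.2, 2, 2)
  sys <- make_system(g = c(0.3, 0.3), d = c(0.2, 0.2), K = K)
  init <- tibble::tibble(reef_id = 1:2, M = c(0.2, 0.2), C = c(0.3, 0.3))
  traj <- simulate_reefs(sys, init, t_end = 200, step_out = 10)
  expect_equal(traj$M[, 1], traj$M[, 2])
  expect_equal(traj$C[, 1], traj$C[, 2])
})

test_that("adaptive integration agrees with the fixed-step RK4 oracle", {
  for (seed in 1:5) {
    sim <- random_system(5, seed = seed)
    traj <- simulate_reefs(sim$system, sim$init, t_end = 50, step_out = 50)
    oracle <- rk4_final(sim$init$M, sim$init$C,
                        g = sim$system$g, d = sim$system$d,
                        a = sim$system$a, r = sim$system$r,
                        gamma = sim$system$gamma,
                        K = sim$system$K, N = sim$system$N,
                        t_end = 50, dt = 0.01)
    expect_lt(max(abs(traj$final$M - oracle$M),
                  abs(traj$final$C - oracle$C)), 1e-4)
  }
})

test_that("covers stay on the simplex along trajectories", {
  for (seed in c(3, 8)) {
    sim <- random_system(5, seed = seed)
    traj <- simulate_reefs(sim$system, sim$init, t_end = 2000, step_out = 10)
    long <- tidy(traj)
    expect_lt(max(abs(long$M + long$C + long$F - 1)), 1e-9)
    expect_true(all(long$M >= -1e-9 & long$M <= 1 + 1e-9))
    expect_true(all(long$C >= -1e-9 & long$C <= 1 + 1e-9))
  }
})

test_that("diagonal connectivity decouples reefs into single-reef runs", {
  withr::with_seed(10, {
    g <- runif(4, 0.1, 0.5)
    d <- runif(4, 0.2, 0.5)
    k_self <- runif(4, 0.5, 1)
    n_self <- runif(4, 0.5, 1)
    M0 <- runif(4, 0.05, 0.4)
    C0 <- runif(4, 0.05, 0.4)
  })
  sys <- make_system(g = g, d = d, K = diag(k_self), N = diag(n_self))
  init <- tibble::tibble(reef_id = 1:4, M = M0, C = C0)
  netw <- simulate_reefs(sys, init, t_end = 500, step_out = 100)
  for (i in 1:4) {
    solo <- make_system(g = g[i], d = d[i], K = matrix(k_self[i], 1, 1),
                        N = matrix(n_self[i], 1, 1))
    straj <- simulate_reefs(solo, tibble::tibble(reef_id = 1, M = M0[i],
                                                 C = C0[i]),
                            t_end = 500, step_out = 100)
    expect_lt(max(abs(netw$M[, i] - straj$M[, 1]),
                  abs(netw$C[, i] - straj$C[, 1])), 1e-8)
  }
})

test_that("equilibrium checking flags unfinished runs", {
  sys <- make_system(g = 0.3, d = 0.44, K = matrix(1, 1, 1))
  init <- tibble::tibble(reef_id = 1, M = 0.05, C = 0.75)
  short <- simulate_reefs(sys, init, t_end = 1, step_out = 1)
  expect_warning(res <- check_equilibrium(short), "not at equilibrium")
  expect_false(res)
  expect_true(check_equilibrium(short, tol = Inf))

  long <- simulate_reefs(sys, init, t_end = 20000, step_out = 1000)
  expect_true(check_equilibrium(long))
})

test_that("isolated-reef regimes behave at the analytic limits", {
  # grazing so strong macroalgae can never invade
  expect_equal(isolated_reef_regime(g = 5, d = 0.44), "coral")
  # no grazing, no mortality: macroalgae overgrow coral from either probe
  expect_equal(isolated_reef_regime(g = 0, d = 0), "macroalgal")
  expect_error(isolated_reef_regime(g = c(0.1, 0.2), d = 0.3),
               class = "reefstates_parameter_error")
})

test_that("calibrated defaults give the three regimes at the scenario medians", {
  expect_equal(isolated_reef_regime(0.1, 0.44), "macroalgal")
  expect_equal(isolated_reef_regime(0.3, 0.44), "bistable")
  expect_equal(isolated_reef_regime(0.5, 0.44), "coral")
})

test_that("invalid initial states and dimension mismatches are caught", {
  sys <- make_system(g = c(0.3, 0.3), d = c(0.2, 0.2), K = matrix(0.1, 2, 2))
  expect_error(
    simulate_reefs(sys, tibble::tibble(reef_id = 1, M = 0.1, C = 0.1)),
    class = "reefstates_structural_error")
  expect_error(
    simulate_reefs(sys, tibble::tibble(reef_id = 1:2, M = c(0.7, 0.1),
                                       C = c(0.6, 0.1)), t_end = 10),
    class = "reefstates_validation_error")
  expect_error(
    reef_derivatives(tibble::tibble(M = 0.1, C = 0.1), sys),
    class = "reefstates_structural_error")
})
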