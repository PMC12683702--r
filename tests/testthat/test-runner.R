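# Small seascapes and short horizons keep the factorial bookkeeping tests
# fast; the full-scale grid is exercised in the acceptance suite.

test_that("the factorial grid has the right bookkeeping shape", {
  world <- default_world(seed = 6, n_reefs = 16)
  grid <- run_grid(world$reefs, world$K, world$N, t_end = 500)
  # 3 scenarios x (1 baseline + 6 interventions) = 21 row-sets
  expect_equal(nrow(grid$results), 21 * 16)
  expect_equal(dim(as.matrix(tidyr::pivot_wider(
    grid$metrics, names_from = "scenario",
    values_from = "n_healthy")[-1])), c(6, 3))
  # every intervention row-set has a matching baseline and zero baseline deltas
  base <- dplyr::filter(grid$results, intervention == "baseline")
  expect_equal(nrow(base), 3 * 16)
  expect_true(all(base$delta_C == 0 & base$delta_M == 0))
})

test_that("an empty intervention list gives a baseline-only result", {
  world <- default_world(seed = 6, n_reefs = 10)
  grid <- run_grid(world$reefs, world$K, world$N,
                   interventions = list(), t_end = 200)
  expect_equal(unique(grid$results$intervention), "baseline")
  expect_equal(nrow(grid$metrics), 0)
})

test_that("rerunning a grid from the same seed is bitwise identical", {
  build <- function() {
    world <- default_world(seed = 8, n_reefs = 12)
    run_grid(world$reefs, world$K, world$N, t_end = 300)$results
  }
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(build(), f1, progress = FALSE)
  readr::write_csv(build(), f2, progress = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("water-quality sweeps cover edge percentages", {
  world <- default_world(seed = 3, n_reefs = 10)
  empty <- water_quality_sweep(world$reefs, world$K, world$N,
                               percents = numeric(0))
  expect_equal(nrow(empty), 0)

  # complete mortality removal must integrate without solver failure
  full <- water_quality_sweep(world$reefs, world$K, world$N,
                              percents = 100, scenarios = "medium",
                              t_end = 2000)
  expect_equal(nrow(full), 1)
  expect_true(all(is.finite(full$mean_final_C)))

  expect_error(water_quality_sweep(world$reefs, world$K, world$N,
                                   percents = c(50, 120)),
               class = "reefstates_parameter_error")
})

test_that("sensitivity grids enumerate the Cartesian product", {
  world <- default_world(seed = 2, n_reefs = 8)
  arms <- default_interventions()[c(1, 3)]
  sens <- sensitivity_grid(world$reefs, world$K, world$N, seed = 2,
                           a_values = c(0.05, 0.1),
                           d_med_values = c(0.3, 0.44),
                           pld_values = NA,
                           ic_scenarios = "empirical",
                           interventions = arms,
                           scenarios = c("low", "high"),
                           t_end = 200)
  expect_equal(nrow(sens$cells), 4)
  expect_true(all(sens$cells$evpi >= -1e-12))
  expect_gte(sens$pooled_evpi, -1e-12)
  # a repeated grid point yields identical sub-results
  rep2 <- sensitivity_grid(world$reefs, world$K, world$N, seed = 2,
                           a_values = c(0.1, 0.1), d_med_values = 0.44,
                           pld_values = NA, ic_scenarios = "empirical",
                           interventions = arms, scenarios = "low",
                           t_end = 200)
  expect_identical(rep2$cells$metrics[[1]], rep2$cells$metrics[[2]])
})

test_that("disconnected components evolve independently", {
  # two 2-reef blocks with no cross-block dispersal
  reefs <- make_reefs(lon = c(0, 0.01, 3, 3.01), lat = c(0, 0, 0, 0),
                      coral = c(0.3, 0.3, 0.3, 0.3),
                      macro = c(0.2, 0.2, 0.2, 0.2))
  block <- matrix(c(0.8, 0.3, 0.3, 0.8), 2)
  K <- rbind(cbind(block, matrix(0, 2, 2)),
             cbind(matrix(0, 2, 2), block))
  expect_equal(network_diagnostics(K)$n_weak_components, 2)
  g <- c(0.3, 0.35, 0.3, 0.35)
  d <- c(0.4, 0.4, 0.4, 0.4)
  sys <- make_system(g = g, d = d, K = K)
  init <- tibble::tibble(reef_id = 1:4, M = rep(0.2, 4), C = rep(0.3, 4))
  base <- simulate_reefs(sys, init, t_end = 2000, step_out = 500)
  # perturb only the first block's coral mortality
  sys_p <- sys
  sys_p$d <- c(0.2, 0.2, 0.4, 0.4)
  pert <- simulate_reefs(sys_p, init, t_end = 2000, step_out = 500)
  expect_lt(max(abs(base$C[, 3:4] - pert$C[, 3:4])), 1e-10)
  expect_gt(max(abs(base$C[, 1:2] - pert$C[, 1:2])), 1e-6)
})

test_that("network-wide coral does not drop as the grazing scenario rises", {
  ok <- 0
  for (seed in 1:10) {
    world <- default_world(seed = seed, n_reefs = 40)
    init <- generate_initial_conditions(world$reefs)
    tot <- vapply(c("low", "medium", "high"), function(sc) {
      sys <- build_system(world$reefs, world$K, world$N, scenario = sc)
      sum(simulate_reefs(sys, init, t_end = 20000,
                         step_out = 20000)$final$C)
    }, numeric(1))
    if (all(diff(tot) >= -1e-6)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
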