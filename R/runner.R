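#' Run the full intervention-by-scenario factorial
#'
#' For each grazing scenario the system is parameterised, a baseline run
#' is integrated, and every intervention is applied and integrated. Final
#' covers, per-reef deltas against the scenario's own baseline, and the
#' healthy-reef counts feeding the EVPI analysis are collected. The
#' computation is deterministic: all stochasticity lives upstream in the
#' seascape and connectivity generators.
#'
#' @param reefs A reef table.
#' @param K,N Coral and macroalgal connectivity matrices in reef order.
#' @param interventions Named list of [intervention()] specs (default
#'   [default_interventions()]). May be empty, giving a baseline-only
#'   result.
#' @param scenarios Character vector of grazing scenario names.
#' @param init_scenario Initial-condition scenario passed to
#'   [generate_initial_conditions()].
#' @param mortality A [mortality_config()].
#' @param a,r,gamma Global rates.
#' @param t_end Integration horizon.
#' @param step_out Output spacing handed to [simulate_reefs()]; final
#'   states do not depend on it.
#' @param threshold Healthy-reef coral-cover threshold.
#' @return An object of class `reef_grid`: `results` (long tibble with
#'   scenario, intervention, reef_id, final covers, equilibrium residual
#'   and percentage-point deltas; baseline rows carry zero deltas) and
#'   `metrics` (long tibble intervention x scenario x n_healthy,
#'   baseline excluded).
#' @export
run_grid <- function(reefs, K, N,
                     interventions = default_interventions(),
                     scenarios = c("low", "medium", "high"),
                     init_scenario = "empirical",
                     mortality = mortality_config(),
                     a = 0.1, r = 1, gamma = 0.8,
                     t_end = 20000, step_out = 100,
                     threshold = 0.30) {
  if (length(interventions) &&
        anyDuplicated(vapply(interventions, `[[`, character(1), "label"))) {
    abort("Intervention labels must be unique.",
          class = "reefstates_parameter_error")
  }
  init <- generate_initial_conditions(reefs, init_scenario)
  dist <- reef_distances(reefs)

  one_run <- function(system, label, scenario) {
    traj <- simulate_reefs(system, init, t_end = t_end, step_out = step_out)
    traj$final |>
      dplyr::mutate(scenario = scenario, intervention = label,
                    .before = 1)
  }

  results <- purrr::map(scenarios, function(sc) {
    system <- build_system(reefs, K, N, scenario = sc,
                           mortality = mortality, a = a, r = r,
                           gamma = gamma)
    base <- withCallingHandlers(
      one_run(system, "baseline", sc),
      error = function(e) {
        abort(paste0("Baseline run failed under scenario '", sc, "'."),
              parent = e)
      })
    arms <- purrr::imap(interventions, function(spec, label) {
      res <- apply_intervention(system, reefs, spec, dist)
      withCallingHandlers(
        one_run(res$system, label, sc),
        error = function(e) {
          abort(paste0("Intervention '", label, "' failed under scenario '",
                       sc, "'."), parent = e)
        })
    })
    dplyr::bind_rows(c(list(baseline = base), arms))
  }) |> dplyr::bind_rows()

  base_only <- results |>
    dplyr::filter(.data$intervention == "baseline") |>
    dplyr::select("scenario", "reef_id", base_C = "C", base_M = "M")
  results <- results |>
    dplyr::left_join(base_only, by = c("scenario", "reef_id")) |>
    dplyr::mutate(delta_C = 100 * (.data$C - .data$base_C),
                  delta_M = 100 * (.data$M - .data$base_M)) |>
    dplyr::select(-"base_C", -"base_M")

  metrics <- results |>
    dplyr::filter(.data$intervention != "baseline") |>
    dplyr::group_by(.data$intervention, .data$scenario) |>
    dplyr::summarise(n_healthy = healthy_count(.data$C, threshold),
                     .groups = "drop") |>
    dplyr::arrange(.data$intervention,
                   match(.data$scenario, scenarios))

  structure(list(results = results, metrics = metrics,
                 scenarios = scenarios,
                 interventions = names(interventions) %||% character(0),
                 threshold = threshold),
            class = "reef_grid")
}

#' @export
print.reef_grid <- function(x, ...) {
  cat("<reef_grid> ", length(x$scenarios), " scenarios x (baseline + ",
      length(x$interventions), " interventions)\n", sep = "")
  if (nrow(x$metrics)) {
    print(tidyr::pivot_wider(x$metrics, names_from = "scenario",
                             values_from = "n_healthy"))
  }
  invisible(x)
}

#' @describeIn run_grid The long results tibble.
#' @param x A `reef_grid`.
#' @param ... Unused.
#' @export
tidy.reef_grid <- function(x, ...) x$results

#' @describeIn run_grid Healthy-reef counts per intervention and scenario.
#' @export
glance.reef_grid <- function(x, ...) x$metrics

#' Water-quality improvement sweep
#'
#' Runs one water-quality intervention per percentage per scenario and
#' summarises the final coral cover, including the count of essentially
#' bare reefs (final coral below 1%), which tracks how much of the
#' network stays collapsed even under large mortality reductions.
#'
#' @inheritParams run_grid
#' @param percents Water-quality improvement percentages (default
#'   30–90 by 10).
#' @return A tibble with one row per scenario x percent: `mean_final_C`,
#'   `n_healthy`, `n_bare` (final C < 1%), plus a `results` list-column
#'   of per-reef finals.
#' @export
water_quality_sweep <- function(reefs, K, N,
                                percents = seq(30, 90, by = 10),
                                scenarios = c("low", "medium", "high"),
                                init_scenario = "empirical",
                                mortality = mortality_config(),
                                a = 0.1, r = 1, gamma = 0.8,
                                t_end = 20000, step_out = 100,
                                threshold = 0.30) {
  if (!length(percents)) {
    return(tibble(scenario = character(), wq_percent = numeric(),
                  mean_final_C = numeric(), n_healthy = integer(),
                  n_bare = integer(), results = list()))
  }
  if (any(percents <= 0 | percents > 100)) {
    abort("`percents` must lie in (0, 100].",
          class = "reefstates_parameter_error")
  }
  init <- generate_initial_conditions(reefs, init_scenario)
  grid <- tidyr::expand_grid(scenario = scenarios, wq_percent = percents)
  rows <- purrr::pmap(grid, function(scenario, wq_percent) {
    system <- build_system(reefs, K, N, scenario = scenario,
                           mortality = mortality, a = a, r = r,
                           gamma = gamma)
    res <- apply_intervention(system, reefs,
                              intervention("water_quality",
                                           wq_percent = wq_percent))
    traj <- simulate_reefs(res$system, init, t_end = t_end,
                           step_out = step_out)
    tibble(scenario = scenario, wq_percent = wq_percent,
           mean_final_C = mean(traj$final$C),
           n_healthy = healthy_count(traj$final$C, threshold),
           n_bare = sum(traj$final$C < 0.01),
           results = list(traj$final))
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity grid over model uncertainties
#'
#' Reruns the full intervention-by-scenario factorial over a Cartesian
#' grid of overgrowth rates, median mortalities, coral larval durations
#' (each duration regenerating the coral connectivity matrix), and
#' initial-condition scenarios. Each cell retains its metric table and
#' per-cell EVPI over the scenario axis, and a pooled EVPI treating every
#' (cell x scenario) combination as a distinct state of the world is also
#' reported.
#'
#' @inheritParams run_grid
#' @param seed Seed used to regenerate connectivity per larval duration.
#' @param a_values,d_med_values Grids of overgrowth and median mortality.
#' @param pld_values Coral larval durations; `NA` means the pooled
#'   weighted-average matrix `K`.
#' @param ic_scenarios Initial-condition scenario labels.
#' @param kernel Kernel used when regenerating coral connectivity.
#' @return A list of class `sensitivity_grid`: `cells` (one row per grid
#'   cell with a nested metric table and the cell EVPI) and
#'   `pooled_evpi` (EVPI over all cells x scenarios jointly).
#' @export
sensitivity_grid <- function(reefs, K, N, seed,
                             a_values = 0.1,
                             d_med_values = 0.44,
                             pld_values = NA,
                             ic_scenarios = "empirical",
                             interventions = default_interventions(),
                             scenarios = c("low", "medium", "high"),
                             mortality = mortality_config(),
                             kernel = kernel_config(),
                             r = 1, gamma = 0.8,
                             t_end = 20000, step_out = 100,
                             threshold = 0.30) {
  if (!length(a_values) || !length(d_med_values) || !length(pld_values) ||
        !length(ic_scenarios)) {
    abort("All sensitivity grids must be non-empty.",
          class = "reefstates_parameter_error")
  }
  grid <- tidyr::expand_grid(a = a_values, d_med = d_med_values,
                             pld = pld_values, ic = ic_scenarios)
  cells <- purrr::pmap(grid, function(a, d_med, pld, ic) {
    K_cell <- if (is.na(pld)) K else {
      generate_connectivity(reefs, pld, kernel, seed = as.integer(seed),
                            kind = "coral")
    }
    gr <- run_grid(reefs, K_cell, N, interventions = interventions,
                   scenarios = scenarios, init_scenario = ic,
                   mortality = mortality_config(d_med, mortality$spread),
                   a = a, r = r, gamma = gamma, t_end = t_end,
                   step_out = step_out, threshold = threshold)
    tibble(a = a, d_med = d_med, pld = pld, ic = ic,
           metrics = list(gr$metrics),
           evpi = compute_evpi(gr$metrics)$evpi)
  })
  cells <- dplyr::bind_rows(cells)
  pooled <- dplyr::bind_rows(purrr::imap(cells$metrics, function(m, i) {
    dplyr::mutate(m, scenario = paste0("cell", i, ":", .data$scenario))
  }))
  structure(list(cells = cells,
                 pooled_evpi = compute_evpi(pooled)$evpi),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("<sensitivity_grid> ", nrow(x$cells), " cells, per-cell EVPI range [",
      format(min(x$cells$evpi), digits = 3), ", ",
      format(max(x$cells$evpi), digits = 3), "], pooled EVPI ",
      format(x$pooled_evpi, digits = 3), "\n", sep = "")
  invisible(x)
}
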