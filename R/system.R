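#' Grazing scenarios
#'
#' The three named grazing scenarios bracket the uncertainty in true
#' herbivore grazing rates and correspond, for an isolated calibrated
#' reef, to the three dynamical regimes: macroalgal dominance (`low`,
#' median g = 0.1), bistability (`medium`, 0.3), and coral dominance
#' (`high`, 0.5).
#'
#' @param name `"low"`, `"medium"` or `"high"`.
#' @return A list of class `grazing_scenario` with `name` and `g_median`.
#' @export
grazing_scenario <- function(name = c("low", "medium", "high")) {
  name <- match.arg(name)
  medians <- c(low = 0.1, medium = 0.3, high = 0.5)
  structure(list(name = name, g_median = unname(medians[name])),
            class = "grazing_scenario")
}

#' Coral mortality configuration
#'
#' Controls how the sediment index maps onto per-reef coral mortality
#' rates: a rank-preserving linear rescale onto
#' `[d_med * (1 - spread), d_med * (1 + spread)]` with the median reef
#' mapped exactly to `d_med`.
#'
#' The default `d_med = 0.44` comes from the package's regime calibration
#' (see [calibrate_regimes()]): it is the mortality at which an isolated
#' reef with unit self-retention passes through macroalgal, bistable and
#' coral regimes at grazing medians 0.1 / 0.3 / 0.5.
#'
#' @param d_med Target median mortality rate (> 0).
#' @param spread Half-width factor of the rescaled range, in \[0, 1).
#' @return A list of class `mortality_config`.
#' @export
mortality_config <- function(d_med = 0.44, spread = 0.5) {
  if (!is.numeric(d_med) || d_med <= 0) {
    abort("`d_med` must be positive.", class = "reefstates_parameter_error")
  }
  if (!is.numeric(spread) || spread < 0 || spread >= 1) {
    abort("`spread` must lie in [0, 1).", class = "reefstates_parameter_error")
  }
  structure(list(d_med = d_med, spread = spread), class = "mortality_config")
}

#' Per-reef grazing rates from herbivore density
#'
#' Multiplies each reef's herbivore density by a common consumption-rate
#' constant chosen so that the median grazing rate equals the scenario
#' median. The map is multiplicative, so zero-density reefs stay at zero
#' and the ranking by density is preserved exactly.
#'
#' @param density Per-reef herbivore density (kg/ha, non-negative).
#' @param scenario A [grazing_scenario()] or its name.
#' @return Per-reef grazing rates with `median(g) == scenario$g_median`.
#' @examples
#' grazing_from_density(c(10, 20, 40), "medium")  # c(0.15, 0.30, 0.60)
#' @export
grazing_from_density <- function(density, scenario = "medium") {
  if (is.character(scenario)) scenario <- grazing_scenario(scenario)
  if (any(density < 0)) {
    abort("Densities must be non-negative.",
          class = "reefstates_parameter_error")
  }
  med <- median(density)
  if (med <= 0) {
    abort("Median herbivore density must be positive for multiplicative scaling.",
          class = "reefstates_parameter_error")
  }
  density * scenario$g_median / med
}

#' Per-reef coral mortality from a sediment index
#'
#' Rank-preserving linear rescale of the sediment index: the median reef
#' is mapped exactly to `d_med` and the most extreme deviation from the
#' median reaches the edge of `[d_med * (1 - spread), d_med * (1 + spread)]`.
#' A constant index maps every reef to `d_med`.
#'
#' @param sediment Per-reef sediment index (non-negative).
#' @param cfg A [mortality_config()].
#' @return Per-reef mortality rates with `median(d) == d_med`.
#' @examples
#' mortality_from_sediment(c(0, 5, 10), mortality_config(0.1, 0.5))
#' @export
mortality_from_sediment <- function(sediment, cfg = mortality_config()) {
  if (!inherits(cfg, "mortality_config")) {
    abort("`cfg` must be a mortality_config.",
          class = "reefstates_parameter_error")
  }
  if (any(sediment < 0)) {
    abort("Sediment index must be non-negative.",
          class = "reefstates_parameter_error")
  }
  med <- median(sediment)
  dev <- sediment - med
  max_dev <- max(abs(dev))
  if (max_dev == 0) {
    return(rep(cfg$d_med, length(sediment)))
  }
  cfg$d_med + dev * (cfg$d_med * cfg$spread / max_dev)
}

#' Assemble the full reef-network dynamical system
#'
#' Combines a reef table, the two connectivity matrices and the global
#' rates into the parameterised system of benthic-cover equations. Grazing
#' rates come from herbivore densities via [grazing_from_density()] under
#' the chosen scenario; coral mortality comes from the sediment index via
#' [mortality_from_sediment()].
#'
#' @param reefs A reef table.
#' @param K Coral larval connectivity matrix (order must match `reefs`).
#' @param N Macroalgal gamete connectivity matrix (same order).
#' @param scenario A [grazing_scenario()] or its name.
#' @param mortality A [mortality_config()].
#' @param a Macroalgal overgrowth rate over coral (global, default 0.1).
#' @param r Coral larval production rate (global, default 1).
#' @param gamma Macroalgal gamete production rate (global, default 0.8).
#' @return An object of class `reef_system`: per-reef `g` and `d`, the
#'   global rates, the matrices, and the scenario name.
#' @export
build_system <- function(reefs, K, N, scenario = "medium",
                         mortality = mortality_config(),
                         a = 0.1, r = 1, gamma = 0.8) {
  validate_reef_table(reefs)
  if (is.character(scenario)) scenario <- grazing_scenario(scenario)
  n <- nrow(reefs)
  for (nm in c("K", "N")) {
    m <- get(nm)
    if (nrow(m) != n || ncol(m) != n) {
      abort(paste0("`", nm, "` must be ", n, " x ", n, " to match `reefs`."),
            class = "reefstates_structural_error")
    }
    ids <- rownames(m)
    if (!is.null(ids) && !identical(as.character(reefs$reef_id), ids)) {
      abort(paste0("`", nm, "` row order does not match `reefs` ",
                   "(no silent reordering is done)."),
            class = "reefstates_structural_error")
    }
  }
  if (a < 0 || r < 0 || gamma < 0) {
    abort("Global rates must be non-negative.",
          class = "reefstates_parameter_error")
  }
  structure(list(
    reef_id = reefs$reef_id,
    g = grazing_from_density(reefs$herbivore_density, scenario),
    d = mortality_from_sediment(reefs$sediment_index, mortality),
    a = a, r = r, gamma = gamma,
    K = unclass(K), N = unclass(N),
    scenario = scenario$name
  ), class = "reef_system")
}

#' @export
print.reef_system <- function(x, ...) {
  cat("<reef_system> ", length(x$reef_id), " reefs, scenario '", x$scenario,
      "'\n", sep = "")
  cat(sprintf("  median g = %.4g, median d = %.4g, a = %g, r = %g, gamma = %g\n",
              median(x$g), median(x$d), x$a, x$r, x$gamma))
  invisible(x)
}

#' @describeIn build_system Per-reef parameters as a tibble
#'   (`reef_id`, `g`, `d`).
#' @param x A `reef_system`.
#' @param ... Unused.
#' @export
tidy.reef_system <- function(x, ...) {
  tibble(reef_id = x$reef_id, g = x$g, d = x$d)
}

#' @describeIn build_system One-row summary of the system's global
#'   structure.
#' @export
glance.reef_system <- function(x, ...) {
  tibble(n_reefs = length(x$reef_id), scenario = x$scenario,
         g_median = median(x$g), d_median = median(x$d),
         a = x$a, r = x$r, gamma = x$gamma)
}
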