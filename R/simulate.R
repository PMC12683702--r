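#' Benthic-cover rates of change
#'
#' Evaluates the right-hand side of the coupled cover equations for every
#' reef. With `F = 1 - M - C` (free space):
#'
#' \deqn{dM_i/dt = a M_i C_i - g_i M_i / (M_i + F_i) +
#'   \sum_j \gamma n_{ij} F_i M_j}
#' \deqn{dC_i/dt = \sum_j r k_{ij} F_i C_j - a M_i C_i - d_i C_i}
#'
#' Macroalgae grow by overgrowing coral, lose cover to indiscriminate
#' grazing spread over macroalgae plus free space, and gain recruits as
#' gametes from every reef settle on local free space. Coral gains
#' recruits from the larval pool and loses cover to overgrowth and
#' mortality. Free space follows by closure, `dF = -dM - dC`, and is never
#' integrated separately, so covers sum to one by construction.
#'
#' The grazing ratio has a removable singularity where `M + F` vanishes
#' (a reef wall-to-wall coral); the denominator is floored at `1e-12`, and
#' states are clipped onto the unit simplex before evaluation so that
#' solver round-off outside the simplex cannot feed back into the rates.
#'
#' @param state A tibble with columns `M` and `C` (and optionally
#'   `reef_id`), one row per reef, in system order.
#' @param system A [build_system()] result.
#' @return A tibble `reef_id`, `dM`, `dC`, `dF`.
#' @export
reef_derivatives <- function(state, system) {
  n <- length(system$reef_id)
  if (nrow(state) != n) {
    abort("`state` must have one row per reef in the system.",
          class = "reefstates_structural_error")
  }
  rates <- rhs_core(state$M, state$C, system)
  tibble(reef_id = system$reef_id, dM = rates$dM, dC = rates$dC,
         dF = -rates$dM - rates$dC)
}

# core vector field; M, C numeric vectors
rhs_core <- function(M, C, p) {
  M <- pmin(pmax(M, 0), 1)
  C <- pmin(pmax(C, 0), 1)
  F <- pmax(1 - M - C, 0)
  graz <- p$g * M / pmax(M + F, 1e-12)
  dM <- p$a * M * C - graz + p$gamma * F * drop(p$N %*% M)
  dC <- p$r * F * drop(p$K %*% C) - p$a * M * C - p$d * C
  list(dM = dM, dC = dC)
}

#' Integrate the reef network forward in time
#'
#' Adaptive-step continuous integration (lsoda) of the cover equations
#' from `t = 0` to `t_end`, recording states at `step_out`-spaced output
#' times. Only macroalgae and coral are integrated; free space is derived
#' algebraically, which guarantees exact cover conservation. Stored states
#' have solver round-off just outside \[0, 1\] (within 1e-8 of either
#' bound) clipped back to the boundary.
#'
#' @param system A [build_system()] result.
#' @param init Initial state tibble (`reef_id`, `M`, `C`), e.g. from
#'   [generate_initial_conditions()].
#' @param t_end Final time (default 20000, ample for the covers to
#'   stabilise).
#' @param step_out Spacing of stored output times (default 1).
#' @param rtol,atol Solver tolerances.
#' @param maxsteps Maximum internal solver steps per output interval.
#' @return An object of class `reef_trajectory`: output `times`, state
#'   matrices `M` and `C` (time x reef), the `final` state tibble and the
#'   `equilibrium_residual` (max absolute derivative at `t_end`).
#' @export
simulate_reefs <- function(system, init, t_end = 20000, step_out = 1,
                           rtol = 1e-8, atol = 1e-10, maxsteps = 1e5) {
  if (t_end <= 0) {
    abort("`t_end` must be positive.", class = "reefstates_parameter_error")
  }
  n <- length(system$reef_id)
  if (nrow(init) != n) {
    abort("`init` must have one row per reef in the system.",
          class = "reefstates_structural_error")
  }
  if (any(init$M < -1e-12 | init$C < -1e-12 | init$M + init$C > 1 + 1e-12)) {
    abort("Initial covers must satisfy 0 <= M, C and M + C <= 1.",
          class = "reefstates_validation_error")
  }
  times <- unique(c(seq(0, t_end, by = step_out), t_end))
  y0 <- c(init$M, init$C)
  rhs <- function(t, y, p) {
    rates <- rhs_core(y[1:n], y[(n + 1):(2 * n)], p)
    list(c(rates$dM, rates$dC))
  }
  out <- suppressWarnings(
    deSolve::ode(y0, times, rhs, system, rtol = rtol, atol = atol,
                 maxsteps = maxsteps)
  )
  flag <- attr(out, "istate")[1]
  if (flag < 0 || nrow(out) < length(times)) {
    abort(sprintf("Integration failed at t = %.6g (solver flag %d).",
                  out[nrow(out), 1], flag),
          class = "reefstates_integration_error")
  }
  M <- out[, 1 + (1:n), drop = FALSE]
  C <- out[, 1 + n + (1:n), drop = FALSE]
  # clip solver round-off just outside [0, 1]; worse excursions are left
  # visible so genuine solver trouble is not masked
  M[M < 0 & M > -1e-8] <- 0
  C[C < 0 & C > -1e-8] <- 0
  M[M > 1 & M < 1 + 1e-8] <- 1
  C[C > 1 & C < 1 + 1e-8] <- 1
  colnames(M) <- colnames(C) <- system$reef_id
  M_end <- unname(M[nrow(M), ])
  C_end <- unname(C[nrow(C), ])
  fin <- rhs_core(M_end, C_end, system)
  residual <- max(abs(c(fin$dM, fin$dC)))
  final <- tibble(
    reef_id = system$reef_id,
    M = M_end,
    C = C_end,
    F = 1 - M_end - C_end,
    equilibrium_residual = residual
  )
  structure(list(times = out[, 1], M = M, C = C, final = final,
                 equilibrium_residual = residual,
                 scenario = system$scenario),
            class = "reef_trajectory")
}

#' @export
print.reef_trajectory <- function(x, ...) {
  cat("<reef_trajectory> ", ncol(x$M), " reefs, t in [0, ",
      max(x$times), "], residual ", format(x$equilibrium_residual,
      digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_reefs Long tibble of the trajectory:
#'   `time`, `reef_id`, `M`, `C`, `F`.
#' @param x A `reef_trajectory`.
#' @param ... Unused.
#' @export
tidy.reef_trajectory <- function(x, ...) {
  n <- ncol(x$M)
  tibble(
    time = rep(x$times, times = n),
    reef_id = rep(as.integer(colnames(x$M)), each = length(x$times)),
    M = as.vector(x$M),
    C = as.vector(x$C)
  ) |>
    dplyr::mutate(F = 1 - .data$M - .data$C)
}

#' @describeIn simulate_reefs One-row summary: number of reefs, final
#'   time, equilibrium residual, mean final covers.
#' @export
glance.reef_trajectory <- function(x, ...) {
  tibble(n_reefs = ncol(x$M), t_end = max(x$times),
         equilibrium_residual = x$equilibrium_residual,
         mean_final_C = mean(x$final$C), mean_final_M = mean(x$final$M))
}

#' Has a trajectory reached equilibrium?
#'
#' Compares the maximum absolute derivative at the final stored state with
#' a tolerance and warns when the run has not settled.
#'
#' @param traj A [simulate_reefs()] result.
#' @param tol Residual tolerance (default 1e-8).
#' @return `TRUE` iff the residual is below `tol`.
#' @export
check_equilibrium <- function(traj, tol = 1e-8) {
  ok <- traj$equilibrium_residual < tol
  if (!ok) {
    warn(sprintf("Trajectory not at equilibrium: residual %.3g >= tol %.3g.",
                 traj$equilibrium_residual, tol))
  }
  ok
}

#' Dynamical regime of an isolated reef
#'
#' Integrates a single self-seeding reef from two probe initial states
#' (coral-heavy: C = 0.75, M = 0.05; macroalgae-heavy: the reverse) and
#' labels the long-run outcome: `"coral"` if both probes end coral-
#' dominated, `"macroalgal"` if both end macroalgae-dominated,
#' `"bistable"` if the probes diverge, and `"degenerate"` when a final
#' state has |C - M| < 1e-6.
#'
#' @param g,d Grazing and mortality rates (scalars).
#' @param a,r,gamma Global rates.
#' @param k_self,n_self Self-retention entries of the 1x1 connectivity
#'   matrices (default 1, the calibration convention).
#' @param t_end Integration horizon.
#' @return One of `"coral"`, `"macroalgal"`, `"bistable"`, `"degenerate"`.
#' @examples
#' isolated_reef_regime(g = 0.5, d = 0.44)  # "coral"
#' @export
isolated_reef_regime <- function(g, d, a = 0.1, r = 1, gamma = 0.8,
                                 k_self = 1, n_self = 1, t_end = 20000) {
  if (length(g) != 1 || length(d) != 1) {
    abort("`g` and `d` must be scalars.", class = "reefstates_parameter_error")
  }
  sys <- structure(list(reef_id = 1L, g = g, d = d, a = a, r = r,
                        gamma = gamma, K = matrix(k_self, 1, 1),
                        N = matrix(n_self, 1, 1), scenario = "probe"),
                   class = "reef_system")
  probe <- function(M0, C0) {
    traj <- simulate_reefs(sys, tibble(reef_id = 1L, M = M0, C = C0),
                           t_end = t_end, step_out = t_end)
    traj$final
  }
  hi <- probe(0.05, 0.75)
  lo <- probe(0.75, 0.05)
  lab <- function(s) {
    if (abs(s$C - s$M) < 1e-6) "degenerate"
    else if (s$C > s$M) "coral" else "macroalgal"
  }
  lhi <- lab(hi); llo <- lab(lo)
  if (lhi == "degenerate" || llo == "degenerate") return("degenerate")
  if (lhi == llo) lhi else "bistable"
}

#' Calibrate the default mortality against the regime structure
#'
#' Grid search over candidate median mortality rates: for each `d`, the
#' isolated-reef regime (unit self-retention) is evaluated at the three
#' scenario grazing medians. A `d` is admissible when the regimes are
#' macroalgal at g = 0.1, bistable at g = 0.3 and coral at g = 0.5 — the
#' structure the scenario medians are meant to represent. The package
#' default `d_med = 0.44` sits in the admissible band.
#'
#' @param d_values Candidate mortality rates.
#' @param g_values Scenario grazing medians (default 0.1, 0.3, 0.5).
#' @param ... Passed to [isolated_reef_regime()].
#' @return A tibble with one row per `d`: the three regime labels and
#'   whether the row is `admissible`.
#' @export
calibrate_regimes <- function(d_values = seq(0.3, 0.6, by = 0.02),
                              g_values = c(0.1, 0.3, 0.5), ...) {
  res <- purrr::map(d_values, function(d) {
    regs <- vapply(g_values, function(g) isolated_reef_regime(g, d, ...),
                   character(1))
    tibble(d = d, regime_low = regs[1], regime_medium = regs[2],
           regime_high = regs[3],
           admissible = identical(unname(regs),
                                  c("macroalgal", "bistable", "coral")))
  })
  dplyr::bind_rows(res)
}
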