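#' Count healthy reefs
#'
#' A reef is "healthy" when its final coral cover is strictly greater
#' than the threshold (default 30%, the cover generally taken to sustain
#' reef biodiversity and fisheries). Values within 1e-9 of the threshold
#' are not counted.
#'
#' @param final_C Per-reef final coral covers, proportions in \[0, 1\].
#' @param threshold Proportion threshold (default 0.30).
#' @return Integer count.
#' @examples
#' healthy_count(c(0.31, 0.30, 0.29))  # 1
#' @export
healthy_count <- function(final_C, threshold = 0.30) {
  if (any(final_C < -1e-9 | final_C > 1 + 1e-9)) {
    abort("Coral covers must lie in [0, 1].",
          class = "reefstates_validation_error")
  }
  sum(final_C > threshold + 1e-9)
}

#' Per-reef change relative to the baseline run
#'
#' Differences in final coral and macroalgal cover between an
#' intervention run and the baseline run under the same grazing scenario,
#' reported in percentage points (intervention minus baseline).
#'
#' @param final Final-state tibble (`reef_id`, `M`, `C`) under the
#'   intervention.
#' @param baseline Final-state tibble under the baseline, same reefs and
#'   scenario.
#' @return A tibble `reef_id`, `delta_C`, `delta_M` (percentage points).
#' @export
delta_vs_baseline <- function(final, baseline) {
  if (!setequal(final$reef_id, baseline$reef_id)) {
    abort("Reef sets differ between intervention and baseline.",
          class = "reefstates_structural_error")
  }
  base <- baseline[match(final$reef_id, baseline$reef_id), ]
  tibble(
    reef_id = final$reef_id,
    delta_C = 100 * (final$C - base$C),
    delta_M = 100 * (final$M - base$M)
  )
}

#' Net larval migration implied by a connectivity matrix
#'
#' For each reef, total immigration minus total emigration, excluding
#' self-retention (which cancels). Positive values mark net larval sinks,
#' negative values net sources; the column sums to zero over the network.
#'
#' @param K A square connectivity matrix.
#' @return A tibble `reef_id`, `net_migration`.
#' @export
net_migration <- function(K) {
  if (nrow(K) != ncol(K)) {
    abort("`K` must be square.", class = "reefstates_structural_error")
  }
  m <- unclass(K)
  diag(m) <- 0
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble(reef_id = as.integer(ids),
         net_migration = rowSums(m) - colSums(m))
}

as_metric_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else {
    needed <- c("intervention", "scenario", "n_healthy")
    if (!all(needed %in% names(table))) {
      abort("Metric table must have columns intervention, scenario, n_healthy.",
            class = "reefstates_structural_error")
    }
    wide <- tidyr::pivot_wider(table[needed], names_from = "scenario",
                               values_from = "n_healthy")
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$intervention
  }
  if (!length(m)) {
    abort("Metric table is empty.", class = "reefstates_structural_error")
  }
  if (anyNA(m)) {
    abort("Metric table has missing cells.",
          class = "reefstates_structural_error")
  }
  m
}

#' Expected value of perfect information over scenarios
#'
#' Given a metric table of healthy-reef counts (interventions x grazing
#' scenarios), computes the "average of the best" (mean over scenarios of
#' the per-scenario maximum — the expected payoff if the true scenario
#' were known before choosing) minus the "best of the averages" (the
#' payoff of the single intervention with the highest scenario-averaged
#' metric). The difference is the expected value of perfect information:
#' zero means one intervention is best regardless of scenario, so
#' resolving the uncertainty would not change the decision.
#'
#' @param table Either a long tibble with columns `intervention`,
#'   `scenario`, `n_healthy`, or a numeric matrix with interventions as
#'   rows and scenarios as columns.
#' @return An object of class `evpi_result` with fields
#'   `average_of_best`, `best_of_averages`, `evpi`, the per-scenario
#'   maxima, per-intervention means, and the metric matrix.
#' @examples
#' m <- matrix(c(3, 0, 0, 3), 2, 2)
#' compute_evpi(m)$evpi  # 1.5
#' @export
compute_evpi <- function(table) {
  m <- as_metric_matrix(table)
  per_scenario_max <- apply(m, 2, max)
  per_intervention_mean <- rowMeans(m)
  average_of_best <- mean(per_scenario_max)
  best_of_averages <- max(per_intervention_mean)
  structure(list(
    average_of_best = average_of_best,
    best_of_averages = best_of_averages,
    evpi = average_of_best - best_of_averages,
    per_scenario_max = per_scenario_max,
    per_intervention_mean = per_intervention_mean,
    table = m
  ), class = "evpi_result")
}

#' @export
print.evpi_result <- function(x, digits = 4, ...) {
  m <- x$table
  disp <- cbind(m, `avg across scenarios` = round(x$per_intervention_mean,
                                                  digits))
  disp <- rbind(disp, `avg across interventions` =
                  c(round(colMeans(m), digits), NA))
  cat("Healthy-reef counts by intervention and grazing scenario\n")
  print(disp, na.print = "")
  cat(sprintf("\naverage of the best:  %.*f\n", digits, x$average_of_best))
  cat(sprintf("best of the averages: %.*f\n", digits, x$best_of_averages))
  cat(sprintf("EVPI:                 %.*f\n", digits, x$evpi))
  invisible(x)
}

#' @describeIn compute_evpi Per-intervention scenario means as a tibble.
#' @param x An `evpi_result`.
#' @param ... Unused.
#' @export
tidy.evpi_result <- function(x, ...) {
  tibble(intervention = rownames(x$table) %||%
           as.character(seq_len(nrow(x$table))),
         mean_n_healthy = unname(x$per_intervention_mean))
}

#' @describeIn compute_evpi One-row summary with the EVPI decomposition.
#' @export
glance.evpi_result <- function(x, ...) {
  tibble(average_of_best = x$average_of_best,
         best_of_averages = x$best_of_averages,
         evpi = x$evpi)
}
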