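#' Declare a management intervention
#'
#' Three intervention families are supported. `expand_closures` grows
#' every periodic fishery closure to a radius, assigning each newly
#' included reef the grazing rate of the closure's original reef (the
#' mean, when several closures capture one reef). `water_quality` lowers
#' coral mortality by `wq_percent` percent, either on all reefs or only
#' on the scattered set of reefs a 2-km closure expansion would newly
#' include. `combined` applies both; order is irrelevant since the two
#' touch disjoint parameters (grazing vs mortality).
#'
#' @param type `"expand_closures"`, `"water_quality"` or `"combined"`.
#' @param radius_km Expansion radius in km (2 or 5 are the conventional
#'   magnitudes). Required for `expand_closures` and `combined`, and for
#'   the scattered water-quality scope.
#' @param same_ground_only Restrict expansion to reefs in the same fishing
#'   ground as the closure's original reef. Defaults to `TRUE` for a 2-km
#'   radius and `FALSE` otherwise, matching the convention that only the
#'   small expansion respects customary fishing-ground boundaries.
#' @param wq_percent Percent reduction of coral mortality, in (0, 100\].
#' @param wq_scope `"all"` (every reef) or `"scattered"` (only reefs newly
#'   included under a 2-km same-ground closure expansion).
#' @param label Optional display label.
#' @return A list of class `intervention_spec`.
#' @examples
#' intervention("combined", radius_km = 2, wq_percent = 25)
#' @export
intervention <- function(type = c("expand_closures", "water_quality",
                                  "combined"),
                         radius_km = NULL, same_ground_only = NULL,
                         wq_percent = NULL,
                         wq_scope = c("all", "scattered"),
                         label = NULL) {
  type <- match.arg(type)
  wq_scope <- match.arg(wq_scope)
  needs_radius <- type %in% c("expand_closures", "combined") ||
    (type == "water_quality" && wq_scope == "scattered")
  if (needs_radius) {
    if (is.null(radius_km)) {
      abort(paste0("`radius_km` is required for type '", type, "'",
                   if (wq_scope == "scattered") " with scattered scope"),
            class = "reefstates_parameter_error")
    }
    if (radius_km < 0) {
      abort("`radius_km` must be non-negative.",
            class = "reefstates_parameter_error")
    }
  }
  if (type %in% c("water_quality", "combined")) {
    if (is.null(wq_percent) || wq_percent <= 0 || wq_percent > 100) {
      abort("`wq_percent` must lie in (0, 100].",
            class = "reefstates_parameter_error")
    }
  }
  if (is.null(same_ground_only) && !is.null(radius_km)) {
    same_ground_only <- radius_km <= 2
  }
  if (is.null(label)) {
    label <- switch(type,
      expand_closures = sprintf("M1-%gkm", radius_km),
      water_quality = sprintf("M2-%g%%%s", wq_percent,
                              if (wq_scope == "scattered") " scat" else ""),
      combined = sprintf("M3-%gkm+%g%%", radius_km, wq_percent))
  }
  structure(list(type = type, radius_km = radius_km,
                 same_ground_only = same_ground_only,
                 wq_percent = wq_percent, wq_scope = wq_scope,
                 label = label),
            class = "intervention_spec")
}

#' The six conventional intervention arms
#'
#' Closure expansion at 2 km (same fishing ground only) and 5 km (across
#' grounds), water-quality improvement of 10% and 25%, and the two
#' combinations of the 2-km expansion with each water-quality magnitude.
#'
#' @return A named list of [intervention()] specs.
#' @export
default_interventions <- function() {
  specs <- list(
    intervention("expand_closures", radius_km = 2, same_ground_only = TRUE),
    intervention("expand_closures", radius_km = 5, same_ground_only = FALSE),
    intervention("water_quality", wq_percent = 10),
    intervention("water_quality", wq_percent = 25),
    intervention("combined", radius_km = 2, wq_percent = 10),
    intervention("combined", radius_km = 2, wq_percent = 25)
  )
  setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Expand fishery closures outward
#'
#' A reef is newly included in closure c when it lies within `radius_km`
#' (haversine) of any reef originally in c and, if `same_ground_only`,
#' shares that reef's fishing ground. Each captured reef — including an
#' original closure reef captured by another closure — takes the mean of
#' the original grazing rates of all closures capturing it (a reef's own
#' closure counts among its captors). Reefs captured by exactly one
#' closure therefore simply inherit that closure's original rate.
#'
#' @param reefs A reef table with at least one `closure_id`.
#' @param g Per-reef grazing rates in reef-table order.
#' @param dist Pairwise distance matrix in km (defaults to
#'   [reef_distances()]).
#' @param radius_km Expansion radius (boundary ties included).
#' @param same_ground_only Restrict capture to the closure reef's ground.
#' @return A list: modified `g`, `newly_included` reef ids,
#'   `g_changed_up` / `g_changed_down` reef-id sets.
#' @export
expand_closures <- function(reefs, g, dist = reef_distances(reefs),
                            radius_km, same_ground_only = TRUE) {
  if (all(is.na(reefs$closure_id))) {
    abort("No reef has a closure_id; nothing to expand.",
          class = "reefstates_structural_error")
  }
  if (radius_km < 0) {
    abort("`radius_km` must be non-negative.",
          class = "reefstates_parameter_error")
  }
  n <- nrow(reefs)
  closures <- unique(reefs$closure_id[!is.na(reefs$closure_id)])
  orig_members <- lapply(closures, function(cid) {
    which(!is.na(reefs$closure_id) & reefs$closure_id == cid)
  })
  orig_g <- vapply(orig_members, function(idx) mean(g[idx]), numeric(1))
  in_any_closure <- !is.na(reefs$closure_id)

  # captors[[i]]: closures whose original reefs reach reef i
  captured_g <- g
  newly_included <- integer(0)
  for (i in seq_len(n)) {
    captures <- vapply(seq_along(closures), function(ci) {
      idx <- orig_members[[ci]]
      ok <- dist[i, idx] <= radius_km
      if (same_ground_only) {
        ok <- ok & (reefs$fishing_ground[idx] == reefs$fishing_ground[i])
      }
      any(ok)
    }, logical(1))
    if (in_any_closure[i]) {
      # an original closure reef always keeps membership of its own closure
      captures <- captures | (closures == reefs$closure_id[i])
      if (sum(captures) > 1) captured_g[i] <- mean(orig_g[captures])
    } else if (any(captures)) {
      captured_g[i] <- mean(orig_g[captures])
      newly_included <- c(newly_included, i)
    }
  }
  list(
    g = captured_g,
    newly_included = reefs$reef_id[newly_included],
    g_changed_up = reefs$reef_id[captured_g > g],
    g_changed_down = reefs$reef_id[captured_g < g]
  )
}

#' Reduce coral mortality to emulate better water quality
#'
#' Multiplies mortality by `1 - wq_percent/100` on the selected reefs.
#'
#' @param d Per-reef mortality rates.
#' @param wq_percent Percent improvement in (0, 100].
#' @param subset Positions (indices) of reefs to modify; `NULL` means all.
#' @return Modified mortality vector; never larger than the input.
#' @export
improve_water_quality <- function(d, wq_percent, subset = NULL) {
  if (wq_percent <= 0 || wq_percent > 100) {
    abort("`wq_percent` must lie in (0, 100].",
          class = "reefstates_parameter_error")
  }
  idx <- subset %||% seq_along(d)
  d[idx] <- d[idx] * (1 - wq_percent / 100)
  d
}

#' Apply an intervention to a parameterised system
#'
#' Dispatches an [intervention()] spec: closure expansion modifies only
#' grazing rates, water quality only mortality rates, and the combination
#' applies both (the order is irrelevant because the touched parameters
#' are disjoint). The scattered water-quality scope first resolves which
#' reefs a 2-km same-ground closure expansion would newly include, then
#' lowers mortality on exactly that set.
#'
#' @param system A [build_system()] result.
#' @param reefs The reef table the system was built from.
#' @param spec An [intervention()].
#' @param dist Optional precomputed distance matrix (km).
#' @return A list of class `intervention_result`: the modified `system`,
#'   the `spec`, and the `newly_included`, `g_changed_up`,
#'   `g_changed_down` reef-id sets.
#' @export
apply_intervention <- function(system, reefs, spec,
                               dist = reef_distances(reefs)) {
  if (!inherits(spec, "intervention_spec")) {
    abort("`spec` must be an intervention_spec.",
          class = "reefstates_parameter_error")
  }
  out <- system
  newly_included <- integer(0)
  g_up <- integer(0)
  g_down <- integer(0)

  if (spec$type %in% c("expand_closures", "combined")) {
    exp_res <- expand_closures(reefs, system$g, dist, spec$radius_km,
                               spec$same_ground_only)
    out$g <- exp_res$g
    newly_included <- exp_res$newly_included
    g_up <- exp_res$g_changed_up
    g_down <- exp_res$g_changed_down
  }
  if (spec$type %in% c("water_quality", "combined")) {
    subset <- NULL
    if (spec$type == "water_quality" && spec$wq_scope == "scattered") {
      scatter <- expand_closures(reefs, system$g, dist,
                                 spec$radius_km %||% 2,
                                 spec$same_ground_only %||% TRUE)
      subset <- match(scatter$newly_included, reefs$reef_id)
      newly_included <- scatter$newly_included
    }
    out$d <- improve_water_quality(system$d, spec$wq_percent, subset)
  }
  structure(list(system = out, spec = spec,
                 newly_included = newly_included,
                 g_changed_up = g_up, g_changed_down = g_down),
            class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("<intervention_result> ", x$spec$label, ": ",
      length(x$newly_included), " newly included, g up/down ",
      length(x$g_changed_up), "/", length(x$g_changed_down), "\n", sep = "")
  invisible(x)
}
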