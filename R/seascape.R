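#' Generate a synthetic reef seascape
#'
#' Builds a table of reefs with the statistical structure the network model
#' assumes: reefs clustered around the centroids of customary fishing
#' grounds, a subset of reefs sitting inside periodic fishery closures,
#' right-skewed herbivore densities, a sediment index that decays with
#' distance from a simulated coastline (the southern edge of the bounding
#' box), and initial coral/macroalgal covers that never overfill a reef.
#'
#' Each closed reef receives its own closure id: a periodic fishery closure
#' is modelled as a small no-take area centred on a single surveyed reef,
#' which is the unit the closure-expansion intervention grows outward from.
#'
#' @param n_reefs Number of reefs (default 75).
#' @param n_grounds Number of fishing grounds the reefs cluster into.
#' @param closure_fraction Fraction of reefs initially inside a fishery
#'   closure (default 21/75). The number of closed reefs is
#'   `round(n_reefs * closure_fraction)`.
#' @param seed Integer seed; the same seed always yields the same table.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees. The default spans roughly one degree of a tropical
#'   seascape.
#' @param cluster_sd Spread (degrees) of reefs around their ground centroid.
#' @param herbivore_meanlog,herbivore_sdlog Log-normal parameters of
#'   herbivore density (kg/ha); the default median is 100 kg/ha.
#' @param sediment_decay E-folding scale (degrees of latitude) of the
#'   sediment index away from the simulated coast.
#' @param sediment_sdlog Log-normal multiplicative noise on the sediment
#'   index.
#'
#' @return A tibble with columns `reef_id`, `lon`, `lat`, `fishing_ground`,
#'   `closure_id` (`NA` outside closures), `herbivore_density`,
#'   `sediment_index`, `initial_coral`, `initial_macroalgae`.
#' @examples
#' reefs <- generate_seascape(seed = 1)
#' sum(!is.na(reefs$closure_id))  # 21 of 75 reefs start inside a closure
#' @export
generate_seascape <- function(n_reefs = 75,
                              n_grounds = 8,
                              closure_fraction = 21 / 75,
                              seed,
                              bbox = c(178.2, 179.2, -17.8, -17.0),
                              cluster_sd = 0.05,
                              herbivore_meanlog = log(100),
                              herbivore_sdlog = 0.75,
                              sediment_decay = 0.3,
                              sediment_sdlog = 0.3) {
  if (!is.numeric(n_reefs) || n_reefs < 2) {
    abort("`n_reefs` must be at least 2.", class = "reefstates_parameter_error")
  }
  if (!is.numeric(n_grounds) || n_grounds < 1) {
    abort("`n_grounds` must be at least 1.", class = "reefstates_parameter_error")
  }
  if (!is.numeric(closure_fraction) || closure_fraction < 0 || closure_fraction > 1) {
    abort("`closure_fraction` must lie in [0, 1].",
          class = "reefstates_parameter_error")
  }
  if (missing(seed)) abort("`seed` is required.", class = "reefstates_parameter_error")
  n_reefs <- as.integer(n_reefs)
  n_grounds <- as.integer(n_grounds)

  withr::with_seed(as.integer(seed), {
    centroid_lon <- runif(n_grounds, bbox[1], bbox[2])
    centroid_lat <- runif(n_grounds, bbox[3], bbox[4])
    ground <- sample(rep_len(seq_len(n_grounds), n_reefs))
    lon <- centroid_lon[ground] + rnorm(n_reefs, 0, cluster_sd)
    lat <- centroid_lat[ground] + rnorm(n_reefs, 0, cluster_sd)

    herb <- rlnorm(n_reefs, herbivore_meanlog, herbivore_sdlog)
    # sediment loads are highest near the coast (southern box edge) and
    # spatially autocorrelated through the shared latitudinal trend
    sediment <- exp(-(lat - min(lat)) / sediment_decay) *
      rlnorm(n_reefs, 0, sediment_sdlog)

    coral <- rbeta(n_reefs, 2, 5)
    macro <- rbeta(n_reefs, 1.5, 6) * (1 - coral)

    n_closed <- round(n_reefs * closure_fraction)
    closure_id <- rep(NA_integer_, n_reefs)
    if (n_closed > 0) {
      closure_id[sample(n_reefs, n_closed)] <- seq_len(n_closed)
    }

    reefs <- tibble(
      reef_id = seq_len(n_reefs),
      lon = lon,
      lat = lat,
      fishing_ground = ground,
      closure_id = closure_id,
      herbivore_density = herb,
      sediment_index = sediment,
      initial_coral = coral,
      initial_macroalgae = macro
    )
  })
  validate_reef_table(reefs)
  reefs
}

#' Validate a reef table
#'
#' Checks the invariants every reef table must satisfy: unique reef ids,
#' finite coordinates, non-negative covariates, and per-reef covers with
#' `initial_coral + initial_macroalgae <= 1`.
#'
#' @param reefs A reef table (see [generate_seascape()]).
#' @return `reefs`, invisibly, if valid; otherwise an error naming the
#'   offending rows and columns.
#' @export
validate_reef_table <- function(reefs) {
  required <- c("reef_id", "lon", "lat", "fishing_ground", "closure_id",
                "herbivore_density", "sediment_index",
                "initial_coral", "initial_macroalgae")
  missing_cols <- setdiff(required, names(reefs))
  if (length(missing_cols)) {
    abort(paste0("Reef table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "reefstates_validation_error")
  }
  if (anyDuplicated(reefs$reef_id)) {
    dup <- unique(reefs$reef_id[duplicated(reefs$reef_id)])
    abort(paste0("Duplicate reef_id: ", paste(dup, collapse = ", ")),
          class = "reefstates_validation_error")
  }
  if (!all(is.finite(reefs$lon)) || !all(is.finite(reefs$lat))) {
    abort("Non-finite lon/lat.", class = "reefstates_validation_error")
  }
  if (any(abs(reefs$lat) > 90)) {
    abort("Latitude outside [-90, 90].", class = "reefstates_validation_error")
  }
  if (any(reefs$herbivore_density < 0, na.rm = TRUE)) {
    abort("Negative herbivore_density.", class = "reefstates_validation_error")
  }
  if (any(reefs$sediment_index < 0, na.rm = TRUE)) {
    abort("Negative sediment_index.", class = "reefstates_validation_error")
  }
  covers <- reefs$initial_coral + reefs$initial_macroalgae
  bad <- which(reefs$initial_coral < 0 | reefs$initial_macroalgae < 0 |
                 covers > 1 + 1e-12)
  if (length(bad)) {
    abort(paste0("Covers invalid (initial_coral + initial_macroalgae must lie ",
                 "in [0, 1]) for reef_id: ",
                 paste(reefs$reef_id[bad], collapse = ", ")),
          class = "reefstates_validation_error")
  }
  invisible(reefs)
}

#' Initial benthic states for a simulation
#'
#' Translates a reef table into per-reef starting covers. `"empirical"`
#' takes the covers stored in the table (in a field application these come
#' from survey data); `"very_high_coral"` and `"very_low_coral"` are the
#' uniform extreme scenarios used to probe sensitivity to initial
#' conditions in a locally bistable system.
#'
#' @param reefs A reef table.
#' @param scenario One of `"empirical"`, `"very_high_coral"`,
#'   `"very_low_coral"`.
#' @param high,low Covers used by the uniform scenarios: the dominant state
#'   gets `high`, the rare one `low` (defaults 0.75 / 0.05).
#' @return A tibble with columns `reef_id`, `M` (macroalgae), `C` (coral).
#' @examples
#' reefs <- generate_seascape(n_reefs = 5, n_grounds = 2, seed = 1)
#' generate_initial_conditions(reefs, "very_high_coral")
#' @export
generate_initial_conditions <- function(reefs,
                                        scenario = c("empirical",
                                                     "very_high_coral",
                                                     "very_low_coral"),
                                        high = 0.75, low = 0.05) {
  scenario <- match.arg(scenario)
  validate_reef_table(reefs)
  if (high + low > 1) {
    abort("`high` + `low` must not exceed 1.",
          class = "reefstates_parameter_error")
  }
  n <- nrow(reefs)
  state <- switch(scenario,
    empirical = tibble(reef_id = reefs$reef_id,
                       M = reefs$initial_macroalgae,
                       C = reefs$initial_coral),
    very_high_coral = tibble(reef_id = reefs$reef_id,
                             M = rep(low, n), C = rep(high, n)),
    very_low_coral = tibble(reef_id = reefs$reef_id,
                            M = rep(high, n), C = rep(low, n))
  )
  state
}
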