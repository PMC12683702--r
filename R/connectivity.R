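#' Pairwise great-circle distances between reefs
#'
#' Haversine distances on a sphere of radius 6371 km, returned in km.
#'
#' @param reefs A reef table with `lon`/`lat` in decimal degrees.
#' @return A symmetric `n x n` matrix (km) with zero diagonal, dimnames set
#'   to the reef ids.
#' @examples
#' reefs <- generate_seascape(n_reefs = 4, n_grounds = 1, seed = 3)
#' reef_distances(reefs)
#' @export
reef_distances <- function(reefs) {
  if (any(abs(reefs$lat) > 90)) {
    abort("Latitude outside [-90, 90].", class = "reefstates_validation_error")
  }
  d <- geosphere::distm(cbind(reefs$lon, reefs$lat),
                        fun = function(a, b) {
                          geosphere::distHaversine(a, b, r = 6371000)
                        }) / 1000
  dimnames(d) <- list(reefs$reef_id, reefs$reef_id)
  d
}

#' Dispersal kernel configuration
#'
#' Parameters of the isotropic exponential distance-decay kernel used to
#' build synthetic connectivity matrices: the probability that a propagule
#' released at reef j settles at reef i is
#' `p0 * exp(-dist_ij / lambda)` with range
#' `lambda = speed_km_per_day * pld_days`, optionally roughened by
#' mean-one log-normal noise and then pruned below a threshold. The kernel
#' stands in for a hydrodynamic larval-transport simulation: it preserves
#' the features the network analysis depends on (dispersal range growing
#' with pelagic larval duration, sparse long-distance links, graph
#' fragmentation at short PLD) without ocean-current data.
#'
#' @param p0 Self-retention scale in (0, 1]: the settlement probability at
#'   zero distance.
#' @param speed_km_per_day Kernel range gained per day of pelagic larval
#'   duration (km/day).
#' @param noise_sd Standard deviation (log scale) of multiplicative
#'   log-normal noise; 0 disables noise. The noise has mean one, so it
#'   roughens entries without inflating them on average.
#' @param prune_threshold Entries below this value are set to zero,
#'   must be smaller than `p0`.
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(p0 = 0.10,
                          speed_km_per_day = 0.15,
                          noise_sd = 0.5,
                          prune_threshold = 1e-4) {
  if (!is.numeric(p0) || p0 <= 0 || p0 > 1) {
    abort("`p0` must lie in (0, 1].", class = "reefstates_parameter_error")
  }
  if (!is.numeric(speed_km_per_day) || speed_km_per_day <= 0) {
    abort("`speed_km_per_day` must be positive.",
          class = "reefstates_parameter_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "reefstates_parameter_error")
  }
  if (!is.numeric(prune_threshold) || prune_threshold < 0 ||
        prune_threshold >= p0) {
    abort("`prune_threshold` must lie in [0, p0).",
          class = "reefstates_parameter_error")
  }
  structure(list(p0 = p0, speed_km_per_day = speed_km_per_day,
                 noise_sd = noise_sd, prune_threshold = prune_threshold),
            class = "kernel_config")
}

#' Default kernel for macroalgal gamete dispersal
#'
#' Macroalgal gametes are short-lived and settle close to home, so their
#' kernel keeps a high self-retention scale; paired with the 5-day
#' dispersal duration this yields strong local retention and fast decay.
#'
#' @inheritParams kernel_config
#' @return A `kernel_config`.
#' @export
macroalgal_kernel <- function(p0 = 0.8, speed_km_per_day = 0.15,
                              noise_sd = 0.5, prune_threshold = 1e-4) {
  kernel_config(p0 = p0, speed_km_per_day = speed_km_per_day,
                noise_sd = noise_sd, prune_threshold = prune_threshold)
}

new_connectivity <- function(m, kind, pld_days, reef_id = NULL) {
  if (!is.null(reef_id)) dimnames(m) <- list(reef_id, reef_id)
  structure(m, kind = kind, pld_days = pld_days,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Generate a dispersal connectivity matrix
#'
#' Evaluates the distance-decay kernel over all reef pairs (see
#' [kernel_config()]). Entry `[i, j]` is the probability-like rate at
#' which propagules produced at reef j settle at reef i. Deterministic
#' given `seed`.
#'
#' @param reefs A reef table.
#' @param pld_days Pelagic larval (or gamete) duration in days; sets the
#'   kernel range `lambda = speed_km_per_day * pld_days`.
#' @param kernel A [kernel_config()].
#' @param seed Integer seed for the kernel noise (required when
#'   `noise_sd > 0`).
#' @param kind `"coral"` or `"macroalgae"`; stored as metadata.
#' @return A square matrix of class `connectivity_matrix` with attributes
#'   `kind` and `pld_days`, entries in \[0, 1\].
#' @examples
#' reefs <- generate_seascape(n_reefs = 10, n_grounds = 2, seed = 2)
#' K <- generate_connectivity(reefs, pld_days = 50,
#'                            kernel = kernel_config(noise_sd = 0), seed = 1)
#' @export
generate_connectivity <- function(reefs, pld_days,
                                  kernel = kernel_config(),
                                  seed = NULL,
                                  kind = c("coral", "macroalgae")) {
  kind <- match.arg(kind)
  if (!inherits(kernel, "kernel_config")) {
    abort("`kernel` must be a kernel_config.",
          class = "reefstates_parameter_error")
  }
  if (!is.numeric(pld_days) || pld_days <= 0) {
    abort("`pld_days` must be positive.", class = "reefstates_parameter_error")
  }
  if (nrow(reefs) < 1) {
    abort("`reefs` must be non-empty.", class = "reefstates_parameter_error")
  }
  if (kernel$noise_sd > 0 && is.null(seed)) {
    abort("`seed` is required when the kernel has noise.",
          class = "reefstates_parameter_error")
  }
  d <- reef_distances(reefs)
  lambda <- kernel$speed_km_per_day * pld_days
  m <- kernel$p0 * exp(-d / lambda)
  if (kernel$noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      noise <- matrix(rlnorm(length(m), -kernel$noise_sd^2 / 2,
                             kernel$noise_sd), nrow(m))
    })
    m <- m * noise
  }
  m[m < kernel$prune_threshold] <- 0
  m <- pmin(pmax(m, 0), 1)
  new_connectivity(m, kind, pld_days, reefs$reef_id)
}

#' Weighted average of connectivity matrices
#'
#' Element-wise convex combination of same-shape connectivity matrices
#' after weight normalisation. Used to pool kernels evaluated at several
#' pelagic larval durations into the single matrix driving the main
#' analysis; the result is marked `pld_days = "weighted-average"`.
#'
#' @param matrices A list of connectivity matrices with identical shape.
#' @param weights Non-negative weights, one per matrix, summing to more
#'   than zero. Defaults to equal weights.
#' @return A `connectivity_matrix`.
#' @export
weighted_average_connectivity <- function(matrices,
                                          weights = rep(1, length(matrices))) {
  if (!length(matrices)) {
    abort("`matrices` must be non-empty.", class = "reefstates_parameter_error")
  }
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All matrices must have the same shape.",
          class = "reefstates_structural_error")
  }
  if (length(weights) != length(matrices) || any(weights < 0)) {
    abort("`weights` must be non-negative, one per matrix.",
          class = "reefstates_parameter_error")
  }
  total <- sum(weights)
  if (total <= 0) {
    abort("`weights` must sum to more than zero.",
          class = "reefstates_parameter_error")
  }
  w <- weights / total
  out <- Reduce(`+`, Map(function(m, wi) unclass(m) * wi, matrices, w))
  kinds <- unique(vapply(matrices, function(m) {
    attr(m, "kind") %||% "coral"
  }, character(1)))
  new_connectivity(out, kind = if (length(kinds) == 1) kinds else "mixed",
                   pld_days = "weighted-average")
}

#' Coral connectivity pooled over a range of larval durations
#'
#' Convenience wrapper generating one kernel matrix per pelagic larval
#' duration and pooling them with [weighted_average_connectivity()].
#'
#' @param reefs A reef table.
#' @param seed Integer seed; sub-seeds are derived per duration.
#' @param pld_days Vector of durations (days).
#' @param kernel A [kernel_config()].
#' @param weights Pooling weights (default equal).
#' @return A `connectivity_matrix` marked as the weighted average.
#' @export
coral_connectivity <- function(reefs, seed,
                               pld_days = seq(10, 130, by = 20),
                               kernel = kernel_config(),
                               weights = rep(1, length(pld_days))) {
  mats <- purrr::imap(as.list(pld_days), function(pld, i) {
    generate_connectivity(reefs, pld, kernel,
                          seed = as.integer(seed) + i, kind = "coral")
  })
  weighted_average_connectivity(mats, weights)
}

#' Macroalgal connectivity at a short gamete dispersal duration
#'
#' @param reefs A reef table.
#' @param seed Integer seed.
#' @param pld_days Gamete dispersal duration (days, default 5).
#' @param kernel A [kernel_config()]; defaults to [macroalgal_kernel()].
#' @return A `connectivity_matrix` of kind `"macroalgae"`.
#' @export
macroalgal_connectivity <- function(reefs, seed, pld_days = 5,
                                    kernel = macroalgal_kernel()) {
  generate_connectivity(reefs, pld_days, kernel, seed = as.integer(seed),
                        kind = "macroalgae")
}

#' Structural diagnostics of a connectivity graph
#'
#' Treats reefs as linked when either direction has a positive dispersal
#' entry and summarises the resulting undirected graph. Short-range
#' kernels fragment the seascape into several weakly connected components;
#' long-range kernels keep it whole.
#'
#' @param K A square connectivity matrix.
#' @return A one-row tibble: `n_reefs`, `n_weak_components`,
#'   `degree_mean`, `degree_max`, `density` (undirected, self-loops
#'   excluded).
#' @export
network_diagnostics <- function(K) {
  if (nrow(K) != ncol(K)) {
    abort("`K` must be square.", class = "reefstates_structural_error")
  }
  adj <- (unclass(K) > 0) | (t(unclass(K)) > 0)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comps <- igraph::components(g)
  deg <- igraph::degree(g)
  tibble(
    n_reefs = nrow(K),
    n_weak_components = comps$no,
    degree_mean = mean(deg),
    degree_max = if (length(deg)) max(deg) else 0L,
    density = igraph::edge_density(g)
  )
}
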