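# Hand-built fixtures and independent oracles shared across the suite.

# A minimal valid reef table with fully controlled fields.
make_reefs <- function(lon, lat,
                       ground = rep(1L, length(lon)),
                       closure = rep(NA_integer_, length(lon)),
                       herb = rep(100, length(lon)),
                       sed = rep(1, length(lon)),
                       coral = rep(0.3, length(lon)),
                       macro = rep(0.2, length(lon))) {
  tibble::tibble(
    reef_id = seq_along(lon), lon = lon, lat = lat,
    fishing_ground = as.integer(ground), closure_id = as.integer(closure),
    herbivore_density = herb, sediment_index = sed,
    initial_coral = coral, initial_macroalgae = macro
  )
}

# Build a reef_system directly from raw pieces (bypasses covariate maps).
make_system <- function(g, d, K, N = K, a = 0.1, r = 1, gamma = 0.8) {
  structure(list(reef_id = seq_along(g), g = g, d = d, a = a, r = r,
                 gamma = gamma, K = K, N = N, scenario = "fixture"),
            class = "reef_system")
}

# Random small system on the simplex, reproducible.
random_system <- function(n, seed) {
  withr::with_seed(seed, {
    K <- matrix(runif(n * n, 0, 0.3), n)
    N <- matrix(runif(n * n, 0, 0.3), n)
    sys <- make_system(g = runif(n, 0.05, 0.6), d = runif(n, 0.1, 0.6),
                       K = K, N = N)
    M0 <- runif(n, 0, 0.5)
    C0 <- runif(n, 0, 1 - M0 - 0.01)
    list(system = sys,
         init = tibble::tibble(reef_id = seq_len(n), M = M0, C = C0))
  })
}

# Independent fixed-step RK4 oracle. The vector field is re-derived here
# from the model equations, written without reference to the package's
# implementation, so the comparison checks both the arithmetic and the
# adaptive integration.
rk4_final <- function(M0, C0, g, d, a, r, gamma, K, N, t_end, dt = 0.01) {
  f <- function(M, C) {
    F <- 1 - M - C
    dM <- a * M * C - g * M / (M + F) + gamma * F * as.vector(N %*% M)
    dC <- r * F * as.vector(K %*% C) - a * M * C - d * C
    cbind(dM, dC)
  }
  y <- cbind(M0, C0)
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) {
    k1 <- f(y[, 1], y[, 2])
    k2 <- f(y[, 1] + dt / 2 * k1[, 1], y[, 2] + dt / 2 * k1[, 2])
    k3 <- f(y[, 1] + dt / 2 * k2[, 1], y[, 2] + dt / 2 * k2[, 2])
    k4 <- f(y[, 1] + dt * k3[, 1], y[, 2] + dt * k3[, 2])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(M = y[, 1], C = y[, 2])
}

# Tag a raw matrix as a connectivity matrix (test-only constructor).
new_conn_for_test <- function(m, reefs, kind = "coral", pld = 30) {
  dimnames(m) <- list(reefs$reef_id, reefs$reef_id)
  structure(m, kind = kind, pld_days = pld,
            class = c("connectivity_matrix", "matrix", "array"))
}

# The printed six-intervention by three-scenario healthy-reef counts.
decision_table_counts <- function() {
  m <- matrix(c(
    1, 11, 12,
    1, 12, 12,
    0, 12, 14,
    1, 13, 16,
    1, 12, 14,
    1, 15, 16
  ), nrow = 6, byrow = TRUE)
  rownames(m) <- c("M1-2km", "M1-5km", "M2-10%", "M2-25%",
                   "M3-2km+10%", "M3-2km+25%")
  colnames(m) <- c("low", "medium", "high")
  m
}

# Shared default seascape + connectivity used by the heavier tests.
default_world <- function(seed = 1, n_reefs = 75) {
  reefs <- generate_seascape(n_reefs = n_reefs, seed = seed)
  list(reefs = reefs,
       K = coral_connectivity(reefs, seed = seed),
       N = macroalgal_connectivity(reefs, seed = seed + 500))
}
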