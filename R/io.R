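#' Read and write reef tables
#'
#' Reef tables are stored as plain CSV with a fixed column order. An
#' empty `closure_id` field means the reef is outside any closure and is
#' read back as `NA`, never as an empty-string category. Reading
#' validates the table and fails with the offending reef ids rather than
#' coercing bad rows.
#'
#' @param path File path.
#' @param reefs A reef table.
#' @return `read_reef_table()` returns a validated tibble;
#'   `write_reef_table()` returns `path` invisibly.
#' @export
read_reef_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "reefstates_io_error")
  }
  reefs <- readr::read_csv(path, col_types = readr::cols(
    reef_id = readr::col_integer(),
    lon = readr::col_double(),
    lat = readr::col_double(),
    fishing_ground = readr::col_integer(),
    closure_id = readr::col_integer(),
    herbivore_density = readr::col_double(),
    sediment_index = readr::col_double(),
    initial_coral = readr::col_double(),
    initial_macroalgae = readr::col_double()
  ), progress = FALSE)
  validate_reef_table(reefs)
  reefs
}

#' @rdname read_reef_table
#' @export
write_reef_table <- function(reefs, path) {
  validate_reef_table(reefs)
  cols <- c("reef_id", "lon", "lat", "fishing_ground", "closure_id",
            "herbivore_density", "sediment_index", "initial_coral",
            "initial_macroalgae")
  readr::write_csv(reefs[cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write connectivity matrices
#'
#' Square CSV with reef ids as header row and first column, preceded by a
#' `#`-prefixed metadata line recording the matrix kind and dispersal
#' duration. Reading rejects non-square grids and NaN cells with their
#' coordinates, and (optionally) checks id order against a reef table
#' instead of silently reordering.
#'
#' @param path File path.
#' @param m A connectivity matrix.
#' @param reefs Optional reef table to validate id order against.
#' @return `read_connectivity()` returns a `connectivity_matrix`;
#'   `write_connectivity()` returns `path` invisibly.
#' @export
read_connectivity <- function(path, reefs = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "reefstates_io_error")
  }
  header <- readLines(path, n = 1)
  meta <- list(kind = "coral", pld_days = NA)
  if (startsWith(header, "#")) {
    fields <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
    kv <- strsplit(fields, "=")
    for (pair in kv) {
      if (length(pair) == 2) meta[[pair[1]]] <- pair[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Matrix is not square: %d rows, %d columns.",
                  nrow(m), ncol(m)),
          class = "reefstates_validation_error")
  }
  if (!identical(ids, colnames(m))) {
    abort("Row ids do not match column ids.",
          class = "reefstates_validation_error")
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("Non-finite entries at (row,col): ",
                 paste(apply(bad, 1, paste, collapse = ","),
                       collapse = "; ")),
          class = "reefstates_validation_error")
  }
  if (!is.null(reefs) && !identical(ids, as.character(reefs$reef_id))) {
    abort("Matrix ids do not match the reef table order (no silent reorder).",
          class = "reefstates_validation_error")
  }
  pld <- suppressWarnings(as.numeric(meta$pld_days))
  new_connectivity(m, kind = meta$kind,
                   pld_days = if (is.na(pld)) meta$pld_days else pld,
                   reef_id = ids)
}

#' @rdname read_connectivity
#' @export
write_connectivity <- function(m, path) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  meta <- sprintf("# kind=%s pld_days=%s",
                  attr(m, "kind") %||% "coral",
                  attr(m, "pld_days") %||% "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- data.frame(reef_id = ids, unclass(m), check.names = FALSE)
  colnames(df) <- c("reef_id", ids)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    seed = NULL,
    n_reefs = 75L,
    n_grounds = 8L,
    closure_fraction = 21 / 75,
    a = 0.1,
    r = 1.0,
    gamma = 0.8,
    d_med = 0.44,
    d_spread = 0.5,
    t_end = 20000,
    threshold = 0.30,
    scenarios = c("low", "medium", "high"),
    init_scenario = "empirical",
    coral_pld_days = seq(10, 130, by = 20),
    macroalgal_pld_days = 5,
    coral_p0 = 0.10,
    macroalgal_p0 = 0.8,
    speed_km_per_day = 0.15,
    noise_sd = 0.5,
    prune_threshold = 1e-4,
    wq_percents = seq(30, 90, by = 10)
  )
}

#' Validate a run configuration
#'
#' Fills defaults into a raw configuration (a named list, or a YAML/JSON
#' file path auto-detected by extension), rejects unknown keys, and
#' checks ranges. A `seed` is mandatory so every run is reproducible.
#'
#' @param raw Named list, or path to a `.yml`/`.yaml`/`.json` file.
#' @return A list of class `run_config` with every default resolved and a
#'   stable `hash` (invariant under key re-ordering of the input).
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    ext <- tolower(tools::file_ext(raw))
    raw <- switch(ext,
      yml = ,
      yaml = yaml::read_yaml(raw),
      json = jsonlite::fromJSON(raw),
      abort(paste0("Unsupported config extension: ", ext),
            class = "reefstates_io_error"))
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "reefstates_validation_error")
  }
  cfg <- modifyList(defaults, raw)
  if (is.null(cfg$seed)) {
    abort("Config must provide `seed`.",
          class = "reefstates_validation_error")
  }
  if (any(cfg$wq_percents <= 0 | cfg$wq_percents > 100)) {
    abort("`wq_percents` must lie in (0, 100].",
          class = "reefstates_validation_error")
  }
  if (cfg$threshold < 0 || cfg$threshold > 1) {
    abort("`threshold` must lie in [0, 1].",
          class = "reefstates_validation_error")
  }
  bad_scen <- setdiff(cfg$scenarios, c("low", "medium", "high"))
  if (length(bad_scen)) {
    abort(paste0("Unknown scenarios: ", paste(bad_scen, collapse = ", ")),
          class = "reefstates_validation_error")
  }
  cfg <- cfg[order(names(cfg))]
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Generates the seascape and connectivity matrices, runs the factorial
#' grid, computes the EVPI, and writes every artifact (reef table,
#' matrices, resolved per-reef rates, long results, metric table, EVPI
#' report) as CSV under `out_dir`, together with a JSON manifest listing
#' the config hash, seed, package version and every output path.
#'
#' @param config A [validate_config()] result (or raw input for it).
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  reefs <- generate_seascape(config$n_reefs, config$n_grounds,
                             config$closure_fraction, seed = config$seed)
  kc <- kernel_config(config$coral_p0, config$speed_km_per_day,
                      config$noise_sd, config$prune_threshold)
  km <- kernel_config(config$macroalgal_p0, config$speed_km_per_day,
                      config$noise_sd, config$prune_threshold)
  K <- coral_connectivity(reefs, seed = config$seed,
                          pld_days = config$coral_pld_days, kernel = kc)
  N <- macroalgal_connectivity(reefs, seed = config$seed + 500,
                               pld_days = config$macroalgal_pld_days,
                               kernel = km)
  grid <- run_grid(reefs, K, N,
                   scenarios = config$scenarios,
                   init_scenario = config$init_scenario,
                   mortality = mortality_config(config$d_med,
                                                config$d_spread),
                   a = config$a, r = config$r, gamma = config$gamma,
                   t_end = config$t_end, threshold = config$threshold)
  evpi <- compute_evpi(grid$metrics)

  write_reef_table(reefs, p("reefs.csv"))
  write_connectivity(K, p("connectivity_coral.csv"))
  write_connectivity(N, p("connectivity_macroalgae.csv"))
  rates <- purrr::map(config$scenarios, function(sc) {
    sys <- build_system(reefs, K, N, scenario = sc,
                        mortality = mortality_config(config$d_med,
                                                     config$d_spread),
                        a = config$a, r = config$r, gamma = config$gamma)
    dplyr::mutate(tidy(sys), scenario = sc)
  }) |> dplyr::bind_rows()
  readr::write_csv(rates, p("rates.csv"), progress = FALSE)
  readr::write_csv(grid$results, p("results.csv"), progress = FALSE)
  readr::write_csv(grid$metrics, p("metrics.csv"), progress = FALSE)
  evpi_df <- tibble(average_of_best = evpi$average_of_best,
                    best_of_averages = evpi$best_of_averages,
                    evpi = evpi$evpi)
  readr::write_csv(evpi_df, p("evpi.csv"), progress = FALSE)
  writeLines(utils::capture.output(print(evpi)), p("evpi_report.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefstates")),
    config_hash = config$hash,
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list(
      reefs = p("reefs.csv"),
      connectivity_coral = p("connectivity_coral.csv"),
      connectivity_macroalgae = p("connectivity_macroalgae.csv"),
      rates = p("rates.csv"),
      results = p("results.csv"),
      metrics = p("metrics.csv"),
      evpi = p("evpi.csv"),
      evpi_report = p("evpi_report.txt")
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
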