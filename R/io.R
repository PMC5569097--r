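config_keys <- c("scenario", "theta", "level", "kappa", "c_ratio", "delta",
                 "alpha", "beta", "gamma", "n_cells", "mcs", "replicates",
                 "S1", "S2", "seed", "output_dir", "metric", "log_level")

#' Load and validate a run configuration
#'
#' Reads a JSON (or YAML, when the `yaml` package is available)
#' configuration, rejects unknown keys, range-checks every value and fills
#' in the standard defaults (`c_A = 1`, `delta = 0.1`, `mcs = 200`,
#' `n_cells = 50`). A config may name a registered experiment (e.g.
#' `"structured-slow-m"`) via `scenario` and override any of its settings.
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`).
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(kappa = 1, c_ratio = 0.25, delta = 0.1, gamma = 0,
                   n_cells = 50L, mcs = 200L, replicates = 50L,
                   S1 = 100L, S2 = 300L, seed = 0L, metric =
                     "euclidean_minimal_image", log_level = "info")
  cfg <- utils::modifyList(defaults, cfg)
  rng_check <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi))
      stop(sprintf("config key '%s' = %s violates range [%g, %g]",
                   key, format(v), lo, hi))
  }
  rng_check("delta", 0, 1); rng_check("gamma", 0, 1)
  rng_check("theta", 0, 1); rng_check("level", 0, 1)
  rng_check("c_ratio", 1e-9, 1)
  for (k in c("alpha", "beta")) rng_check(k, 0, 1)
  if (cfg$kappa < 0) stop("config key 'kappa' must be >= 0")
  if (!is.null(cfg$scenario) &&
      !cfg$scenario %in% names(experiment_registry()))
    stop("unknown scenario '", cfg$scenario, "'; registered: ",
         paste(names(experiment_registry()), collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Registered experiment recipes
#'
#' Named recipes encoding the simulation-study design: the homogeneous
#' low/high-resistance scans (`homog-low`, `homog-high`), the heterogeneous
#' highly-structured scenarios at large and small migration rate ratio
#' (`structured-fast-m`, `structured-slow-m`), the heterogeneity-by-rate-ratio phase diagram
#' (`phase-diagram`), the cooperativity experiment (`cooperativity`), the critical
#' homogeneous-resistance scan (`critical-scan`) and the chemotactic
#' sensitivity scan (`kappa-scan`).
#'
#' @return Named list of recipe functions; each takes
#'   `(base_seed, replicates = NULL, ...)` and returns the experiment's
#'   result object.
#' @export
experiment_registry <- function() {
  scen <- function(ecm, c_ratio) function(base_seed = 0, replicates = NULL, ...)
    run_scenario(scenario_spec(ecm = ecm, c_ratio = c_ratio,
                               replicates = replicates %||% 50L,
                               base_seed = base_seed, ...))
  list(
    `homog-low` = scen(ecm_homogeneous(0.1), 0.25),
    `homog-high` = scen(ecm_homogeneous(0.9), 0.25),
    `structured-fast-m` = scen(ecm_heterogeneous(0.5), 0.75),
    `structured-slow-m` = scen(ecm_heterogeneous(0.5), 0.25),
    `phase-diagram` = function(base_seed = 0, replicates = NULL, ...)
      phase_diagram(replicates = replicates %||% 20L,
                    base_seed = base_seed, ...),
    cooperativity = function(base_seed = 0, replicates = NULL, ...)
      cooperativity_experiment(repeats = replicates %||% 100L,
                               base_seed = base_seed, ...),
    `critical-scan` = function(base_seed = 0, replicates = NULL, ...)
      critical_resistance_scan(replicates = replicates %||% 20L,
                               base_seed = base_seed, ...),
    `kappa-scan` = function(base_seed = 0, replicates = NULL, ...)
      kappa_sensitivity(base_seed = base_seed,
                        replicates = replicates %||% 50L, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a named test fixture
#'
#' Writes a small, fully seeded simulation input bundle to `dir`: the ECM
#' field (CSV + JSON descriptor) and the initial cell placement (CSV).
#' `tiny_lattice` is a 1 x `size` lattice with a single cell, used by the
#' exact Markov-chain oracle tests; the `initial_*` kinds are the standard
#' initial conditions (homogeneous 0.5; heterogeneous weakly structured
#' `theta = 0.1`; heterogeneous highly structured `theta = 0.5`) with a
#' seeded left-column population of 50 cells.
#'
#' @param kind one of `"tiny_lattice"`, `"initial_homogeneous"`,
#'   `"initial_weak"`, `"initial_structured"`.
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param size number of columns of the tiny lattice (3 to 12).
#' @return Invisibly, the written file paths.
#' @export
generate_fixture <- function(kind = c("tiny_lattice", "initial_homogeneous",
                                      "initial_weak", "initial_structured"),
                             seed = 0, dir = tempdir(), size = 3) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  if (kind == "tiny_lattice") {
    stopifnot(size >= 3, size <= 12)
    dims <- lattice_dims(1, size)
    params <- model_params(kappa = 0, n_cells = 1, mcs = 2, dims = dims,
                           c_M = 0.25)
    ecm <- make_homogeneous_ecm(dims, 0.5)
  } else {
    dims <- lattice_dims(100, 300)
    params <- model_params(alpha = 1, beta = 1, c_M = 0.25, dims = dims)
    ecm <- switch(kind,
                  initial_homogeneous = make_homogeneous_ecm(dims, 0.5),
                  initial_weak = make_heterogeneous_ecm(dims, 0.1),
                  initial_structured = make_heterogeneous_ecm(dims, 0.5))
  }
  state <- initialize_state(params, ecm)
  ecm_path <- file.path(dir, paste0(kind, "_ecm.csv"))
  cells_path <- file.path(dir, paste0(kind, "_cells.csv"))
  write_ecm_field(ecm, ecm_path)
  utils::write.csv(state$cells, cells_path, row.names = FALSE)
  invisible(c(ecm = ecm_path, ecm_meta = paste0(ecm_path, ".json"),
              cells = cells_path))
}

#' Write tidy results with a reproducibility manifest
#'
#' Writes each element of `tables` as a CSV under `output_dir` and a
#' `manifest.json` echoing the configuration, seeds, package version,
#' timestamps and MD5 hashes of the written files. Re-running the same
#' configuration reproduces identical hashes.
#'
#' @param tables named list of data frames.
#' @param config the `run_config` (or any list) to echo.
#' @param output_dir output directory, created if missing; must be
#'   writable.
#' @param seeds integer vector of replicate seeds used.
#' @return Invisibly, a named vector of written paths.
#' @export
write_results <- function(tables, config, output_dir, seeds = integer()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, mode = 2) != 0)
    stop("output directory not writable: ", output_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  manifest <- list(config = unclass(config), seeds = seeds,
                   package_version = as.character(utils::packageVersion("switchmig")),
                   written = format(Sys.time(), tz = "UTC"),
                   hashes = as.list(tools::md5sum(paths)))
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mpath))
}
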