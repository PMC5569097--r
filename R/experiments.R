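#' Default switch-ratio grid
#'
#' The scanned phenotypic switch ratios `alpha/beta`:
#' `{1/10, 2/10, ..., 1, 2, ..., 10}`. Ratios below 1 favor the amoeboid
#' mode, above 1 the mesenchymal mode.
#'
#' @return Numeric vector of 19 ratios.
#' @export
switch_ratio_grid <- function() c((1:10) / 10, 2:10)

#' Realize a switch ratio as (alpha, beta) rates
#'
#' A ratio `<= 1` is realized as `alpha = ratio, beta = 1`; a ratio `> 1`
#' as `alpha = 1, beta = 1/ratio`, so both rate constants stay in (0, 1].
#' Population behavior depends on the ratio only, not on the particular
#' pair.
#'
#' @param ratio positive switch ratio.
#' @return List with `alpha` and `beta`.
#' @export
ratio_to_rates <- function(ratio) {
  stopifnot(ratio > 0)
  if (ratio <= 1) list(alpha = ratio, beta = 1)
  else list(alpha = 1, beta = 1 / ratio)
}

#' Scenario specification
#'
#' One cell of the simulation-study design: an ECM condition combined with
#' a chemotactic responsiveness, under which a switching arm (scanned over
#' switch ratios) is compared with a non-switching arm (scanned over
#' M-cell fractions `gamma`).
#'
#' @param ecm an `ecm_spec`, see [ecm_homogeneous()].
#' @param kappa chemotactic responsiveness.
#' @param c_ratio migration rate ratio `c_M / c_A` (with `c_A = 1`).
#' @param ratio_grid switch ratios for the switching arm.
#' @param gamma_grid M-cell fractions for the non-switching arm.
#' @param delta ECM degradation rate.
#' @param n_cells,mcs population size and run length.
#' @param replicates independent simulations per grid point.
#' @param base_seed replicate `r` uses seed `base_seed + r`; the same
#'   seeds are shared across grid points (common random numbers).
#' @param dims lattice dimensions.
#' @param metric distance metric for the summaries.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(ecm, kappa = 1, c_ratio = 0.25,
                          ratio_grid = switch_ratio_grid(),
                          gamma_grid = c(0, 0.3, 0.7, 1),
                          delta = 0.1, n_cells = 50, mcs = 200,
                          replicates = 50, base_seed = 0,
                          dims = lattice_dims(100, 300),
                          metric = "euclidean_minimal_image") {
  stopifnot(inherits(ecm, "ecm_spec"), c_ratio > 0, c_ratio <= 1,
            all(ratio_grid > 0), all(gamma_grid >= 0 & gamma_grid <= 1),
            replicates >= 1)
  structure(list(ecm = ecm, kappa = kappa, c_ratio = c_ratio,
                 ratio_grid = ratio_grid, gamma_grid = gamma_grid,
                 delta = delta, n_cells = as.integer(n_cells),
                 mcs = as.integer(mcs), replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), dims = dims,
                 metric = metric),
            class = "scenario_spec")
}

scenario_params <- function(spec, arm, setting) {
  if (arm == "switching") {
    ab <- ratio_to_rates(setting)
    model_params(alpha = ab$alpha, beta = ab$beta, c_A = 1,
                 c_M = spec$c_ratio, delta = spec$delta, kappa = spec$kappa,
                 switching = TRUE, n_cells = spec$n_cells, mcs = spec$mcs,
                 dims = spec$dims)
  } else {
    model_params(alpha = 0, beta = 0, c_A = 1, c_M = spec$c_ratio,
                 delta = spec$delta, kappa = spec$kappa, gamma = setting,
                 switching = FALSE, n_cells = spec$n_cells, mcs = spec$mcs,
                 dims = spec$dims)
  }
}

run_arm <- function(spec, arm, settings) {
  do.call(rbind, lapply(settings, function(s) {
    params <- scenario_params(spec, arm, s)
    reps <- do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
      simulate_replicate(params, spec$ecm, spec$base_seed + r,
                         metric = spec$metric)
    }))
    reps$arm <- arm
    reps$setting <- s
    reps$replicate <- seq_len(spec$replicates)
    reps
  }))
}

#' Run a full scenario (switching vs non-switching arms)
#'
#' Runs `replicates` seeded simulations for every switch ratio of the
#' switching arm and every `gamma` of the non-switching arm, and compares
#' the best settings of the two arms via [compare_best()].
#'
#' @param spec a [scenario_spec()].
#' @return A `scenario_result`: list with `summaries` (one row per
#'   replicate and grid point), `arm_means` (replicate means/sds per grid
#'   point), `comparison` (the [compare_best()] output) and `spec`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  summaries <- rbind(run_arm(spec, "switching", spec$ratio_grid),
                     run_arm(spec, "nonswitching", spec$gamma_grid))
  arm_means <- arm_mean_table(summaries)
  sw <- arm_means[arm_means$arm == "switching", ]
  ns <- arm_means[arm_means$arm == "nonswitching", ]
  comparison <- compare_best(
    setNames(sw$mean_d_p, sw$setting), setNames(ns$mean_d_p, ns$setting),
    setNames(sw$mean_d_max, sw$setting), setNames(ns$mean_d_max, ns$setting))
  structure(list(summaries = summaries, arm_means = arm_means,
                 comparison = comparison, spec = spec),
            class = "scenario_result")
}

arm_mean_table <- function(summaries) {
  agg <- do.call(rbind, lapply(split(summaries,
                                     summaries[c("setting", "arm")],
                                     drop = TRUE), function(g) {
    data.frame(arm = g$arm[1], setting = g$setting[1],
               mean_d_p = mean(g$d_p), sd_d_p = stats::sd(g$d_p),
               mean_d_max = mean(g$d_max), sd_d_max = stats::sd(g$d_max),
               replicates = nrow(g))
  }))
  rownames(agg) <- NULL
  agg[order(agg$arm, agg$setting), ]
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result\n")
  print(x$arm_means, row.names = FALSE)
  cat(sprintf("delta_d_p (best switching - best non-switching): %.3f\n",
              x$comparison$delta_d_p))
  invisible(x)
}

#' Critical homogeneous-resistance scan
#'
#' Scans constant ECM resistance levels and locates the crossover level at
#' which the greatest population-mean migration distance passes from the
#' pure amoeboid population (`gamma = 0`) to the pure mesenchymal one
#' (`gamma = 1`).
#'
#' @param levels sorted homogeneous resistance levels in [0, 1].
#' @param kappa,c_ratio,delta,n_cells,mcs,replicates,base_seed,dims,metric
#'   run settings, as in [scenario_spec()].
#' @return List with `table` (per-level means and sds for both arms and
#'   their difference), `crossover` (midpoint of the bracketing levels, or
#'   `NA`), and `outcome` (`"crossover"` or `"no crossover"`).
#' @export
critical_resistance_scan <- function(levels = seq(0.1, 0.9, by = 0.1),
                                     kappa = 1, c_ratio = 0.25, delta = 0.1,
                                     n_cells = 50, mcs = 200,
                                     replicates = 20, base_seed = 0,
                                     dims = lattice_dims(100, 300),
                                     metric = "euclidean_minimal_image") {
  stopifnot(!is.unsorted(levels), length(levels) >= 2L)
  rows <- lapply(levels, function(lev) {
    out <- lapply(c(0, 1), function(gam) {
      params <- model_params(c_M = c_ratio, delta = delta, kappa = kappa,
                             gamma = gam, switching = FALSE,
                             n_cells = n_cells, mcs = mcs, dims = dims)
      d_p <- vapply(seq_len(replicates), function(r)
        simulate_replicate(params, ecm_homogeneous(lev), base_seed + r,
                           metric = metric)$d_p, numeric(1))
      c(mean = mean(d_p), sd = stats::sd(d_p))
    })
    data.frame(level = lev,
               d_p_A = out[[1]]["mean"], sd_A = out[[1]]["sd"],
               d_p_M = out[[2]]["mean"], sd_M = out[[2]]["sd"])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$diff <- tab$d_p_A - tab$d_p_M
  flips <- which(tab$diff[-nrow(tab)] * tab$diff[-1] < 0)
  if (length(flips) == 0L) {
    list(table = tab, crossover = NA_real_, outcome = "no crossover")
  } else {
    i <- flips[1]
    list(table = tab,
         crossover = (tab$level[i] + tab$level[i + 1]) / 2,
         outcome = "crossover")
  }
}

#' Plasticity-advantage phase diagram
#'
#' Computes the best-arm difference `delta_d_p` on a grid of ECM
#' heterogeneity `theta` by migration rate ratio `c_M/c_A`. Positive
#' entries mark conditions under which phenotypic switching out-migrates
#' every fixed-mix population.
#'
#' @param theta_grid sorted heterogeneity values in [0, 1].
#' @param c_ratio_grid sorted migration rate ratios in (0, 1].
#' @param kappa,delta,n_cells,mcs,replicates,base_seed,dims,metric,
#'   ratio_grid,gamma_grid settings applied at every grid point
#'   (replicates default lower than single-scenario runs because the grid
#'   multiplies the cost).
#' @return A `phase_diagram_result`: list with `delta_d_p` (matrix, rows =
#'   `theta_grid`, cols = `c_ratio_grid`), the grids, and `details` (the
#'   per-point [compare_best()] outputs).
#' @export
phase_diagram <- function(theta_grid = seq(0, 1, by = 0.1),
                          c_ratio_grid = seq(0.1, 1, by = 0.1),
                          kappa = 1, delta = 0.1, n_cells = 50, mcs = 200,
                          replicates = 20, base_seed = 0,
                          dims = lattice_dims(100, 300),
                          metric = "euclidean_minimal_image",
                          ratio_grid = switch_ratio_grid(),
                          gamma_grid = c(0, 0.3, 0.7, 1)) {
  stopifnot(!is.unsorted(theta_grid), !is.unsorted(c_ratio_grid))
  m <- matrix(NA_real_, length(theta_grid), length(c_ratio_grid),
              dimnames = list(theta = theta_grid, c_ratio = c_ratio_grid))
  details <- list()
  for (i in seq_along(theta_grid)) for (j in seq_along(c_ratio_grid)) {
    res <- run_scenario(scenario_spec(
      ecm = ecm_heterogeneous(theta_grid[i]), kappa = kappa,
      c_ratio = c_ratio_grid[j], ratio_grid = ratio_grid,
      gamma_grid = gamma_grid, delta = delta, n_cells = n_cells,
      mcs = mcs, replicates = replicates, base_seed = base_seed,
      dims = dims, metric = metric))
    m[i, j] <- res$comparison$delta_d_p
    details[[sprintf("theta=%g,c_ratio=%g", theta_grid[i],
                     c_ratio_grid[j])]] <- res$comparison
  }
  structure(list(delta_d_p = m, theta_grid = theta_grid,
                 c_ratio_grid = c_ratio_grid, details = details),
            class = "phase_diagram_result")
}

#' Chemotactic-responsiveness sensitivity
#'
#' Recomputes the best-arm difference `delta_d_p` for each chemotactic
#' responsiveness in `kappa_grid` under a fixed ECM condition, and reports
#' the Spearman rank correlation of `delta_d_p` with `kappa` as the
#' monotone-trend statistic.
#'
#' @param kappa_grid responsiveness values in [0, 1].
#' @param ecm an `ecm_spec`.
#' @param ... further arguments passed to [scenario_spec()].
#' @return List with `table` (`kappa`, `delta_d_p`, best settings) and
#'   `spearman_rho`.
#' @export
kappa_sensitivity <- function(kappa_grid = c(0, 0.25, 0.5, 1),
                              ecm = ecm_heterogeneous(0.5), ...) {
  rows <- lapply(kappa_grid, function(k) {
    res <- run_scenario(scenario_spec(ecm = ecm, kappa = k, ...))
    data.frame(kappa = k, delta_d_p = res$comparison$delta_d_p,
               best_switching = res$comparison$best_switching_setting,
               best_nonswitching = res$comparison$best_nonswitching_setting)
  })
  tab <- do.call(rbind, rows)
  rho <- if (nrow(tab) >= 3L)
    stats::cor(tab$kappa, tab$delta_d_p, method = "spearman")
  else NA_real_
  list(table = tab, spearman_rho = rho)
}

#' Cooperativity experiment
#'
#' Compares the maximum migration distance of (i) a switching population
#' of `n` cells, (ii) a single switching cell simulated `n` times (taking
#' the maximum over repetitions), (iii) a non-switching population of `n`
#' cells, and (iv) a single non-switching cell simulated `n` times. Each
#' arm is repeated `repeats` times. A larger `d_max` for arm (i) than (ii)
#' indicates cooperative path creation: mesenchymal cells open routes that
#' the population exploits.
#'
#' Single-cell runs within one repeat share one RNG stream (including a
#' fresh ECM realization per run); population arms use one stream per
#' repeat. The single-cell arms are composition-matched to their
#' population: of the `n` single-cell repetitions of arm (iv),
#' `round(gamma * n)` start as M-cells and the rest as A-cells, mirroring
#' the population mix, and arm (ii) singles start half M, half A like the
#' switching population.
#'
#' @param n population size (and number of single-cell repetitions).
#' @param repeats number of repeats per arm.
#' @param ecm an `ecm_spec`.
#' @param ratio switch ratio of the switching arms.
#' @param gamma M-cell fraction of the non-switching arms.
#' @param c_ratio,kappa,delta,mcs run settings.
#' @param base_seed seed base; each (arm, repeat) gets a distinct offset.
#' @param dims lattice dimensions; `S1` must be at least `n`.
#' @param metric distance metric.
#' @return List with `d_max` (data frame: `arm`, `repeat_id`, `d_max`) and
#'   `arm_means` (named vector of mean `d_max` per arm, names
#'   `pop_switching`, `single_switching`, `pop_nonswitching`,
#'   `single_nonswitching`).
#' @export
cooperativity_experiment <- function(n = 500, repeats = 100,
                                     ecm = ecm_heterogeneous(0.5),
                                     ratio = 1, gamma = 0.5, c_ratio = 0.25,
                                     kappa = 1, delta = 0.1, mcs = 200,
                                     base_seed = 0,
                                     dims = lattice_dims(max(n, 100), 300),
                                     metric = "euclidean_minimal_image") {
  stopifnot(dims$S1 >= n, repeats >= 1)
  ab <- ratio_to_rates(ratio)
  p_pop_sw <- model_params(alpha = ab$alpha, beta = ab$beta, c_M = c_ratio,
                           delta = delta, kappa = kappa, switching = TRUE,
                           n_cells = n, mcs = mcs, dims = dims)
  p_one_sw <- model_params(alpha = ab$alpha, beta = ab$beta, c_M = c_ratio,
                           delta = delta, kappa = kappa, switching = TRUE,
                           n_cells = 1, mcs = mcs, dims = dims)
  p_pop_ns <- model_params(c_M = c_ratio, delta = delta, kappa = kappa,
                           gamma = gamma, switching = FALSE, n_cells = n,
                           mcs = mcs, dims = dims)
  p_one_ns <- model_params(c_M = c_ratio, delta = delta, kappa = kappa,
                           gamma = gamma, switching = FALSE, n_cells = 1,
                           mcs = mcs, dims = dims)

  # composition-matched single-cell repetitions: the first n_M of the n
  # runs start mesenchymal, the rest amoeboid
  single_arm_dmax <- function(params, m_frac, seed) {
    set.seed(seed)
    n_M <- as.integer(floor(m_frac * n + 0.5))
    max(vapply(seq_len(n), function(j) {
      state <- initialize_state(params, ecm,
                                init_m_fraction = as.numeric(j <= n_M))
      state <- run_mcs(state, params)
      max(cell_distance(state, metric = metric))
    }, numeric(1)))
  }
  arms <- list(
    pop_switching = function(t)
      simulate_replicate(p_pop_sw, ecm, base_seed + t, metric)$d_max,
    single_switching = function(t)
      single_arm_dmax(p_one_sw, 0.5, base_seed + repeats + t),
    pop_nonswitching = function(t)
      simulate_replicate(p_pop_ns, ecm, base_seed + 2L * repeats + t,
                         metric)$d_max,
    single_nonswitching = function(t)
      single_arm_dmax(p_one_ns, gamma, base_seed + 3L * repeats + t))

  d_max <- do.call(rbind, lapply(names(arms), function(a) {
    data.frame(arm = a, repeat_id = seq_len(repeats),
               d_max = vapply(seq_len(repeats), arms[[a]], numeric(1)))
  }))
  arm_means <- vapply(split(d_max$d_max, d_max$arm), mean, numeric(1))
  list(d_max = d_max, arm_means = arm_means[names(arms)])
}
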