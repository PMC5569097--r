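#' Per-cell migration distance
#'
#' Distance of each cell from its initial position. Two metrics are
#' available: `euclidean_minimal_image` (default) takes the Euclidean
#' distance with the `r1` displacement reduced modulo the periodic axis to
#' the minimal image; `axial_r2` projects onto the gradient axis,
#' `|r2 - r2_initial|`.
#'
#' @param state a `ca_state`, or a data frame with columns `r1`, `r2`,
#'   `r1_0`, `r2_0`.
#' @param dims a [lattice_dims()] object (taken from `state` when omitted).
#' @param metric distance metric.
#' @return Numeric vector of distances, one per cell.
#' @export
cell_distance <- function(state, dims = NULL,
                          metric = c("euclidean_minimal_image", "axial_r2")) {
  metric <- match.arg(metric)
  cells <- if (inherits(state, "ca_state")) state$cells else state
  if (is.null(dims) && inherits(state, "ca_state")) dims <- state$dims
  d2 <- abs(cells$r2 - cells$r2_0)
  if (metric == "axial_r2") return(as.numeric(d2))
  stopifnot(inherits(dims, "lattice_dims"))
  d1 <- abs(cells$r1 - cells$r1_0)
  d1 <- pmin(d1, dims$S1 - d1)          # minimal image on the r1 torus
  sqrt(d1^2 + d2^2)
}

#' Population-level migration summary
#'
#' Computes the invasion observables of one simulation: the migration
#' distance from the initial position averaged over the whole population
#' (`d_p`), the maximum migration distance (`d_max`), the within-run
#' standard deviation of per-cell distances, and the phenotype mix.
#'
#' @param state a `ca_state` with at least one cell.
#' @param metric distance metric, see [cell_distance()].
#' @return A one-row data frame with columns `d_p`, `d_max`, `within_sd`,
#'   `n_cells`, `frac_A`, `frac_M`, `mcs`, `metric`.
#' @export
summarize_population <- function(state,
                                 metric = c("euclidean_minimal_image", "axial_r2")) {
  metric <- match.arg(metric)
  stopifnot(inherits(state, "ca_state"))
  if (nrow(state$cells) == 0L) stop("empty population")
  d <- cell_distance(state, metric = metric)
  data.frame(d_p = mean(d), d_max = max(d),
             within_sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
             n_cells = length(d),
             frac_A = mean(state$cells$phenotype == "A"),
             frac_M = mean(state$cells$phenotype == "M"),
             mcs = state$mcs_elapsed, metric = metric)
}

#' Across-replicate statistics of d_p
#'
#' Mean, standard deviation and coefficient of variation of the
#' population-averaged migration distance across independent replicates
#' (the between-simulation variability; the within-simulation spread is
#' carried per replicate as `within_sd`).
#'
#' @param summaries data frame of replicate summaries (needs a `d_p`
#'   column), e.g. rows from [simulate_replicate()].
#' @return A list with `mean_d_p`, `sd_between`, `cv_between` and
#'   `n_replicates`. `cv_between` is `NA` with a warning when
#'   `mean_d_p == 0`.
#' @export
replicate_statistics <- function(summaries) {
  d_p <- summaries$d_p
  stopifnot(is.numeric(d_p), length(d_p) >= 2L)
  m <- mean(d_p)
  s <- stats::sd(d_p)
  cv <- if (m == 0) {
    warning("mean d_p is zero; coefficient of variation undefined")
    NA_real_
  } else s / m
  list(mean_d_p = m, sd_between = s, cv_between = cv,
       n_replicates = length(d_p))
}

#' Best-arm comparison between switching and non-switching populations
#'
#' The headline observable of the model: the difference between the best
#' switching population (over the scanned switch ratios `alpha/beta`) and
#' the best non-switching population (over the scanned M-cell fractions
#' `gamma`), in population-mean migration distance. Positive values mean
#' phenotypic plasticity is advantageous.
#'
#' @param switching named numeric vector of replicate-mean `d_p`, one per
#'   switch-ratio setting (names are the ratios).
#' @param nonswitching named numeric vector of replicate-mean `d_p`, one
#'   per `gamma` setting.
#' @param switching_d_max,nonswitching_d_max optional matching vectors of
#'   replicate-mean `d_max` for the secondary `delta_d_max` observable.
#' @return A list with `delta_d_p`, `best_switching_setting`,
#'   `best_nonswitching_setting`, the two best means, and (when the
#'   `d_max` vectors are supplied) `delta_d_max`.
#' @export
compare_best <- function(switching, nonswitching,
                         switching_d_max = NULL, nonswitching_d_max = NULL) {
  stopifnot(length(switching) >= 1L, length(nonswitching) >= 1L)
  is_b <- which.max(switching)
  in_b <- which.max(nonswitching)
  out <- list(delta_d_p = unname(switching[is_b] - nonswitching[in_b]),
              best_switching_setting = names(switching)[is_b],
              best_nonswitching_setting = names(nonswitching)[in_b],
              best_switching_d_p = unname(switching[is_b]),
              best_nonswitching_d_p = unname(nonswitching[in_b]))
  if (!is.null(switching_d_max) && !is.null(nonswitching_d_max))
    out$delta_d_max <- max(switching_d_max) - max(nonswitching_d_max)
  out
}

#' Vertically averaged cell density profile
#'
#' One-dimensional density profile along the gradient axis: the fraction
#' of occupied sites in each column `r2`, averaged over the periodic `r1`
#' direction. Summing the profile over columns gives `n_cells / S1`.
#'
#' @param state a `ca_state`.
#' @return Numeric vector of length `S2`.
#' @export
density_profile <- function(state) {
  stopifnot(inherits(state, "ca_state"))
  colMeans(state$occ != 0L)
}
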