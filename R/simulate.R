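phen_codes <- function(phenotype) ifelse(phenotype == "A", 1L, 2L)

run_core <- function(state, params, n_updates, forced_cell = 0L) {
  out <- cpp_run_updates(state$occ, state$cells$r1, state$cells$r2,
                         phen_codes(state$cells$phenotype), state$ecm,
                         params$alpha, params$beta, params$c_A, params$c_M,
                         params$delta, params$kappa, params$switching,
                         n_updates, forced_cell)
  state$occ <- out$occ
  state$cells$r1 <- out$r1
  state$cells$r2 <- out$r2
  state$cells$phenotype <- c("A", "M")[out$phen]
  state$ecm <- out$ecm
  state
}

#' Advance the automaton by whole Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is `n_cells` elementary updates, each
#' selecting one cell uniformly at random (with replacement) and applying
#' the three rules in order: resistance-dependent phenotype switch (R1,
#' skipped for non-switching populations), local ECM degradation if the
#' cell is mesenchymal (R2), and a chemotactically biased move attempt
#' under volume exclusion (R3). On average each cell is updated once per
#' MCS, the model's time unit.
#'
#' @param state a `ca_state` from [initialize_state()].
#' @param params the [model_params()] used to build the state.
#' @param n_mcs number of Monte Carlo steps; defaults to `params$mcs`.
#' @return The advanced `ca_state` (the input is not modified).
#' @export
run_mcs <- function(state, params, n_mcs = params$mcs) {
  stopifnot(inherits(state, "ca_state"), inherits(params, "model_params"),
            n_mcs >= 0)
  if (n_mcs == 0) return(state)
  state <- run_core(state, params, as.double(n_mcs) * nrow(state$cells))
  state$mcs_elapsed <- state$mcs_elapsed + as.integer(n_mcs)
  state
}

#' Apply one elementary update to a chosen cell
#'
#' Forces the single-cell update (rules R1-R3 in order) onto `cell_id`
#' instead of a randomly selected cell. Intended for rule-level testing
#' and illustration; [run_mcs()] is the simulation driver.
#'
#' @inheritParams run_mcs
#' @param cell_id cell to update (1-based id).
#' @return The updated `ca_state`.
#' @export
step_cell <- function(state, cell_id, params) {
  stopifnot(inherits(state, "ca_state"),
            cell_id >= 1, cell_id <= nrow(state$cells))
  run_core(state, params, n_updates = 1, forced_cell = as.integer(cell_id))
}

#' Run one seeded replicate end to end
#'
#' Seeds the RNG, realizes the ECM field (heterogeneous noise included),
#' places the cells, runs `params$mcs` Monte Carlo steps and summarizes
#' migration distances. All stochastic draws of the replicate come from
#' the one stream seeded here, so a (params, ecm, seed) triple fully
#' determines the outcome.
#'
#' @param params a [model_params()] object.
#' @param ecm an `ecm_spec` (see [ecm_homogeneous()]) or a concrete
#'   `ecm_field`.
#' @param seed integer replicate seed.
#' @param metric distance metric passed to [summarize_population()].
#' @param keep_state if `TRUE`, attach the final `ca_state` as attribute
#'   `"state"` of the returned summary.
#' @param init_m_fraction optional initial M-fraction override, see
#'   [initialize_state()].
#' @return A one-row data frame from [summarize_population()].
#' @examples
#' p <- model_params(alpha = 1, beta = 1, c_M = 0.25, kappa = 1,
#'                   n_cells = 10, mcs = 20, dims = lattice_dims(20, 60))
#' simulate_replicate(p, ecm_heterogeneous(0.5), seed = 1)
#' @export
simulate_replicate <- function(params, ecm, seed,
                               metric = c("euclidean_minimal_image", "axial_r2"),
                               keep_state = FALSE, init_m_fraction = NULL) {
  metric <- match.arg(metric)
  set.seed(as.integer(seed))
  state <- initialize_state(params, ecm, init_m_fraction)
  state <- run_mcs(state, params)
  out <- summarize_population(state, metric)
  out$seed <- as.integer(seed)
  if (keep_state) attr(out, "state") <- state
  out
}
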