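#' Phenotype switch rate
#'
#' Resistance-dependent switch propensity: an A-cell becomes mesenchymal
#' with rate `alpha * mu`, an M-cell becomes amoeboid with rate
#' `beta * (1 - mu)`. High local resistance therefore pushes cells toward
#' the matrix-degrading mesenchymal mode and free space pulls them back to
#' the fast amoeboid mode.
#'
#' @param phenotype `"A"` or `"M"`.
#' @param mu local ECM resistance in [0, 1].
#' @param params a [model_params()] object.
#' @return The switch rate, a value in [0, 1].
#' @examples
#' p <- model_params(alpha = 0.7, beta = 0.6)
#' switch_rate("A", 0.5, p)  # 0.35
#' @export
switch_rate <- function(phenotype, mu, params) {
  stopifnot(phenotype %in% c("A", "M"), mu >= 0, mu <= 1)
  if (phenotype == "A") params$alpha * mu else params$beta * (1 - mu)
}

#' Migration rate
#'
#' Sigmoidal resistance dependence
#' \deqn{\lambda_X(\mu) = c_X / (1 + e^{15 (\mu - 0.5)}),}
#' with \eqn{c_X = c_A} for amoeboid and \eqn{c_M} for mesenchymal cells.
#' Movement is essentially unhindered at low resistance, falls steeply
#' around \eqn{\mu = 0.5}, and is almost blocked at high resistance; the
#' steepness 15 fixes the width of the transition zone.
#'
#' @inheritParams switch_rate
#' @return The migration rate, in `(0, c_X)`.
#' @examples
#' p <- model_params(c_M = 0.25)
#' migration_rate("A", 0.5, p)  # 0.5: the logistic midpoint
#' @export
migration_rate <- function(phenotype, mu, params) {
  stopifnot(phenotype %in% c("A", "M"), mu >= 0, mu <= 1)
  c_X <- if (phenotype == "A") params$c_A else params$c_M
  c_X / (1 + exp(15 * (mu - 0.5)))
}

#' ECM degradation
#'
#' One degradation event by a mesenchymal cell: the local resistance
#' decays multiplicatively, `mu -> (1 - delta) * mu`, so degradation is
#' always partial and fully degraded sites (`mu = 0`) stay degraded.
#'
#' @param mu local ECM resistance in [0, 1].
#' @param delta degradation rate in [0, 1].
#' @return The degraded resistance, in `[0, mu]`.
#' @examples
#' degrade_ecm(0.5, 0.1)  # 0.45
#' @export
degrade_ecm <- function(mu, delta) {
  stopifnot(mu >= 0, mu <= 1, delta >= 0, delta <= 1)
  (1 - delta) * mu
}

#' Subtractive ECM degradation (sensitivity variant)
#'
#' Alternative degradation kernel `mu -> max(0, mu - delta)` for
#' sensitivity checks against the default multiplicative form.
#'
#' @inheritParams degrade_ecm
#' @return The degraded resistance.
#' @export
degrade_ecm_subtractive <- function(mu, delta) {
  stopifnot(mu >= 0, mu <= 1, delta >= 0, delta <= 1)
  pmax(0, mu - delta)
}

#' Chemotactic move-direction distribution
#'
#' Probability of attempting each von Neumann neighbor. Directions are
#' weighted exponentially in the gradient difference to the target site,
#' `exp(kappa * S2 * dG)`; since the gradient is linear with slope `1/S2`
#' along `r2`, the weights reduce to `exp(kappa)` for right, `exp(-kappa)`
#' for left and 1 for up/down — dimensionless and lattice-size
#' independent. At `kappa = 0` the distribution is uniform (unbiased
#' random walk). Off-lattice targets at the reflecting `r2` boundaries
#' keep their weight here; such attempts are aborted at execution time.
#'
#' @param kappa chemotactic responsiveness `>= 0`.
#' @return Named numeric vector of probabilities over
#'   `c("left", "right", "up", "down")`, summing to 1.
#' @examples
#' chemotactic_move_distribution(0)  # uniform 1/4
#' @export
chemotactic_move_distribution <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0)
  w <- c(left = exp(-kappa), right = exp(kappa), up = 1, down = 1)
  w / sum(w)
}
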