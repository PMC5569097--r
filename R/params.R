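#' Model parameters
#'
#' Bundles all rule parameters and run settings of the automaton.
#'
#' Rates are per unit time (one Monte Carlo step) and double as per-attempt
#' probabilities in the update scheme, which is consistent because every
#' rate constant lies in [0, 1].
#'
#' @param alpha A-to-M phenotype switch rate constant in [0, 1]; the actual
#'   switch probability of an A-cell is `alpha * mu` at local resistance
#'   `mu`.
#' @param beta M-to-A switch rate constant in [0, 1]; an M-cell switches
#'   with probability `beta * (1 - mu)`.
#' @param c_A amoeboid migration rate constant (fixed at 1 throughout the
#'   study design).
#' @param c_M mesenchymal migration rate constant in `[0, c_A]`; the ratio
#'   `c_M / c_A` measures how much slower mesenchymal movement is.
#' @param delta ECM degradation rate in [0, 1]; each update of an M-cell
#'   multiplies the local resistance by `1 - delta` (partial, never
#'   complete, degradation).
#' @param kappa chemotactic responsiveness `>= 0`; 0 gives an unbiased
#'   random walk, larger values bias moves up the gradient.
#' @param gamma fraction of M-cells in a non-switching population, in
#'   [0, 1]. Ignored when `switching = TRUE`.
#' @param switching logical; `FALSE` freezes phenotypes (`alpha` and
#'   `beta` are forced to 0).
#' @param n_cells population size; must not exceed `S1` (cells seed one
#'   per site in the left column).
#' @param mcs number of Monte Carlo steps per run; one MCS is `n_cells`
#'   random sequential single-cell updates.
#' @param dims a [lattice_dims()] object. The default 100 x 300 keeps the
#'   reflecting right boundary out of reach within 200 MCS.
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = 1, beta = 1, c_M = 0.25, kappa = 1)
#' @export
model_params <- function(alpha = 0, beta = 0, c_A = 1, c_M = 0.25,
                         delta = 0.1, kappa = 1, gamma = 0,
                         switching = alpha > 0 || beta > 0,
                         n_cells = 50, mcs = 200,
                         dims = lattice_dims(100, 300)) {
  stopifnot(inherits(dims, "lattice_dims"))
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("%s must be a single value in [0, 1]", nm))
  }
  chk01(alpha, "alpha"); chk01(beta, "beta"); chk01(c_M, "c_M")
  chk01(delta, "delta"); chk01(gamma, "gamma")
  if (!is.numeric(c_A) || c_A <= 0) stop("c_A must be positive")
  if (c_M > c_A) stop("c_M must not exceed c_A (mesenchymal cells are slower)")
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (!isTRUE(switching) && !isFALSE(switching))
    stop("switching must be TRUE or FALSE")
  if (!switching) alpha <- beta <- 0
  n_cells <- as.integer(n_cells)
  mcs <- as.integer(mcs)
  if (n_cells < 1L) stop("n_cells must be positive")
  if (n_cells > dims$S1)
    stop(sprintf("n_cells (%d) exceeds S1 (%d): the seeding column cannot hold the population",
                 n_cells, dims$S1))
  if (mcs < 0L) stop("mcs must be non-negative")
  structure(list(alpha = alpha, beta = beta, c_A = c_A, c_M = c_M,
                 delta = delta, kappa = kappa, gamma = gamma,
                 switching = switching, n_cells = n_cells, mcs = mcs,
                 dims = dims),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("model_params: %s population, n = %d, %d MCS on %d x %d\n",
                     "  alpha = %g, beta = %g, c_A = %g, c_M = %g, delta = %g,",
                     " kappa = %g, gamma = %g\n"),
              if (x$switching) "switching" else "non-switching",
              x$n_cells, x$mcs, x$dims$S1, x$dims$S2,
              x$alpha, x$beta, x$c_A, x$c_M, x$delta, x$kappa, x$gamma))
  invisible(x)
}
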