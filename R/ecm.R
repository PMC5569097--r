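#' Homogeneous ECM resistance field
#'
#' Generates a spatially constant ECM resistance field
#' `mu(r1, r2) = level`. ECM resistance is a lumped scalar in [0, 1]
#' combining matrix density, stiffness and porosity as a barrier to cell
#' movement: 0 is free space, 1 maximally resistant matrix.
#'
#' @param dims a [lattice_dims()] object.
#' @param level constant resistance value in [0, 1].
#' @return An `ecm_field` object: a list with `values` (`S1 x S2` numeric
#'   matrix), `dims`, and a `descriptor` recording generator and
#'   parameters.
#' @examples
#' f <- make_homogeneous_ecm(lattice_dims(10, 10), 0.5)
#' all(f$values == 0.5)
#' @export
make_homogeneous_ecm <- function(dims, level) {
  stopifnot(inherits(dims, "lattice_dims"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level > 1)
    stop("level must be a single value in [0, 1]")
  new_ecm_field(matrix(level, dims$S1, dims$S2), dims,
                list(generator = "homogeneous", level = level, seed = NA))
}

#' Heterogeneous ECM resistance field
#'
#' Generates a structured-plus-noise resistance field
#' \deqn{\mu(r_1, r_2) = 1 - \theta/2 + (\theta/2)\,
#'   \sin(2\pi r_1/25 + 3\pi/2)\,\sin(\pi r_2/25 + \pi/2)
#'   - (1-\theta)\,\xi(r_1, r_2),}
#' where \eqn{\xi(r_1, r_2)} are i.i.d. uniform(0, 1) variates drawn once
#' per site and fixed for the simulation's duration. The heterogeneity
#' parameter \eqn{\theta} interpolates between completely random
#' (`theta = 0`, pure per-site noise `1 - xi`) and completely coherent
#' (`theta = 1`, pure sinusoid) structure. All values lie in [0, 1] by
#' construction (the extremes are attained at sinusoid \eqn{\pm 1} and
#' \eqn{\xi \in \{0, 1\}}), so no clipping is applied; an internal
#' assertion guards the bound. The spatial mean is approximately 0.5 for
#' every `theta`.
#'
#' @param dims a [lattice_dims()] object.
#' @param theta heterogeneity parameter in [0, 1].
#' @param seed optional integer; when supplied the field is generated from
#'   a private RNG stream seeded with `seed` (the caller's RNG state is
#'   untouched) and regeneration with the same descriptor is bit-identical.
#'   When `NULL`, the noise is drawn from the current RNG stream, which is
#'   how per-replicate simulation streams consume it.
#' @param wavelength_r1,wavelength_r2 spatial periods (lattice units) of
#'   the coherent sinusoidal structure along `r1` and `r2`. Defaults give
#'   the standard field; they are exposed so alternative structured forms
#'   can be explored.
#' @return An `ecm_field` object (see [make_homogeneous_ecm()]).
#' @examples
#' f <- make_heterogeneous_ecm(lattice_dims(100, 300), theta = 0.5, seed = 1)
#' abs(mean(f$values) - 0.5) < 0.02
#' @export
make_heterogeneous_ecm <- function(dims, theta, seed = NULL,
                                   wavelength_r1 = 25, wavelength_r2 = 50) {
  stopifnot(inherits(dims, "lattice_dims"))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("theta must be a single value in [0, 1]")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  r1 <- seq_len(dims$S1)
  r2 <- seq_len(dims$S2)
  sinusoid <- outer(sin(2 * pi * r1 / wavelength_r1 + 3 * pi / 2),
                    sin(2 * pi * r2 / wavelength_r2 + pi / 2))
  xi <- matrix(stats::runif(dims$S1 * dims$S2), dims$S1, dims$S2)
  values <- 1 - theta / 2 + (theta / 2) * sinusoid - (1 - theta) * xi
  stopifnot(all(values >= 0), all(values <= 1))
  new_ecm_field(values, dims,
                list(generator = "heterogeneous", theta = theta,
                     seed = if (is.null(seed)) NA else as.integer(seed),
                     wavelength_r1 = wavelength_r1,
                     wavelength_r2 = wavelength_r2))
}

new_ecm_field <- function(values, dims, descriptor) {
  structure(list(values = values, dims = dims, descriptor = descriptor),
            class = "ecm_field")
}

#' @export
print.ecm_field <- function(x, ...) {
  d <- x$descriptor
  extra <- if (d$generator == "homogeneous") sprintf("level = %g", d$level)
           else sprintf("theta = %g, seed = %s", d$theta, d$seed)
  cat(sprintf("ECM resistance field %d x %d (%s, %s); mean %.3f\n",
              x$dims$S1, x$dims$S2, d$generator, extra, mean(x$values)))
  invisible(x)
}

#' Write / read an ECM field
#'
#' The field matrix is stored as a headerless CSV and its descriptor
#' (generator, parameters, seed) as a JSON side-car `<path>.json`, so
#' fields are regenerable and comparable.
#'
#' @param field an `ecm_field`.
#' @param path CSV file path.
#' @return `write_ecm_field` returns `path` invisibly; `read_ecm_field`
#'   returns the reconstructed `ecm_field`.
#' @export
write_ecm_field <- function(field, path) {
  stopifnot(inherits(field, "ecm_field"))
  utils::write.table(field$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    c(field$descriptor[!is.na(field$descriptor)],
      list(S1 = field$dims$S1, S2 = field$dims$S2)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ecm_field
#' @export
read_ecm_field <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- lattice_dims(meta$S1, meta$S2)
  stopifnot(nrow(values) == dims$S1, ncol(values) == dims$S2)
  meta$S1 <- meta$S2 <- NULL
  new_ecm_field(values, dims, as.list(meta))
}
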