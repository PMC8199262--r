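#' Energy parameters for the confidence-weighted Lennard-Jones loss
#'
#' The pair loss is `beta * theta^n * ((rm/d)^12 - 2 * (rm/d)^6)`, truncated
#' to zero beyond `cutoff`. The well depth `beta * theta^n` encodes how hard
#' a pair's in-contact distance is to break: observed contacts (`theta = 1`)
#' get the full depth `beta`, imputed neighbours shallower wells, and
#' `theta = 0` pairs no constraint at all.
#'
#' Exactly one of `sigma` (the zero-crossing distance) or `rm` (the well
#' position, `rm = 2^(1/6) * sigma`) is given; the other is derived. The two
#' benchmark settings are `sigma = 8` (so `rm` is about 8.976) and `rm = 8`.
#'
#' @param sigma Distance at which the potential crosses zero (lattice units).
#' @param rm Distance at the bottom of the well (lattice units); mutually
#'   exclusive with `sigma`.
#' @param n Well-depth exponent (positive integer); default 2.
#' @param beta Scaling factor; default 10.
#' @param cutoff Truncation distance (lattice units); default 16, pairs
#'   further apart contribute zero loss.
#' @return An `energy_params` object with fields `sigma`, `rm`, `n`, `beta`,
#'   `cutoff`.
#' @export
energy_params <- function(sigma = 8, rm = NULL, n = 2L, beta = 10,
                          cutoff = 16) {
  if (!is.null(rm)) {
    stopifnot(rm > 0)
    sigma <- rm / 2^(1 / 6)
  } else {
    stopifnot(sigma > 0)
    rm <- equilibrium_distance(sigma)
  }
  stopifnot(n >= 1, beta > 0, cutoff > rm)
  structure(list(sigma = sigma, rm = rm, n = as.integer(n), beta = beta,
                 cutoff = cutoff),
            class = "energy_params")
}

#' The Lennard-Jones pair potential
#'
#' `V(r) = epsilon * ((rm/r)^12 - 2 * (rm/r)^6)`: minimum `-epsilon` at
#' `r = rm`, zero at `r = rm / 2^(1/6)`, repulsive below, weakly attractive
#' above.
#'
#' @param r Distance(s), must be positive.
#' @param epsilon Well depth.
#' @param rm Well position.
#' @return Potential energy, vectorized over `r`.
#' @export
lj_potential <- function(r, epsilon, rm) {
  if (any(r <= 0)) stop("lj_potential requires r > 0")
  s6 <- (rm / r)^6
  epsilon * (s6^2 - 2 * s6)
}

#' Well position from the zero-crossing distance
#'
#' @param sigma Zero-crossing distance; must be positive.
#' @return `2^(1/6) * sigma`, the distance at the bottom of the well.
#' @export
equilibrium_distance <- function(sigma) {
  stopifnot(all(sigma > 0))
  2^(1 / 6) * sigma
}

#' Confidence-weighted truncated Lennard-Jones pair loss
#'
#' @param theta Contact confidence in \[0, 1\].
#' @param d Pair distance (lattice units); must be positive.
#' @param params An [energy_params()] object.
#' @return `beta * theta^n * ((rm/d)^12 - 2 * (rm/d)^6)`, or 0 when
#'   `d > cutoff` or `theta = 0`. Vectorized over `theta` and `d`.
#' @export
pair_loss <- function(theta, d, params = energy_params()) {
  if (any(d <= 0)) stop("pair_loss requires d > 0 (overlapping beads)")
  stopifnot(all(theta >= 0), all(theta <= 1))
  out <- ifelse(d > params$cutoff | theta == 0, 0,
                params$beta * theta^params$n *
                  ((params$rm / d)^12 - 2 * (params$rm / d)^6))
  out
}

#' Total loss of a conformation
#'
#' Sum of [pair_loss()] over all unordered bead pairs i < j, with Euclidean
#' distances taken from the lattice coordinates.
#'
#' @param conf A `lattice_conformation` (or bare l x 3 coordinate matrix).
#' @param theta A `theta_matrix` (or bare l x l matrix).
#' @param params An [energy_params()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(conf, theta, params = energy_params()) {
  xyz <- coords_of(conf)
  th <- theta_values(theta)
  if (nrow(xyz) != nrow(th)) {
    stop("conformation has ", nrow(xyz), " beads but theta has ", nrow(th))
  }
  total_loss_cpp(xyz, th, params$rm, params$n, params$beta, params$cutoff)
}

#' Loss change for a single-bead move
#'
#' Change in [total_loss()] if `bead` moved to `new_pos`, computed from the
#' moved bead's pair terms only; exactly equals the full-recomputation
#' difference.
#'
#' @param conf A `lattice_conformation`.
#' @param theta A `theta_matrix`.
#' @param params An [energy_params()] object.
#' @param bead Bead index (1-based).
#' @param new_pos Integer 3-vector, the proposed lattice site.
#' @return Scalar loss change.
#' @export
delta_loss <- function(conf, theta, params, bead, new_pos) {
  xyz <- coords_of(conf)
  th <- theta_values(theta)
  stopifnot(bead >= 1, bead <= nrow(xyz), length(new_pos) == 3L)
  new_pos <- as.integer(new_pos)
  occ <- which(xyz[, 1L] == new_pos[1L] & xyz[, 2L] == new_pos[2L] &
                 xyz[, 3L] == new_pos[3L])
  if (length(occ) > 0L && !identical(occ, as.integer(bead))) {
    stop("target lattice site is occupied by bead ", occ[1L])
  }
  delta_loss_cpp(xyz, th, params$rm, params$n, params$beta, params$cutoff,
                 bead - 1L, new_pos)
}
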