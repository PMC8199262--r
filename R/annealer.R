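#' Simulated annealing configuration
#'
#' Defaults follow the method's published schedule: start at temperature 10,
#' multiply by 0.9 at each level, run each level until either `100 * l`
#' attempts or `10 * l` accepted moves, stop below temperature 0.01 (by which
#' uphill acceptance is negligible; the schedule itself states no stopping
#' rule). Refinement to higher resolution uses `5 * l` attempts at a constant
#' temperature of 0.1.
#'
#' @param t0 Initial temperature.
#' @param cool_factor Per-level temperature multiplier in (0, 1).
#' @param attempts_factor Attempts cap per level is `attempts_factor * l`.
#' @param accepts_factor Accepted-move cap per level is `accepts_factor * l`.
#' @param t_min Stopping temperature; levels run while `Tc >= t_min`.
#' @param seed Master RNG seed; replicate m of an ensemble uses `seed + m - 1`.
#' @param n_models Number of replicate structures for model selection.
#' @param refine_temp Constant temperature during high-resolution refinement.
#' @param refine_attempts_factor Refinement attempts are
#'   `refine_attempts_factor * l_fine`.
#' @return An `anneal_config` object.
#' @export
anneal_config <- function(t0 = 10, cool_factor = 0.9, attempts_factor = 100,
                          accepts_factor = 10, t_min = 0.01, seed = 1L,
                          n_models = 50L, refine_temp = 0.1,
                          refine_attempts_factor = 5) {
  stopifnot(cool_factor > 0, cool_factor < 1, t_min > 0, t_min < t0,
            attempts_factor > 0, accepts_factor > 0,
            refine_attempts_factor > 0, refine_temp > 0, n_models >= 1)
  structure(list(t0 = t0, cool_factor = cool_factor,
                 attempts_factor = attempts_factor,
                 accepts_factor = accepts_factor, t_min = t_min,
                 seed = as.integer(seed), n_models = as.integer(n_models),
                 refine_temp = refine_temp,
                 refine_attempts_factor = refine_attempts_factor),
            class = "anneal_config")
}

#' Temperature at a cooling level
#'
#' @param p Level index (0-based; 0 is the initial temperature).
#' @param config An [anneal_config()].
#' @return `t0 * cool_factor^p`, vectorized over `p`.
#' @export
temperature_at <- function(p, config = anneal_config()) {
  stopifnot(all(p >= 0))
  config$t0 * config$cool_factor^p
}

cooling_schedule <- function(config) {
  p_max <- floor(log(config$t_min / config$t0) / log(config$cool_factor))
  temps <- temperature_at(0:(p_max + 1L), config)
  temps[temps >= config$t_min]
}

#' Metropolis acceptance probability
#'
#' Downhill and neutral moves (`delta <= 0`) are always accepted; uphill
#' moves with probability `exp(-delta / tc)`.
#'
#' @param delta Loss change of the proposed move.
#' @param tc Current temperature; must be positive.
#' @return Acceptance probability in (0, 1\], vectorized over `delta`.
#' @export
acceptance_probability <- function(delta, tc) {
  stopifnot(tc > 0)
  ifelse(delta <= 0, 1, exp(-delta / tc))
}

# 26 lattice neighbour offsets (all +-1 combinations minus the null move)
neighbor_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Propose a single-bead move
#'
#' Picks a bead uniformly and one of its 26 adjacent lattice cells uniformly.
#' The proposal is flagged invalid (never acceptable, but still counted as an
#' attempt by the sampler) if it leaves the lattice or lands on an occupied
#' site.
#'
#' @param conf A `lattice_conformation`.
#' @return List with `bead` (1-based index), `new_pos` (integer 3-vector) and
#'   `valid` (logical).
#' @export
propose_move <- function(conf) {
  xyz <- coords_of(conf)
  l <- nrow(xyz)
  b <- sample.int(l, 1L)
  off <- neighbor_offsets()[sample.int(26L, 1L), ]
  np <- as.integer(xyz[b, ] + off)
  inside <- all(np >= 0L) && all(np < conf$lattice_side)
  occupied <- inside &&
    any(xyz[, 1L] == np[1L] & xyz[, 2L] == np[2L] & xyz[, 3L] == np[3L])
  list(bead = b, new_pos = np, valid = inside && !occupied)
}

#' Random lattice initialization of a bead chain
#'
#' Beads are added one by one: each new bead is placed at a Euclidean
#' distance in \[2, 10\] from its sequential predecessor and at distance >= 2
#' from all previously placed beads, on a free site of the `5 * l` cube.
#' (Requiring distance in \[2, 10\] from *all* previous beads, available via
#' `constraint = "all"`, caps the chain diameter at 10 and is unsatisfiable
#' for long chains.) Dead ends trigger bounded backtracking, then a restart.
#'
#' @param l Number of beads.
#' @param seed Optional RNG seed; if `NULL`, the current RNG state is used.
#' @param lattice_side Cube side, default `5 * l`.
#' @param constraint `"predecessor"` (default) or `"all"`.
#' @param resolution Bead size in bp, stored on the result.
#' @return A `lattice_conformation`.
#' @export
initialize_structure <- function(l, seed = NULL, lattice_side = 5L * l,
                                 constraint = c("predecessor", "all"),
                                 resolution = NA_real_) {
  constraint <- match.arg(constraint)
  stopifnot(l >= 1, lattice_side >= 1)
  if (l > lattice_side^3) stop("lattice cannot hold ", l, " beads")
  if (!is.null(seed)) set.seed(seed)

  for (restart in 1:50) {
    coords <- matrix(NA_integer_, l, 3L)
    center <- as.integer(lattice_side %/% 2L)
    coords[1L, ] <- c(center, center, center)
    i <- 2L
    backtracks <- 0L
    while (i <= l) {
      placed <- FALSE
      for (try in 1:200) {
        off <- sample.int(21L, 3L, replace = TRUE) - 11L  # [-10, 10]
        d2p <- sum(off^2)
        if (d2p < 4 || d2p > 100) next
        np <- coords[i - 1L, ] + off
        if (any(np < 0L) || any(np >= lattice_side)) next
        prev <- coords[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1L] - np[1L])^2 + (prev[, 2L] - np[2L])^2 +
          (prev[, 3L] - np[3L])^2
        ok <- if (constraint == "all") all(d2 >= 4 & d2 <= 100)
              else all(d2 >= 4)
        if (!ok) next
        coords[i, ] <- as.integer(np)
        placed <- TRUE
        break
      }
      if (placed) {
        i <- i + 1L
      } else if (i > 2L && backtracks < 10L * l) {
        coords[i - 1L, ] <- NA_integer_
        i <- i - 1L
        backtracks <- backtracks + 1L
      } else {
        break
      }
    }
    if (i > l) {
      return(lattice_conformation(coords, lattice_side = lattice_side,
                                  resolution = resolution))
    }
  }
  stop("initialization failed for l = ", l,
       " after bounded restarts (constraint = ", constraint, ")")
}

#' Anneal a conformation against an imputed contact-confidence matrix
#'
#' Runs lattice Metropolis-Hastings simulated annealing: starting from a
#' random initialization, at each temperature level proposals are drawn until
#' the attempts or accepted-moves cap is hit, then the temperature is
#' multiplied by the cooling factor, stopping below `t_min`. Fully
#' reproducible from `config$seed`.
#'
#' @param theta A `theta_matrix` (or bare symmetric matrix in \[0,1\]).
#' @param params An [energy_params()] object.
#' @param config An [anneal_config()] object.
#' @param init Optional starting `lattice_conformation`; by default a fresh
#'   random initialization is drawn.
#' @param resolution Bead size in bp, stored on the result.
#' @return List with `conformation` (a `lattice_conformation`), `trace`
#'   (data.frame: level, temp, loss, accept_rate, attempts) and `loss`
#'   (final total loss).
#' @export
anneal <- function(theta, params = energy_params(), config = anneal_config(),
                   init = NULL, resolution = NA_real_) {
  th <- theta_values(theta)
  l <- nrow(th)
  set.seed(config$seed)
  if (is.null(init)) {
    init <- initialize_structure(l, lattice_side = 5L * l,
                                 resolution = resolution)
  }
  temps <- cooling_schedule(config)
  res <- metropolis_run_cpp(init$coords, th, params$rm, params$n,
                            params$beta, params$cutoff, temps,
                            as.integer(config$attempts_factor * l),
                            config$accepts_factor * l, init$lattice_side)
  trace <- data.frame(level = seq_along(temps) - 1L,
                      temp = res$trace[, 1L], loss = res$trace[, 2L],
                      accept_rate = res$trace[, 3L],
                      attempts = res$trace[, 4L])
  conf <- lattice_conformation(res$coords, lattice_side = init$lattice_side,
                               resolution = resolution)
  list(conformation = conf, trace = trace, loss = res$loss)
}

# Nearest free lattice site to p0, searching shells of increasing Chebyshev
# radius; deterministic (offsets ordered by squared norm, then lexicographic).
snap_to_free_site <- function(p0, occupied_keys, lattice_side, max_radius = 4L) {
  for (r in 0:max_radius) {
    offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    offs <- offs[apply(abs(offs), 1L, max) == r, , drop = FALSE]
    ord <- order(rowSums(offs^2), offs[, 1L], offs[, 2L], offs[, 3L])
    offs <- offs[ord, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      p <- p0 + offs[k, ]
      if (any(p < 0) || any(p >= lattice_side)) next
      key <- paste(p, collapse = ",")
      if (!(key %in% occupied_keys)) return(as.integer(p))
    }
  }
  NULL
}

#' Refine a coarse structure to higher resolution
#'
#' Inserts `ratio - 1` beads between every two consecutive coarse beads by
#' jittered linear interpolation (uniform jitter of +-1 per axis, snapped to
#' the nearest free lattice site, genomic order preserved), then applies
#' exactly `refine_attempts_factor * l_fine` Metropolis attempts at the
#' constant refinement temperature — enough to relax the inserted beads
#' without a large alteration of the coarse topology. Coarse anchor beads
#' remain movable.
#'
#' @param coarse A coarse `lattice_conformation` (e.g. 500 kb beads).
#' @param theta_fine `theta_matrix` at the fine resolution; its bead count
#'   must equal `ratio * (l_coarse - 1) + 1`.
#' @param params An [energy_params()] object.
#' @param config An [anneal_config()] object (seed, refinement settings).
#' @param ratio Coarse-to-fine bead ratio (default 10: 500 kb to 50 kb).
#' @return List with `conformation`, `trace`, `loss` as in [anneal()].
#' @export
refine_high_resolution <- function(coarse, theta_fine,
                                   params = energy_params(),
                                   config = anneal_config(), ratio = 10L) {
  th <- theta_values(theta_fine)
  lc <- nrow(coarse$coords)
  lf <- as.integer(ratio * (lc - 1L) + 1L)
  if (nrow(th) != lf) {
    stop("theta_fine has ", nrow(th), " beads; expected ", lf,
         " = ", ratio, " * (", lc, " - 1) + 1")
  }
  set.seed(config$seed)
  side <- max(coarse$lattice_side, 5L * lf)
  fine <- matrix(NA_integer_, lf, 3L)
  fine[seq.int(1L, lf, by = ratio), ] <- coarse$coords
  keys <- apply(coarse$coords, 1L, paste, collapse = ",")
  for (a in seq_len(lc - 1L)) {
    p1 <- coarse$coords[a, ]
    p2 <- coarse$coords[a + 1L, ]
    for (k in seq_len(ratio - 1L)) {
      t_frac <- k / ratio
      p0 <- round(p1 + t_frac * (p2 - p1)) +
        sample.int(3L, 3L, replace = TRUE) - 2L  # jitter in {-1,0,1}
      p0 <- pmin(pmax(as.integer(p0), 0L), side - 1L)
      p <- snap_to_free_site(p0, keys, side)
      if (is.null(p)) {
        stop("could not place inserted bead between coarse beads ", a,
             " and ", a + 1L, "; consider a larger lattice")
      }
      fine[(a - 1L) * ratio + 1L + k, ] <- p
      keys <- c(keys, paste(p, collapse = ","))
    }
  }
  res <- metropolis_run_cpp(fine, th, params$rm, params$n, params$beta,
                            params$cutoff, config$refine_temp,
                            as.integer(config$refine_attempts_factor * lf),
                            Inf, side)
  conf <- lattice_conformation(res$coords, lattice_side = side,
                               resolution = if (is.na(coarse$resolution))
                                 NA_real_ else coarse$resolution / ratio)
  trace <- data.frame(level = 0L, temp = res$trace[, 1L],
                      loss = res$trace[, 2L], accept_rate = res$trace[, 3L],
                      attempts = res$trace[, 4L])
  list(conformation = conf, trace = trace, loss = res$loss)
}
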