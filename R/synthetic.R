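#' Generate a ground-truth reference chain on the lattice
#'
#' Builds a self-avoiding lattice chain with consecutive-bead steps among the
#' 26 neighbours (distances in \[1, sqrt(3)\]). `"confined_globule"`
#' additionally confines the walk to a ball of radius `confinement * l^(1/3)`
#' around the lattice centre, mimicking chromosome-territory compaction;
#' `"random_walk"` is unconfined. Dead ends trigger backtracking, then a
#' restart.
#'
#' @param l Number of beads (>= 2).
#' @param style `"confined_globule"` (default) or `"random_walk"`.
#' @param seed Optional RNG seed.
#' @param confinement Radius coefficient for the confined style (default 2).
#' @param resolution Bead size in bp stored on the result.
#' @return A `lattice_conformation`.
#' @export
generate_reference_chain <- function(l, style = c("confined_globule",
                                                  "random_walk"),
                                     seed = NULL, confinement = 2,
                                     resolution = NA_real_) {
  style <- match.arg(style)
  stopifnot(l >= 2)
  if (!is.null(seed)) set.seed(seed)
  side <- 5L * l
  center <- rep(side %/% 2L, 3L)
  radius2 <- if (style == "confined_globule") (confinement * l^(1 / 3))^2
             else Inf
  offs <- neighbor_offsets()

  for (restart in 1:50) {
    coords <- matrix(NA_integer_, l, 3L)
    coords[1L, ] <- center
    occ <- new.env(hash = TRUE, parent = emptyenv())
    assign(paste(center, collapse = ","), TRUE, envir = occ)
    i <- 2L
    backtracks <- 0L
    while (i <= l) {
      ord <- sample.int(26L)
      placed <- FALSE
      for (m in ord) {
        np <- coords[i - 1L, ] + offs[m, ]
        if (any(np < 0L) || any(np >= side)) next
        if (sum((np - center)^2) > radius2) next
        key <- paste(np, collapse = ",")
        if (exists(key, envir = occ, inherits = FALSE)) next
        coords[i, ] <- as.integer(np)
        assign(key, TRUE, envir = occ)
        placed <- TRUE
        break
      }
      if (placed) {
        i <- i + 1L
      } else if (i > 2L && backtracks < 20L * l) {
        rm(list = paste(coords[i - 1L, ], collapse = ","), envir = occ)
        coords[i - 1L, ] <- NA_integer_
        i <- i - 1L
        backtracks <- backtracks + 1L
      } else {
        break
      }
    }
    if (i > l) {
      return(lattice_conformation(coords, lattice_side = side,
                                  resolution = resolution))
    }
  }
  stop("could not grow a self-avoiding chain of length ", l,
       " (style = ", style, ")")
}

#' Sample a sparse single-cell-like contact list from a known structure
#'
#' Draws `n_contacts` bead pairs uniformly without replacement from the
#' non-adjacent pairs whose true Euclidean distance is below `threshold`
#' (adjacent pairs carry no information: the backbone already fixes them),
#' and writes them in the plain-text contact-list dialect read by
#' [read_contacts()], with genomic positions at bin midpoints so binning at
#' `resolution` recovers exactly the sampled bead pairs.
#'
#' @param conf The ground-truth `lattice_conformation`.
#' @param threshold True-distance ceiling defining candidate contacts.
#' @param n_contacts Number of contacts to sample.
#' @param resolution Bead size in bp.
#' @param seed Optional RNG seed.
#' @param chrom Chromosome name to write.
#' @param path Optional output file; if `NULL` the lines are only returned.
#' @return Invisibly, a list with `pairs` (n x 2 matrix of 1-based bead
#'   indices), `lines` (the contact-list text) and `path`.
#' @export
sample_contacts <- function(conf, threshold, n_contacts, resolution,
                            seed = NULL, chrom = "chrS", path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- distance_matrix(conf)
  l <- nrow(dm)
  cand <- which(upper.tri(dm) & dm < threshold &
                  abs(row(dm) - col(dm)) > 1L, arr.ind = TRUE)
  if (nrow(cand) < n_contacts) {
    stop("only ", nrow(cand), " bead pairs lie within distance ", threshold,
         "; cannot sample ", n_contacts)
  }
  sel <- cand[sample.int(nrow(cand), n_contacts), , drop = FALSE]
  pos_a <- (sel[, 1L] - 1L) * resolution + resolution / 2
  pos_b <- (sel[, 2L] - 1L) * resolution + resolution / 2
  lines <- sprintf("%s %d %s %d", chrom, as.integer(pos_a), chrom,
                   as.integer(pos_b))
  if (!is.null(path)) writeLines(lines, path)
  invisible(list(pairs = unname(sel), lines = lines, path = path))
}

#' Build a complete synthetic benchmarking scenario
#'
#' @param l Bead count (default 333, the X-chromosome bead count at 500 kb).
#' @param n_contacts Sparse contact count (default 438, the surviving
#'   single-cell contact count after self-contact removal).
#' @param style Chain style, see [generate_reference_chain()].
#' @param contact_threshold True-distance ceiling for candidate contacts
#'   (default 8 lattice units, the in-contact distance).
#' @param resolution Bead size in bp.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return A `synthetic_scenario` object: list with `true_conf`, `contacts`
#'   (sampled pairs + text lines), `contact_matrix` and the generating
#'   parameters.
#' @export
synthetic_scenario <- function(l = 333L, n_contacts = 438L,
                               style = "confined_globule",
                               contact_threshold = 8, resolution = 500000,
                               seed = 1L, chrom = "chrS") {
  true_conf <- generate_reference_chain(l, style = style, seed = seed,
                                        resolution = resolution)
  contacts <- sample_contacts(true_conf, contact_threshold, n_contacts,
                              resolution, chrom = chrom)
  tmp <- tempfile(fileext = ".con.txt")
  writeLines(contacts$lines, tmp)
  recs <- read_contacts(tmp, chrom)
  unlink(tmp)
  cm <- bin_to_matrix(recs, resolution, chrom_length = l * resolution,
                      chrom = chrom)
  structure(list(l = l, true_conf = true_conf, contacts = contacts,
                 contact_matrix = cm, contact_threshold = contact_threshold,
                 n_contacts = n_contacts, resolution = resolution,
                 style = style, seed = seed, chrom = chrom),
            class = "synthetic_scenario")
}

#' Run a structure-recovery experiment on a synthetic scenario
#'
#' Pipelines the scenario's sampled contacts through imputation, replicate
#' annealing and consensus selection, then measures how well the selected
#' model recovers the ground truth: the confidence-distance Pearson
#' correlation, the Mann-Whitney test between the `theta = 1` and
#' `theta in (0, 0.7]` distance bins, and the Spearman correlation between
#' true and inferred distance matrices (upper triangles).
#'
#' @param scenario A [synthetic_scenario()].
#' @param impute_params An [impute_params()] object.
#' @param energy_params An [energy_params()] object.
#' @param config An [anneal_config()]; replicate m uses `seed + m - 1`.
#' @return List with `selected` (the chosen conformation), `ensemble`,
#'   `pearson`, `mwu_1_vs_low`, `spearman_true` (rho + p) and `theta`.
#' @export
recovery_experiment <- function(scenario,
                                impute_params = scLJfold::impute_params(),
                                energy_params = scLJfold::energy_params(),
                                config = anneal_config(n_models = 5L)) {
  theta <- gaussian_impute(scenario$contact_matrix, impute_params)
  models <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    cfg_m <- config
    cfg_m$seed <- config$seed + m - 1L
    models[[m]] <- anneal(theta, energy_params, cfg_m,
                          resolution = scenario$resolution)$conformation
  }
  sel <- if (config$n_models > 1L) select_best(models)
         else list(index = 1L, ensemble = NULL)
  best <- models[[sel$index]]
  pear <- pearson_theta_distance(theta, best)
  bins <- suppressWarnings(distances_by_theta_bins(theta, best))
  mwu <- if (length(bins$theta_1) > 0L && length(bins$theta_low) > 0L) {
    mann_whitney_u(bins$theta_1, bins$theta_low)
  } else list(u = NA_real_, p = NA_real_)
  ut <- upper.tri(matrix(0, scenario$l, scenario$l))
  sp <- suppressWarnings(
    stats::cor.test(distance_matrix(scenario$true_conf)[ut],
                    distance_matrix(best)[ut], method = "spearman"))
  list(selected = best, ensemble = sel$ensemble, models = models,
       pearson = pear, mwu_1_vs_low = mwu, theta_bins = bins,
       spearman_true = list(rho = unname(sp$estimate), p = sp$p.value),
       theta = theta)
}
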