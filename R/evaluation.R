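#' Euclidean distance matrix of a conformation
#'
#' @param conf A `lattice_conformation` or l x 3 coordinate matrix.
#' @return Symmetric l x l matrix of pairwise Euclidean distances, zero
#'   diagonal.
#' @export
distance_matrix <- function(conf) {
  as.matrix(stats::dist(coords_of(conf)))
}

#' Pearson correlation between contact confidences and model distances
#'
#' Correlates theta values with Euclidean distances over the strict upper
#' triangle (`l * (l - 1) / 2` pairs, diagonal excluded). A good fit gives a
#' negative correlation: high-confidence pairs should sit at short distances.
#'
#' @param theta A `theta_matrix` (or bare matrix).
#' @param conf A `lattice_conformation`.
#' @return List with `r`, `p` (two-sided) and `n_pairs`.
#' @export
pearson_theta_distance <- function(theta, conf) {
  th <- theta_values(theta)
  dm <- distance_matrix(conf)
  if (nrow(th) != nrow(dm)) stop("bead counts differ")
  ut <- upper.tri(th)
  x <- th[ut]
  y <- dm[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant theta or distances; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_pairs = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x))
}

#' Partition model distances by contact-confidence bin
#'
#' Splits strict-upper-triangle pairs into the three confidence bins used
#' throughout the evaluation: `theta = 1`, `theta in (0.7, 1)` and
#' `theta in (0, 0.7]`; pairs with `theta = 0` are excluded entirely.
#'
#' @param theta A `theta_matrix` (or bare matrix).
#' @param conf A `lattice_conformation`.
#' @return Named list of three numeric distance vectors: `theta_1`,
#'   `theta_high` and `theta_low`.
#' @export
distances_by_theta_bins <- function(theta, conf) {
  th <- theta_values(theta)
  dm <- distance_matrix(conf)
  if (nrow(th) != nrow(dm)) stop("bead counts differ")
  ut <- upper.tri(th)
  x <- th[ut]
  d <- dm[ut]
  out <- list(theta_1 = d[x == 1],
              theta_high = d[x > 0.7 & x < 1],
              theta_low = d[x > 0 & x <= 0.7])
  empty <- names(out)[vapply(out, length, integer(1)) == 0L]
  if (length(empty) > 0L) {
    warning("empty theta bin(s): ", paste(empty, collapse = ", "))
  }
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Normal approximation with continuity and tie correction (via
#' [stats::wilcox.test()]; the reported W for `x` is the U statistic).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `u` (U statistic for `x`) and `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Contact probability as a function of genomic distance
#'
#' For each genomic separation `s` (in beads), the fraction of bead pairs at
#' that separation whose Euclidean distance is below `contact_threshold`.
#' The returned curve uses every integer separation up to 50 beads and
#' log-spaced bins beyond. The log-log slope of P(s), fitted by least
#' squares over `s` in `[fit_range[1], fit_range[2]]` (defaults 2 beads to
#' l/4), is reported next to the fractal-globule (-1) and equilibrium-globule
#' (-3/2) reference exponents.
#'
#' @param conf A `lattice_conformation`.
#' @param contact_threshold Distance below which a pair counts as a contact
#'   (default 8 lattice units).
#' @param resolution Bead size in bp used to report `s_bp`.
#' @param fit_range Optional length-2 vector of bead separations over which
#'   to fit the slope.
#' @return List with `curve` (data.frame: s_beads, s_bp, prob, n_pairs) and
#'   `slope` (fitted log10 P vs log10 s slope), plus the two reference
#'   exponents.
#' @export
contact_probability_curve <- function(conf, contact_threshold = 8,
                                      resolution = NA_real_,
                                      fit_range = NULL) {
  stopifnot(contact_threshold > 0)
  xyz <- coords_of(conf)
  l <- nrow(xyz)
  dm <- distance_matrix(xyz)
  s_all <- seq_len(l - 1L)
  prob <- numeric(l - 1L)
  npair <- integer(l - 1L)
  for (s in s_all) {
    i <- seq_len(l - s)
    dd <- dm[cbind(i, i + s)]
    prob[s] <- mean(dd < contact_threshold)
    npair[s] <- length(dd)
  }
  # integer separations up to 50 beads; geometric bins beyond
  if (l - 1L > 50L) {
    edges <- unique(round(exp(seq(log(51), log(l - 1L), length.out = 15L))))
    bins <- c(as.list(1:50), mapply(function(a, b) seq.int(a, b),
                                    c(51L, utils::head(edges, -1L) + 1L),
                                    edges, SIMPLIFY = FALSE))
    bins <- bins[vapply(bins, length, integer(1)) > 0L]
  } else {
    bins <- as.list(s_all)
  }
  curve <- do.call(rbind, lapply(bins, function(ss) {
    ss <- ss[ss <= l - 1L]
    w <- npair[ss]
    data.frame(s_beads = sum(ss * w) / sum(w),
               prob = sum(prob[ss] * w) / sum(w),
               n_pairs = sum(w))
  }))
  curve$s_bp <- curve$s_beads * resolution
  if (is.null(fit_range)) fit_range <- c(2, max(2, floor(l / 4)))
  sel <- s_all >= fit_range[1L] & s_all <= fit_range[2L] & prob > 0
  slope <- if (sum(sel) >= 2L) {
    unname(stats::coef(stats::lm(log10(prob[sel]) ~ log10(s_all[sel])))[2L])
  } else NA_real_
  list(curve = curve[, c("s_beads", "s_bp", "prob", "n_pairs")],
       slope = slope, fractal_reference = -1, equilibrium_reference = -1.5)
}

#' Radius of gyration
#'
#' Root-mean-square bead distance from the centroid; smaller values mean a
#' more compact structure. Because absolute lattice units are
#' scale-dependent, a normalized variant (raw value divided by the maximum
#' pairwise distance) is reported alongside.
#'
#' @param conf A `lattice_conformation`.
#' @return List with `rg_raw` (lattice units) and `rg_normalized`
#'   (dimensionless; `NA` for a single bead).
#' @export
radius_of_gyration <- function(conf) {
  xyz <- coords_of(conf)
  cen <- colMeans(xyz)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2L, cen)^2)))
  dmax <- if (nrow(xyz) > 1L) max(stats::dist(xyz)) else 0
  list(rg_raw = rg,
       rg_normalized = if (dmax > 0) rg / dmax else NA_real_)
}

#' Distances of user-supplied probe pairs
#'
#' Extracts model distances for a list of bead pairs, e.g. to correlate the
#' structure against 3D-FISH probe-pair measurements.
#'
#' @param conf A `lattice_conformation`.
#' @param probe_pairs Two-column matrix (or data.frame) of 1-based bead
#'   indices.
#' @return Numeric vector of Euclidean distances, one per row.
#' @export
probe_pair_distances <- function(conf, probe_pairs) {
  xyz <- coords_of(conf)
  pp <- as.matrix(probe_pairs)
  stopifnot(ncol(pp) == 2L)
  if (any(pp < 1L) || any(pp > nrow(xyz))) {
    stop("probe pair index out of range 1..", nrow(xyz))
  }
  sqrt(rowSums((xyz[pp[, 1L], , drop = FALSE] -
                  xyz[pp[, 2L], , drop = FALSE])^2))
}

#' Full evaluation report for a reconstructed structure
#'
#' @param theta A `theta_matrix`.
#' @param conf A `lattice_conformation`.
#' @param contact_threshold Contact distance for the P(s) curve.
#' @param resolution Bead size in bp.
#' @return List with the confidence-distance correlation, the Mann-Whitney
#'   tests between confidence bins, the contact-probability curve and slope,
#'   and the radius of gyration.
#' @export
evaluate_structure <- function(theta, conf, contact_threshold = 8,
                               resolution = NA_real_) {
  pear <- pearson_theta_distance(theta, conf)
  bins <- suppressWarnings(distances_by_theta_bins(theta, conf))
  mwu <- list()
  pairs <- list(c("theta_1", "theta_high"), c("theta_1", "theta_low"),
                c("theta_high", "theta_low"))
  for (pr in pairs) {
    nm <- paste(pr, collapse = "_vs_")
    mwu[[nm]] <- if (length(bins[[pr[1L]]]) > 0L &&
                       length(bins[[pr[2L]]]) > 0L) {
      mann_whitney_u(bins[[pr[1L]]], bins[[pr[2L]]])
    } else {
      list(u = NA_real_, p = NA_real_)
    }
  }
  pofs <- contact_probability_curve(conf, contact_threshold, resolution)
  rg <- radius_of_gyration(conf)
  list(pearson = pear, theta_bins = bins, mwu = mwu, pofs = pofs,
       rg = rg)
}
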