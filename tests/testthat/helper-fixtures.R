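# Shared fixtures and independent oracles.

# Random valid lattice conformation (distinct sites, inside the 5l cube).
random_conformation <- function(l, seed = 1, lattice_side = 5L * l) {
  set.seed(seed)
  repeat {
    coords <- matrix(sample.int(lattice_side, 3L * l, replace = TRUE) - 1L,
                     l, 3L)
    if (!anyDuplicated(coords)) break
  }
  lattice_conformation(coords, lattice_side = lattice_side)
}

# Independent brute-force total loss: plain double loop over the loss
# formula, no package energy code involved.
brute_total_loss <- function(coords, theta, rm, n, beta, cutoff) {
  l <- nrow(coords)
  total <- 0
  for (i in seq_len(l - 1L)) {
    for (j in seq.int(i + 1L, l)) {
      th <- theta[i, j]
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (th > 0 && d <= cutoff) {
        total <- total + beta * th^n * ((rm / d)^12 - 2 * (rm / d)^6)
      }
    }
  }
  total
}

# Exact Mann-Whitney U (counting oracle) with two-sided permutation p-value
# by full enumeration; small samples only.
exact_mwu <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  mu <- nx * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# Independent TM-score oracle: direct numerical maximization of the TM
# objective over rigid motions (rotation angles + translation), multi-start.
oracle_tm <- function(a, b, n_starts = 25, seed = 42) {
  set.seed(seed)
  L <- nrow(a)
  d0 <- if (L > 15) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8) else 0.5
  rot_mat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    rx %*% ry %*% rz
  }
  score_of <- function(par) {
    bt <- sweep(b %*% t(rot_mat(par[1:3])), 2L, par[4:6], `+`)
    -mean(1 / (1 + rowSums((a - bt)^2) / d0^2))
  }
  pool <- numeric(0)
  pars <- list()
  for (s in seq_len(n_starts)) {
    ang0 <- stats::runif(3, 0, 2 * pi)
    # translation start matching the centroids under the starting rotation
    tr0 <- colMeans(a) - as.numeric(rot_mat(ang0) %*% colMeans(b)) +
      stats::rnorm(3, 0, 0.5)
    par0 <- c(ang0, tr0)
    fit <- stats::optim(par0, score_of, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    pool <- c(pool, -fit$value)
    pars[[s]] <- fit$par
  }
  # polish the leading local optima with a gradient-free second pass
  for (k in order(pool, decreasing = TRUE)[1:min(5, length(pool))]) {
    fit2 <- stats::optim(pars[[k]], score_of, method = "BFGS",
                         control = list(maxit = 500))
    pool <- c(pool, -fit2$value)
  }
  max(pool)
}

# Tiny contact list file in the standard 4+ column dialect.
write_contact_fixture <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
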