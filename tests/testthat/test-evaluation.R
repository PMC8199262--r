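test_that("distance matrix is Euclidean, symmetric, zero-diagonal", {
  co <- rbind(c(0L, 0L, 0L), c(3L, 4L, 0L), c(1L, 1L, 1L))
  dm <- distance_matrix(lattice_conformation(co, lattice_side = 15L))
  expect_equal(dm[1, 2], 5)
  expect_equal(diag(dm), rep(0, 3), ignore_attr = TRUE)
  expect_equal(dm, t(dm))
})

test_that("confidence-distance correlation runs on the strict upper triangle", {
  l <- 333L
  expect_equal(l * (l - 1L) / 2L, 55278L)

  conf <- random_conformation(20, seed = 2)
  dm <- distance_matrix(conf)
  # theta exactly proportional to -distance: r = -1
  th <- 1 - dm / max(dm)
  diag(th) <- 0
  res <- pearson_theta_distance(th, conf)
  expect_equal(res$r, -1)
  expect_equal(res$n_pairs, 190L)

  # matches the textbook formula on a small fixture
  set.seed(3)
  th2 <- matrix(runif(400), 20, 20)
  th2 <- (th2 + t(th2)) / 2
  diag(th2) <- 0
  r2 <- pearson_theta_distance(th2, conf)
  ut <- upper.tri(dm)
  x <- th2[ut]; y <- dm[ut]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2$r, hand, tolerance = 1e-12)
  expect_equal(r2$n_pairs, choose(20, 2))

  expect_warning(flat <- pearson_theta_distance(matrix(0, 20, 20), conf),
                 "constant")
  expect_true(is.na(flat$r))
})

test_that("theta bins partition the non-zero pairs", {
  conf <- random_conformation(15, seed = 6)
  set.seed(7)
  th <- matrix(runif(225), 15, 15)
  th[th < 0.3] <- 0
  th <- pmax(th, t(th))
  diag(th) <- 0
  th[2, 9] <- th[9, 2] <- 1
  bins <- distances_by_theta_bins(th, conf)
  n_zero <- sum(th[upper.tri(th)] == 0)
  expect_equal(length(bins$theta_1) + length(bins$theta_high) +
                 length(bins$theta_low) + n_zero, choose(15, 2))
  expect_true(length(bins$theta_1) >= 1)

  all_one <- matrix(1, 15, 15); diag(all_one) <- 0
  expect_warning(b2 <- distances_by_theta_bins(all_one, conf), "empty")
  expect_equal(length(b2$theta_high), 0L)
  expect_equal(length(b2$theta_low), 0L)
  expect_equal(length(b2$theta_1), choose(15, 2))
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  res <- mann_whitney_u(x, y)
  expect_equal(res$u, 0)
  oracle <- exact_mwu(x, y)
  expect_equal(oracle$u, 0)
  expect_equal(oracle$p, 0.1)  # 2/20 assignments as extreme

  # identical samples: U = n^2 / 2
  z <- c(2.5, 3.1, 4.7, 5.2)
  expect_equal(mann_whitney_u(z, z)$u, 8)

  set.seed(15)
  for (k in 1:4) {
    a <- round(runif(5), 2)
    b <- round(runif(6) + 0.2, 2)
    expect_equal(mann_whitney_u(a, b)$u, exact_mwu(a, b)$u)
  }

  # large shifted normals: overwhelming evidence
  set.seed(16)
  big <- mann_whitney_u(rnorm(500), rnorm(500) + 2)
  expect_lt(big$p, 1e-10)
  expect_error(mann_whitney_u(numeric(0), y), "empty")
})

test_that("contact probability is exact on degenerate geometries", {
  # straight chain, unit spacing: P(s) = 1 for s <= 7, 0 beyond (threshold 8)
  l <- 30L
  co <- cbind(0:(l - 1L), 0L, 0L)
  conf <- lattice_conformation(co, lattice_side = 5L * l)
  pc <- contact_probability_curve(conf, contact_threshold = 8)
  int_part <- pc$curve[pc$curve$s_beads <= l - 1, ]
  expect_equal(int_part$prob[int_part$s_beads <= 7], rep(1, 7))
  expect_equal(int_part$prob[int_part$s_beads >= 8], rep(0, 22))

  # tight ball: all pairs in contact at every separation
  co2 <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  pc2 <- contact_probability_curve(lattice_conformation(co2, 20L), 8)
  expect_equal(pc2$curve$prob, rep(1, 3))
})

test_that("a lattice random walk scales with a plausible globule exponent", {
  conf <- generate_reference_chain(300, "random_walk", seed = 21)
  pc <- contact_probability_curve(conf, contact_threshold = 8)
  expect_false(is.na(pc$slope))
  expect_gt(pc$slope, -2.0)
  expect_lt(pc$slope, -1.0)
  expect_equal(pc$fractal_reference, -1)
  expect_equal(pc$equilibrium_reference, -1.5)
})

test_that("radius of gyration has its closed-form values", {
  one <- lattice_conformation(matrix(c(1L, 1L, 1L), 1), lattice_side = 10L)
  expect_equal(radius_of_gyration(one)$rg_raw, 0)
  two <- lattice_conformation(rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)),
                              lattice_side = 10L)
  expect_equal(radius_of_gyration(two)$rg_raw, 1)
  expect_equal(radius_of_gyration(two)$rg_normalized, 0.5)
  # 8 corners of a side-2 cube: rg = sqrt(3)
  corners <- as.matrix(expand.grid(c(0L, 2L), c(0L, 2L), c(0L, 2L)))
  cube <- lattice_conformation(corners, lattice_side = 10L)
  expect_equal(radius_of_gyration(cube)$rg_raw, sqrt(3))
})

test_that("probe pair distances match the distance matrix", {
  conf <- random_conformation(25, seed = 5)
  dm <- distance_matrix(conf)
  pairs <- rbind(c(1, 1), c(2, 7), c(3, 25), c(10, 11))
  d <- probe_pair_distances(conf, pairs)
  expect_equal(d[1], 0)
  expect_equal(d, dm[pairs])
  co <- rbind(c(0L, 0L, 0L), c(3L, 4L, 0L))
  expect_equal(probe_pair_distances(lattice_conformation(co, 10L),
                                    cbind(1, 2)), 5)
  expect_error(probe_pair_distances(conf, rbind(c(0, 5))), "range")
  expect_error(probe_pair_distances(conf, rbind(c(1, 26))), "range")
})

test_that("evaluation quantities are invariant under rigid motion", {
  conf <- random_conformation(18, seed = 14)
  set.seed(14)
  th <- matrix(runif(324), 18, 18)
  th <- (th + t(th)) / 2
  diag(th) <- 0
  shifted <- lattice_conformation(conf$coords + 5L,
                                  lattice_side = conf$lattice_side + 5L)
  r1 <- pearson_theta_distance(th, conf)
  r2 <- pearson_theta_distance(th, shifted)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(radius_of_gyration(conf)$rg_raw,
               radius_of_gyration(shifted)$rg_raw, tolerance = 1e-12)
  pc1 <- contact_probability_curve(conf, 8)
  pc2 <- contact_probability_curve(shifted, 8)
  expect_equal(pc1$curve$prob, pc2$curve$prob)
})
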