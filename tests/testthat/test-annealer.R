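test_that("cooling schedule is geometric and strictly decreasing", {
  cfg <- anneal_config()
  expect_equal(temperature_at(0, cfg), 10)
  expect_equal(temperature_at(1, cfg), 9)
  expect_equal(temperature_at(2, cfg), 8.1)
  expect_equal(temperature_at(22, cfg), 10 * 0.9^22)
  expect_lt(temperature_at(22, cfg), 1)
  expect_gt(temperature_at(21, cfg), 1)
  temps <- scLJfold:::cooling_schedule(cfg)
  expect_true(all(diff(temps) < 0))
  expect_true(all(temps >= cfg$t_min))
  expect_lt(temps[length(temps)] * cfg$cool_factor, cfg$t_min)
  expect_equal(temps, 10 * 0.9^(seq_along(temps) - 1))
})

test_that("acceptance probability implements the Metropolis rule", {
  expect_equal(acceptance_probability(-3.2, 5), 1)
  expect_equal(acceptance_probability(0, 5), 1)
  expect_equal(acceptance_probability(5, 5), exp(-1))
  expect_equal(acceptance_probability(2, 0.5), exp(-4))
  expect_error(acceptance_probability(1, 0))
})

test_that("initialization respects spacing constraints and the lattice", {
  one <- initialize_structure(1, seed = 1)
  expect_equal(nrow(one$coords), 1L)

  two <- initialize_structure(2, seed = 2)
  d <- sqrt(sum((two$coords[1, ] - two$coords[2, ])^2))
  expect_gte(d, 2)
  expect_lte(d, 10)

  conf <- initialize_structure(60, seed = 3)
  expect_true(all(conf$coords >= 0) && all(conf$coords < 300))
  expect_equal(anyDuplicated(conf$coords), 0L)
  # consecutive beads within [2, 10], all pairs >= 2
  steps <- sqrt(rowSums(diff(conf$coords)^2))
  expect_true(all(steps >= 2 & steps <= 10))
  expect_gte(min(dist(conf$coords)), 2)

  # all-pairs variant feasible only for short chains: diameter capped at 10
  small <- initialize_structure(8, seed = 4, constraint = "all")
  expect_lte(max(dist(small$coords)), 10)
  expect_gte(min(dist(small$coords)), 2)
})

test_that("initialization is deterministic from its seed", {
  a <- initialize_structure(50, seed = 11)
  b <- initialize_structure(50, seed = 11)
  expect_identical(a$coords, b$coords)
})

test_that("proposals are uniform over the 26 neighbours", {
  conf <- lattice_conformation(matrix(c(50L, 50L, 50L), 1), lattice_side = 101L)
  set.seed(99)
  n <- 10000L
  keys <- character(n)
  for (k in seq_len(n)) {
    pr <- propose_move(conf)
    expect_true(pr$valid)
    keys[k] <- paste(pr$new_pos, collapse = ",")
  }
  counts <- table(keys)
  expect_length(counts, 26L)
  # 3-sigma binomial bounds around n/26
  p <- 1 / 26
  bound <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= bound))
})

test_that("corner and occupied-site proposals are flagged invalid", {
  conf <- lattice_conformation(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                               lattice_side = 10L)
  set.seed(5)
  seen_invalid <- FALSE
  for (k in 1:200) {
    pr <- propose_move(conf)
    inside <- all(pr$new_pos >= 0L) && all(pr$new_pos < 10L)
    onto_other <- any(apply(conf$coords, 1, function(r)
      all(r == pr$new_pos)))
    expect_equal(pr$valid, inside && !onto_other)
    if (!pr$valid) seen_invalid <- TRUE
  }
  expect_true(seen_invalid)
})

test_that("annealing a null objective leaves loss at zero and moves freely", {
  th <- matrix(0, 10, 10)
  fit <- anneal(th, energy_params(), anneal_config(seed = 3, t0 = 1,
                                                   t_min = 0.5,
                                                   attempts_factor = 20))
  expect_equal(fit$loss, 0)
  expect_true(all(fit$trace$loss == 0))
  expect_gt(mean(fit$trace$accept_rate), 0.5)  # only invalid proposals fail
})

test_that("two beads with theta = 1 settle into the potential well", {
  th <- matrix(c(0, 1, 1, 0), 2, 2)
  p <- energy_params()
  fit <- anneal(th, p, anneal_config(seed = 21, attempts_factor = 200))
  d <- sqrt(sum((fit$conformation$coords[1, ] - fit$conformation$coords[2, ])^2))
  expect_gte(d, p$sigma)
  expect_lte(d, p$cutoff)
  expect_lte(fit$loss, -0.5 * p$beta)
})

test_that("annealing is deterministic and respects per-level caps", {
  set.seed(1000)  # outer state must not matter
  th <- gaussian_impute(synthetic_scenario(l = 30, n_contacts = 40,
                                           seed = 5)$contact_matrix)
  cfg <- anneal_config(seed = 17, attempts_factor = 40, accepts_factor = 4)
  a <- anneal(th, energy_params(), cfg)
  b <- anneal(th, energy_params(), cfg)
  expect_identical(a$conformation$coords, b$conformation$coords)
  expect_identical(a$trace, b$trace)
  expect_true(all(a$trace$attempts <= 40 * 30))
  # a level ending before the attempts cap must have hit the accepts cap:
  # acceptance counts = rate * attempts = 4 * 30 where capped
  early <- a$trace$attempts < 40 * 30
  expect_true(all(round(a$trace$accept_rate[early] *
                          a$trace$attempts[early]) == 4 * 30))
})

test_that("accepted conformations never overlap or leave the lattice", {
  th <- gaussian_impute(synthetic_scenario(l = 25, n_contacts = 30,
                                           seed = 9)$contact_matrix)
  fit <- anneal(th, energy_params(), anneal_config(seed = 2,
                                                   attempts_factor = 30))
  co <- fit$conformation$coords
  expect_equal(anyDuplicated(co), 0L)
  expect_true(all(co >= 0) && all(co < fit$conformation$lattice_side))
})

test_that("a lone contact pulls its pair closer than matched unconstrained pairs", {
  l <- 14L
  th <- matrix(0, l, l)
  th[3, 12] <- th[12, 3] <- 1
  p <- energy_params()
  cfg0 <- anneal_config(attempts_factor = 60)
  d_contact <- d_control <- numeric(20)
  for (s in 1:20) {
    cfg <- cfg0
    cfg$seed <- 100 + s
    fit <- anneal(th, p, cfg)
    dm <- distance_matrix(fit$conformation)
    d_contact[s] <- dm[3, 12]
    # matched theta = 0 pairs at the same sequence separation
    d_control[s] <- median(c(dm[1, 10], dm[2, 11], dm[4, 13], dm[5, 14]))
  }
  expect_lt(median(d_contact), median(d_control))
})

test_that("longer cooling finds no worse minima on a fixed fixture", {
  th <- gaussian_impute(synthetic_scenario(l = 20, n_contacts = 25,
                                           seed = 13)$contact_matrix)
  p <- energy_params()
  loss_short <- loss_long <- numeric(8)
  for (s in 1:8) {
    loss_short[s] <- anneal(th, p, anneal_config(seed = 200 + s, t_min = 1,
                                                 attempts_factor = 40))$loss
    loss_long[s] <- anneal(th, p, anneal_config(seed = 200 + s, t_min = 0.01,
                                                attempts_factor = 40))$loss
  }
  expect_lte(mean(loss_long), mean(loss_short))
})

test_that("refinement inserts nine beads per coarse interval and preserves order", {
  coarse <- initialize_structure(2, seed = 31, lattice_side = 200L,
                                 resolution = 500000)
  th_fine <- matrix(0, 11, 11)
  fit <- refine_high_resolution(coarse, th_fine, energy_params(),
                                anneal_config(seed = 31))
  expect_equal(nrow(fit$conformation$coords), 11L)
  expect_equal(fit$loss, 0)  # null fine objective: loss untouched
  expect_equal(fit$trace$attempts, 5 * 11)
  expect_equal(fit$conformation$resolution, 50000)
  expect_error(refine_high_resolution(coarse, matrix(0, 12, 12)),
               "expected 11")
})

test_that("refined chains stay near the coarse path under the chain term", {
  sc <- synthetic_scenario(l = 8, n_contacts = 6, contact_threshold = 10,
                           seed = 41)
  th <- gaussian_impute(sc$contact_matrix)
  cfg <- anneal_config(seed = 41, attempts_factor = 40)
  fit <- anneal(th, energy_params(), cfg, resolution = 5e5)
  lf <- 10L * 7L + 1L
  cmf <- matrix(0L, lf, lf)
  th_fine <- gaussian_impute(contact_matrix(cmf, 5e4), connect_chain = TRUE)
  ref <- refine_high_resolution(fit$conformation, th_fine, energy_params(),
                                cfg)
  co <- ref$conformation$coords
  expect_equal(anyDuplicated(co), 0L)
  # anchors started on the coarse path; bounded drift after 5l attempts
  anchors <- co[seq.int(1L, lf, by = 10L), ]
  drift <- sqrt(rowSums((anchors - fit$conformation$coords)^2))
  expect_lte(max(drift), 2 * sqrt(3) * 5 + 1e-9)
})
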