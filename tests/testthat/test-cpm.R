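test_that("Hamiltonian matches exhaustive enumeration and closed-form terms", {
  pp <- potts_params()
  # all-empty lattice has zero energy (empty-empty interface energy is 0)
  empty <- lattice_state(matrix(0L, 8, 8), 10)
  expect_identical(hamiltonian(empty, integer(0), pp), 0)

  # one 4-site square cell, toy parameters: only the interface term remains
  toy <- potts_params(lambda_a = 1e-4, lambda_p = 0, a0 = 400)
  g <- matrix(0L, 10, 10); g[5:6, 5:6] <- 1L
  lat <- lattice_state(g, 10)
  expect_equal(hamiltonian(lat, 0L, toy),
               oracle_hamiltonian(g, 0L, toy, 10))
  # area term vanishes at a = a0 = 400, so H is the weighted boundary-pair
  # count times J10 * dx: 8 first-order edges + 12 external diagonal pairs
  # at w2 = 1/2 (the 2 internal diagonals are same-cell, excluded)
  expect_equal(hamiltonian(lat, 0L, toy), (8 + 0.5 * 12) * 0.06 * 10)

  # 21-site initial cell with typical values: area term lambda_a*(2100-1960)^2
  lat21 <- fixture_single_cell_lattice(c(20, 20), 10)
  expect_equal(1e-4 * (2100 - 1960)^2, 1.96)
  expect_equal(hamiltonian(lat21, 0L, pp),
               oracle_hamiltonian(lat21$grid, 0L, pp, 10))
  # and with the elongation flag set, the lambda_l / l term joins in
  expect_equal(hamiltonian(lat21, 1L, pp),
               oracle_hamiltonian(lat21$grid, 1L, pp, 10))
})

test_that("incremental energy change equals full recompute on random proposals", {
  pp <- potts_params(connectivity = FALSE)
  lat <- fixture_random_lattice(c(12, 12), 3, dx = 10, seed = 7)
  phi <- c(0L, 1L, 1L)
  set.seed(31)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  n_checked <- 0
  attempts <- 0
  while (n_checked < 1000 && attempts < 20000) {
    attempts <- attempts + 1
    x <- c(sample(12, 1), sample(12, 1))
    xp <- (x - 1 + offs[sample(8, 1), ]) %% 12 + 1
    snew <- lat$grid[x[1], x[2]]
    if (lat$grid[xp[1], xp[2]] == snew) {
      expect_identical(delta_h(lat, phi, pp, x, xp), 0)
      next
    }
    dh <- delta_h(lat, phi, pp, x, xp)
    if (!is.finite(dh)) next  # annihilation guard
    H1 <- oracle_hamiltonian(lat$grid, phi, pp, 10)
    g2 <- lat$grid; g2[xp[1], xp[2]] <- snew
    H2 <- oracle_hamiltonian(g2, phi, pp, 10)
    expect_equal(dh, H2 - H1, tolerance = 1e-10)
    n_checked <- n_checked + 1
    # evolve the state through some accepted proposals to vary the test cases
    if (runif(1) < 0.3) lat$grid[xp[1], xp[2]] <- snew
  }
  expect_gte(n_checked, 1000)
})

test_that("a copy that would annihilate a cell's last site is rejected", {
  g <- matrix(0L, 6, 6); g[3, 3] <- 1L; g[3, 4] <- 2L
  lat <- lattice_state(g, 10)
  pp <- potts_params()
  dh <- delta_h(lat, c(0L, 0L), pp, c(3, 4), c(3, 3))
  expect_identical(dh, Inf)
})

test_that("haptotaxis bias follows the occupancy-difference rule", {
  g <- matrix(0L, 6, 6); g[3, 3] <- 1L
  lat <- lattice_state(g, 10)
  pp <- potts_params(mu_h = 1.5e14)
  b <- matrix(1e-13, 6, 6)
  # equal bound VEGF: no bias
  expect_equal(haptotaxis_bias(2.5, b, lat, pp, c(3, 3), c(3, 4)), 2.5)
  # both sites cell-occupied: bias vanishes regardless of the gradient
  g2 <- g; g2[3, 4] <- 2L
  lat2 <- lattice_state(g2, 10)
  b2 <- b; b2[3, 4] <- 5e-13
  expect_equal(haptotaxis_bias(2.5, b2, lat2, pp, c(3, 3), c(3, 4)), 2.5)
  # cell extending into medium up a gradient of 1e-14: -1.5 a.e.u. at dh = 0
  b3 <- b; b3[3, 4] <- b[3, 3] + 1e-14
  expect_equal(haptotaxis_bias(0, b3, lat, pp, c(3, 3), c(3, 4)), -1.5)
})

test_that("Metropolis acceptance probability has the printed form", {
  expect_identical(acceptance_probability(0), 1)
  expect_identical(acceptance_probability(-7.3), 1)
  expect_equal(acceptance_probability(log(2)), 0.5)
  expect_equal(acceptance_probability(c(-1, 0, 1)), c(1, 1, exp(-1)))
  # empirical acceptance frequency matches the probability (binomial CI)
  set.seed(41)
  p_target <- acceptance_probability(1.2)
  acc <- mean(runif(20000) < p_target)
  expect_lt(abs(acc - p_target), 3 * sqrt(p_target * (1 - p_target) / 20000))
})

test_that("cell geometry returns exact lattice measures", {
  g <- matrix(0L, 10, 10); g[4, 4] <- 1L
  one <- cell_geometry(lattice_state(g, 10))
  expect_equal(one$area, 100)
  expect_equal(one$perimeter, 40)
  expect_equal(one$length, 0)
  expect_equal(one$r, 1)

  g2 <- matrix(0L, 10, 10); g2[4:5, 4] <- 1L
  dom <- cell_geometry(lattice_state(g2, 10))
  expect_equal(dom$area, 200)
  expect_equal(dom$perimeter, 60)
  expect_equal(dom$length, 10)

  lat21 <- fixture_single_cell_lattice(c(20, 20), 10)
  d21 <- cell_geometry(lat21)
  expect_equal(d21$area, 2100)
  w <- which(lat21$grid == 1)
  ii <- (w - 1) %% 20 + 1; jj <- (w - 1) %/% 20 + 1
  expect_equal(d21$length, oracle_max_pairwise(ii, jj, 20, 20) * 10)
  # perimeter against direct edge enumeration
  edges <- 0
  for (k in seq_along(w)) {
    nb <- rbind(c(ii[k] %% 20 + 1, jj[k]), c((ii[k] - 2) %% 20 + 1, jj[k]),
                c(ii[k], jj[k] %% 20 + 1), c(ii[k], (jj[k] - 2) %% 20 + 1))
    edges <- edges + sum(lat21$grid[nb] != 1)
  }
  expect_equal(d21$perimeter, edges * 10)
  expect_error(cell_geometry(lat21, 5), "registry")
})

test_that("initialization stamps disjoint 21-site cells reproducibly", {
  set.seed(1)
  one <- initialize_cells(1, c(170, 170), 10)
  expect_equal(sum(one$lattice$grid == 1), 21)
  expect_equal(cell_geometry(one$lattice)$area, 2100)

  set.seed(2)
  full <- initialize_cells(400, c(170, 170), 10)
  expect_equal(sum(full$lattice$grid > 0), 8400)
  expect_equal(sort(unique(as.vector(full$lattice$grid))), 0:400)
  expect_true(all(tabulate(full$lattice$grid, 400) == 21))
  expect_true(all(full$phi == 0))

  set.seed(2)
  again <- initialize_cells(400, c(170, 170), 10)
  expect_identical(full$lattice$grid, again$lattice$grid)

  set.seed(3)
  expect_error(initialize_cells(40, c(20, 20), 10, max_tries = 2000),
               "density too high")
})

test_that("a Monte-Carlo step is an unbiased walk without haptotaxis", {
  pp <- potts_params(mu_h = 0)
  disp <- matrix(0, 60, 2)
  for (r in 1:60) {
    set.seed(100 + r)
    init <- initialize_cells(1, c(30, 30), 10)
    res <- monte_carlo_step(init$lattice, init$phi, NULL, pp, nsweeps = 15)
    c0 <- cell_geometry(init$lattice)[, c("cx", "cy")]
    d <- c(res$centroids[1, 1, 15] - c0$cx, res$centroids[1, 2, 15] - c0$cy)
    disp[r, ] <- (d + 150) %% 300 - 150
  }
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_lt(abs(mean(disp[, 1])), 4 * se[1] + 1e-9)
  expect_lt(abs(mean(disp[, 2])), 4 * se[2] + 1e-9)
})

test_that("haptotaxis drives net displacement up the bound-VEGF gradient", {
  pp <- potts_params()  # mu_h at the typical value
  b <- fixture_gradient_field(c(40, 40), slope = 2e-15, axis = 1)
  drift <- numeric(40)
  for (r in 1:40) {
    set.seed(200 + r)
    init <- initialize_cells(1, c(40, 40), 10)
    res <- monte_carlo_step(init$lattice, init$phi, b, pp, nsweeps = 10)
    c0 <- cell_geometry(init$lattice)$cx
    drift[r] <- (res$centroids[1, 1, 10] - c0 + 200) %% 400 - 200
  }
  expect_gt(mean(drift), 0)
  expect_gt(mean(drift) / (sd(drift) / sqrt(length(drift))), 2)
})

test_that("infinitely unfavorable proposals leave the state unchanged", {
  # target area pinned at the initial 2100 um^2 with a huge restraint: every
  # copy changes some cell's area, so every proposal carries an enormous
  # energy penalty and is rejected
  pp <- potts_params(a0 = 2100, lambda_a = 1e8)
  set.seed(7)
  init <- initialize_cells(2, c(20, 20), 10)
  res <- monte_carlo_step(init$lattice, init$phi, NULL, pp, nsweeps = 3)
  expect_identical(res$lattice$grid, init$lattice$grid)
})

test_that("morphology switching follows mu_m * c * r and is irreversible", {
  pp <- potts_params()
  # c = 0: no switch ever
  lat <- fixture_single_cell_lattice(c(20, 20), 10)
  set.seed(5)
  phi <- morphology_update(lat, 0L, matrix(0, 20, 20), pp)
  expect_identical(phi, 0L)
  # typical values: per-MCS probability mu_m * c0 * r = 2.6e-3 at r = 1
  cf <- matrix(2e-11, 20, 20)
  set.seed(6)
  hits <- sum(vapply(1:20000, function(k) morphology_update(lat, 0L, cf, pp), 0L))
  p <- 1.3e8 * 2e-11 * 1
  expect_lt(abs(hits / 20000 - p), 4 * sqrt(p * (1 - p) / 20000))
  # a cell fully surrounded by another cell cannot elongate (r = 0)
  g <- matrix(2L, 6, 6); g[3, 3] <- 1L
  g[g == 2L & row(g) > 4] <- 0L  # keep cell 2 connected but not everywhere
  g[, 5:6] <- 0L; g[5:6, ] <- 0L
  lat2 <- lattice_state(g, 10)
  set.seed(8)
  for (k in 1:50) {
    phi2 <- morphology_update(lat2, c(0L, 0L), matrix(1e-3, 6, 6), pp)
    expect_identical(phi2[1], 0L)
  }
  # phi never decreases
  set.seed(9)
  phi3 <- 1L
  expect_identical(morphology_update(lat, phi3, cf, pp), 1L)
})

test_that("cells are conserved and phi is monotone across a short run", {
  cfg <- sim_config(grid = c(60, 60), n_cells = 50, duration = 30, seed = 12,
                    snapshot_every = 10)
  traj <- run_simulation(cfg)
  last <- traj$snapshots[[length(traj$snapshots)]]
  counts <- tabulate(last$grid, 50)
  expect_true(all(counts > 0))                    # no cell death
  expect_equal(sort(unique(as.vector(last$grid))), 0:50)
  dphi <- apply(traj$phi_history, 1, diff)
  expect_true(all(dphi >= 0))                     # irreversible switch
})

test_that("displacement directions are symmetric with both couplings off", {
  cfg <- sim_config(grid = c(50, 50), n_cells = 25, duration = 60, seed = 21,
                    morphology_on = FALSE, haptotaxis_on = FALSE,
                    snapshot_every = 60)
  traj <- run_simulation(cfg)
  L <- 500
  steps <- NULL
  for (s in 1:25) {
    px <- traj$centroids[s, 1, ]; py <- traj$centroids[s, 2, ]
    dxs <- (diff(px) + L / 2) %% L - L / 2
    dys <- (diff(py) + L / 2) %% L - L / 2
    steps <- rbind(steps, cbind(dxs, dys))
  }
  steps <- steps[steps[, 1] != 0 | steps[, 2] != 0, ]
  ang <- atan2(steps[, 2], steps[, 1]) %% (2 * pi)
  counts <- tabulate(pmin(floor(ang / (pi / 6)) + 1, 12), 12)
  chi2 <- sum((counts - sum(counts) / 12)^2 / (sum(counts) / 12))
  expect_lt(chi2, qchisq(0.99, df = 11))
})
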