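test_that("dip statistic reproduces hand-derived exact values", {
  # equal two-point mixture: dip = 1/4
  expect_equal(dip_statistic(c(0, 0, 1, 1)), 0.25, tolerance = 1e-8)
  expect_equal(dip_statistic(c(0, 1)), 0.25, tolerance = 1e-8)
  # unequal two-point mixture with weights (p, 1-p): dip = min(p, 1-p)/2
  expect_equal(dip_statistic(c(0, 0, 0, 1)), 0.125, tolerance = 1e-8)
  expect_equal(dip_statistic(c(rep(0, 9), 1)), 0.05, tolerance = 1e-8)
  # k equally weighted atoms: dip = 1/(2k)
  expect_equal(dip_statistic(c(0, 1, 2)), 1 / 6, tolerance = 1e-8)
  expect_equal(dip_statistic(0:3), 1 / 8, tolerance = 1e-8)
  expect_equal(dip_statistic(rep(0:3, each = 5)), 1 / 8, tolerance = 1e-8)
  # a point mass is unimodal: dip 0
  expect_equal(dip_statistic(rep(2, 60)), 0)
  # invariance under affine transformation
  x <- c(0, 0, 1, 1, 1, 4, 4)
  expect_equal(dip_statistic(x), dip_statistic(3 * x - 7), tolerance = 1e-8)
  # merging two modes into one removes the dip
  expect_lt(dip_statistic(rep(1, 8)), dip_statistic(rep(c(0, 1), 4)))
})

test_that("bimodal samples score a larger dip than unimodal ones", {
  unimodal <- rep(c(5, 6, 7), c(10, 40, 10))
  bimodal <- rep(c(1, 6, 12), c(25, 10, 25))
  expect_gt(dip_statistic(bimodal), 2 * dip_statistic(unimodal))
})

test_that("trivially directional windows classify as expected", {
  # all 60 steps in a single direction bin
  steps <- cbind(rep(2, 60), rep(0.1, 60))
  expect_equal(classify_modality(steps)[1], "one-direction")
  # asymmetric opposed movement (38 vs 22 steps): head-and-tail
  ht <- rbind(cbind(rep(2, 38), rep(0.1, 38)), cbind(rep(-2, 22), rep(-0.1, 22)))
  expect_equal(classify_modality(ht)[1], "head-and-tail")
  # under the concentration-sensitive chi-square screen even the perfectly
  # balanced 30/30 opposed sample is head-and-tail; under the resultant-
  # length screen its zero resultant makes it isotropic by construction
  ht50 <- rbind(cbind(rep(2, 30), rep(0.1, 30)), cbind(rep(-2, 30), rep(-0.1, 30)))
  expect_equal(classify_modality(ht50, uniformity = "chisq")[1], "head-and-tail")
  expect_equal(classify_modality(ht50)[1], "isotropic")
  # too few nonzero steps: isotropic by convention, flagged
  few <- rbind(cbind(rep(1, 5), 0), matrix(0, 55, 2))
  lab <- classify_modality(few)
  expect_equal(lab[1], "isotropic")
  expect_true(attr(lab, "flagged"))
})

test_that("fixture trajectories of each modality are recovered", {
  for (s in 1:5) {
    one <- fixture_trajectory("one-direction", theta0 = s, seed = s)
    expect_equal(classify_modality(one)[1], "one-direction")
    ht <- fixture_trajectory("head-and-tail", theta0 = s / 2, seed = s)
    expect_equal(classify_modality(ht)[1], "head-and-tail")
  }
})

test_that("uniform direction samples are labelled non-isotropic at rate ~alpha1", {
  set.seed(77)
  n_rep <- 400
  labs <- vapply(seq_len(n_rep), function(k) {
    ang <- runif(60, 0, 2 * pi)
    classify_modality(cbind(cos(ang), sin(ang)))[1]
  }, "")
  frac <- mean(labs != "isotropic")
  # binomial CI around the nominal 0.1 (discreteness of the MC null makes the
  # realized level slightly conservative)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.16)
})

test_that("modality census tabulates one label per cell-window", {
  cfg <- sim_config(grid = c(40, 40), n_cells = 12, duration = 120, seed = 55,
                    snapshot_every = 120)
  traj <- run_simulation(cfg)
  cen <- modality_census(traj$centroids, cfg)
  expect_equal(nrow(cen), 2)  # 120 MCS = two 2-hour windows
  expect_equal(cen$t_end_mcs, c(60, 120))
  expect_true(all(cen$isotropic + cen$one_direction + cen$head_and_tail == 12))
})
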