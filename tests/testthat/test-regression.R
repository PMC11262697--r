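test_that("saturating-exponential coefficients are recovered from noiseless data", {
  d <- fixture_regression_dataset("saturating_exp",
                                  list(a = 148, b = 143, c = 8.32e-9))
  fit <- fit_regressions(d, "saturating_exp")
  expect_equal(unname(fit$coefficients["a"]), 148, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["b"]), 143, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["c"]), 8.32e-9, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("linear fit is exact on two points", {
  d <- data.frame(x = c(1e9, 3e9), y = c(32.5 + 1.12e-8 * 1e9, 32.5 + 1.12e-8 * 3e9))
  fit <- fit_regressions(d, "linear")
  expect_equal(unname(fit$coefficients["a1"]), 32.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["b1"]), 1.12e-8, tolerance = 1e-8)
})

test_that("logistic coefficients are recovered from noiseless data", {
  truth <- list(a3 = 36.6, b3 = 64.0, c3 = 7.72e-3, d3 = 1.1)
  d <- fixture_regression_dataset("logistic", truth,
                                  x = seq(25, 1200, length.out = 16))
  fit <- fit_regressions(d, "logistic")
  for (nm in names(truth)) {
    expect_equal(unname(fit$coefficients[nm]), truth[[nm]], tolerance = 1e-3)
  }
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("binding-site saturating form is recovered (second exponential use)", {
  truth <- list(a = 129.8, b = 57.4, c = 1.31e5)
  d <- fixture_regression_dataset("saturating_exp", truth,
                                  x = c(1, 2, 4, 8, 16, 32) * 2.5e-6)
  fit <- fit_saturating_exp(d$x, d$y)
  expect_equal(unname(fit$coefficients["a"]), truth$a, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["b"]), truth$b, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["c"]), truth$c, tolerance = 1e-4)
})

test_that("two-factor junction-time model reproduces noiseless data with r2 = 1", {
  co <- list(A = 192, B = 1.03e-10, C = 5.60e-15, D = 9.60e9, E = 7.20e-10,
             F = 1.64e-5, G = 0.777, H = 0.489, I = 1.707, J = 0.593)
  typ <- list(mu_m = 1.3e8, mu_h = 1.5e14, c0 = 2e-11, kr = 8.6e5 / 3.6e-3)
  design <- NULL
  for (p in names(typ)) {
    for (m in c(0.5, 1, 2, 4)) {
      row <- typ; row[[p]] <- typ[[p]] * m
      for (t_h in c(4, 8, 12, 16, 20, 24)) {
        design <- rbind(design, data.frame(row, t = t_h * 3600))
      }
    }
  }
  d <- fixture_regression_dataset("junction_time", co, x = design)
  fit <- fit_regressions(d, "junction_time")
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(unname(fit$fitted), d$junctions, tolerance = 1e-3)
})

test_that("condition comparison flags separated groups and not identical ones", {
  mk <- function(vals) data.frame(time_mcs = 720, metric = "junctions",
                                  value = vals)
  same <- compare_conditions(list(ref = mk(c(100, 101, 99)),
                                  other = mk(c(100, 101, 99))), "ref")
  expect_true(all(same$stars == "ns"))
  # groups offset by ~10 SD
  far <- compare_conditions(list(ref = mk(c(100, 101, 99)),
                                 other = mk(c(120, 121, 119))), "ref")
  expect_true(all(far$p_value < 0.01))
  expect_true(all(far$stars == "**"))
  # degenerate: zero variance in both groups
  deg <- compare_conditions(list(ref = mk(c(5, 5, 5)),
                                 other = mk(c(5, 5, 5))), "ref")
  expect_true(all(deg$degenerate))
  expect_true(all(deg$p_value == 1))
})
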