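# Deterministic toy-input generators so every pipeline stage is testable
# without running the full coupled model.

#' Generate a deterministic test fixture
#'
#' @param kind one of `"single_cell_lattice"`, `"random_lattice"`,
#'   `"gradient_field"`, `"uniform_gel"`, `"bar_mask"`, `"plus_mask"`,
#'   `"ring_mask"`, `"trajectory"`, `"regression_dataset"`.
#' @param ... kind-specific arguments, see the individual generators.
#' @param seed RNG seed for the stochastic kinds; the same arguments and seed
#'   regenerate bit-identical output.
#' @return the typed object for the target module.
#' @export
make_fixture <- function(kind, ..., seed = 1) {
  switch(kind,
         single_cell_lattice = fixture_single_cell_lattice(...),
         random_lattice = fixture_random_lattice(..., seed = seed),
         gradient_field = fixture_gradient_field(...),
         uniform_gel = fixture_uniform_gel(...),
         bar_mask = fixture_bar_mask(...),
         plus_mask = fixture_plus_mask(...),
         ring_mask = fixture_ring_mask(...),
         trajectory = fixture_trajectory(..., seed = seed),
         regression_dataset = fixture_regression_dataset(...),
         stop("unknown fixture kind: ", kind))
}

#' @rdname make_fixture
#' @param shape lattice dimensions.
#' @param dx lattice spacing (um).
#' @export
fixture_single_cell_lattice <- function(shape = c(12, 12), dx = 10) {
  g <- matrix(0L, shape[1], shape[2])
  off <- .footprint_offsets()
  ci <- shape[1] %/% 2; cj <- shape[2] %/% 2
  g[cbind((ci - 1 + off[, 1]) %% shape[1] + 1,
          (cj - 1 + off[, 2]) %% shape[2] + 1)] <- 1L
  lattice_state(g, dx)
}

#' @rdname make_fixture
#' @param n_cells number of randomly placed square 2x2 cells.
#' @export
fixture_random_lattice <- function(shape = c(12, 12), n_cells = 3, dx = 10,
                                   seed = 1) {
  .with_local_seed(seed, function() {
    g <- matrix(0L, shape[1], shape[2])
    placed <- 0L
    while (placed < n_cells) {
      i <- sample.int(shape[1], 1); j <- sample.int(shape[2], 1)
      ii <- (i - 1 + 0:1) %% shape[1] + 1
      jj <- (j - 1 + 0:1) %% shape[2] + 1
      if (any(g[ii, jj] != 0)) next
      placed <- placed + 1L
      g[ii, jj] <- placed
    }
    lattice_state(g, dx)
  })
}

#' @rdname make_fixture
#' @param slope field increment per site along the gradient axis.
#' @param axis 1 for a gradient along rows, 2 along columns.
#' @export
fixture_gradient_field <- function(shape = c(12, 12), slope = 1e-14, axis = 1) {
  if (axis == 1) {
    matrix(rep(seq_len(shape[1]) * slope, shape[2]), shape[1], shape[2])
  } else {
    matrix(rep(seq_len(shape[2]) * slope, each = shape[1]), shape[1], shape[2])
  }
}

#' @rdname make_fixture
#' @param rho0 uniform density value.
#' @export
fixture_uniform_gel <- function(shape = c(32, 32), rho0 = 1e-5) {
  matrix(rho0, shape[1], shape[2])
}

#' @rdname make_fixture
#' @param length_sites bar length in sites (1 site wide).
#' @export
fixture_bar_mask <- function(shape = c(80, 80), length_sites = 50) {
  m <- matrix(0L, shape[1], shape[2])
  i0 <- (shape[1] - length_sites) %/% 2
  m[i0 + seq_len(length_sites), shape[2] %/% 2] <- 1L
  m
}

#' @rdname make_fixture
#' @param arm_sites arm length in sites of the plus sign (each of 4 arms).
#' @export
fixture_plus_mask <- function(shape = c(80, 80), arm_sites = 20) {
  m <- matrix(0L, shape[1], shape[2])
  ci <- shape[1] %/% 2; cj <- shape[2] %/% 2
  m[ci + (-arm_sites:arm_sites), cj] <- 1L
  m[ci, cj + (-arm_sites:arm_sites)] <- 1L
  m
}

#' @rdname make_fixture
#' @param radius_sites ring radius in sites.
#' @export
fixture_ring_mask <- function(shape = c(80, 80), radius_sites = 20) {
  ci <- shape[1] / 2; cj <- shape[2] / 2
  i <- matrix(seq_len(shape[1]), shape[1], shape[2])
  j <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  r <- sqrt((i - ci)^2 + (j - cj)^2)
  m <- (abs(r - radius_sites) <= 0.6) + 0L
  m
}

#' @rdname make_fixture
#' @param modality `"isotropic"`, `"one-direction"` or `"head-and-tail"`.
#' @param n_steps number of displacement vectors.
#' @param step_um step magnitude (um).
#' @param theta0 preferred direction (radians) for the directional kinds.
#' @param concentration for the directional kinds, the sd (radians) of the
#'   angular noise around the preferred direction(s).
#' @param head_fraction for `"head-and-tail"`, the fraction of steps along
#'   the primary direction (the rest go the opposite way). The default 0.65
#'   gives the slight asymmetry real head-and-tail movers show; a perfectly
#'   balanced 0.5 has zero resultant vector and is indistinguishable from
#'   isotropic under a uniformity-first screen.
#' @export
fixture_trajectory <- function(modality = "isotropic", n_steps = 60,
                               step_um = 2, theta0 = 0, concentration = 0.2,
                               head_fraction = 0.65, seed = 1) {
  .with_local_seed(seed, function() {
    ang <- switch(modality,
      isotropic = runif(n_steps, 0, 2 * pi),
      `one-direction` = theta0 + rnorm(n_steps, 0, concentration),
      `head-and-tail` = theta0 + rnorm(n_steps, 0, concentration) +
        pi * (runif(n_steps) > head_fraction),
      stop("unknown modality: ", modality))
    cbind(step_um * cos(ang), step_um * sin(ang))
  })
}

#' @rdname make_fixture
#' @param eq regression form, as in [fit_regressions()].
#' @param coefficients named coefficient list for the chosen form.
#' @param x predictor values at which to evaluate the noiseless curve.
#' @export
fixture_regression_dataset <- function(eq = "saturating_exp",
                                       coefficients = list(a = 148, b = 143,
                                                           c = 8.32e-9),
                                       x = NULL) {
  co <- coefficients
  switch(eq,
    saturating_exp = {
      if (is.null(x)) x <- seq(0.25, 4, by = 0.25) / co$c
      data.frame(x = x, y = co$a - co$b * exp(-co$c * x))
    },
    linear = {
      if (is.null(x)) x <- seq(1, 8)
      data.frame(x = x, y = co$a1 + co$b1 * x)
    },
    logistic = {
      if (is.null(x)) x <- seq(0.1, 3, length.out = 12) * co$d3 / co$c3
      data.frame(x = x, y = co$a3 + co$b3 / (1 + exp(-co$c3 * x + co$d3)))
    },
    junction_time = {
      if (is.null(x)) stop("junction_time fixtures need an explicit design; pass x as a data.frame")
      d <- x
      d$junctions <- co$A *
        (1 - exp(-co$B * d$mu_m - co$C * d$mu_h - co$D * d$c0 - co$E * d$kr)) *
        (1 - exp(-co$F * d$mu_m^co$G * d$mu_h^co$H * d$c0^co$I * d$kr^co$J * d$t))
      d
    },
    stop("unknown regression form: ", eq))
}
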