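#' Cellular Potts model parameters
#'
#' Interface energies, shape restraints and chemical coupling strengths for the
#' lattice model. Defaults are the calibrated typical values for HUVECs on
#' air-dried collagen.
#'
#' @param J11,J10,J01,J00 interface energies (a.e.u./um) for cell-cell,
#'   cell-medium, medium-cell and medium-medium lattice pairs. `J10` and `J01`
#'   must be equal (the pair energy is symmetric).
#' @param lambda_a area restraint (a.e.u./um^4).
#' @param lambda_p perimeter restraint (a.e.u./um).
#' @param lambda_l elongation restraint (a.e.u. um); enters as
#'   `lambda_l * phi / l` so it only acts on cells that have switched
#'   morphology, rewarding a larger head-to-tail length.
#' @param a0 target cell area (um^2); default is a 50-um round cell footprint.
#' @param mu_m morphology-change strength (um^3/ng) multiplying the soluble
#'   VEGF concentration in the per-step elongation probability.
#' @param mu_h haptotaxis strength (a.e.u. um^3/ng) multiplying the bound-VEGF
#'   difference between the target and source sites of a copy attempt.
#' @param neighbor_weight_order2 energy and proposal weight of the four
#'   second-order (diagonal) neighbours relative to the first-order ones.
#'   Default 1/2; set to `1/sqrt(2)` for the inverse-distance alternative.
#' @param connectivity if `TRUE` (default), a copy attempt that would split
#'   the retracting cell into disconnected pieces is rejected (local
#'   arc-counting constraint). The elongation restraint rewards a large
#'   head-to-tail length, which without this guard pays cells to shed
#'   fragments and let them drift apart; see the methods vignette.
#' @return a named list of class `potts_params`.
#' @export
potts_params <- function(J11 = 0.12, J10 = 0.06, J01 = 0.06, J00 = 0,
                         lambda_a = 1.0e-4, lambda_p = 1.0e-2, lambda_l = 5.0e3,
                         a0 = 1960, mu_m = 1.3e8, mu_h = 1.5e14,
                         neighbor_weight_order2 = 0.5, connectivity = TRUE) {
  if (J10 != J01) stop("interface energies must be symmetric: J10 == J01")
  stopifnot(lambda_a >= 0, lambda_p >= 0, lambda_l >= 0, a0 > 0,
            mu_m >= 0, mu_h >= 0, neighbor_weight_order2 > 0)
  structure(list(J11 = J11, J10 = J10, J01 = J01, J00 = J00,
                 lambda_a = lambda_a, lambda_p = lambda_p, lambda_l = lambda_l,
                 a0 = a0, mu_m = mu_m, mu_h = mu_h,
                 neighbor_weight_order2 = neighbor_weight_order2,
                 connectivity = isTRUE(connectivity)),
            class = "potts_params")
}

#' Biogel mechanical parameters
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio (dimensionless, must be < 0.5; the thickness
#'   relation divides by `1 - 2 nu`).
#' @param mu1,mu2 shear and bulk viscosities (Pa s).
#' @param beta1,beta2 long-range (fiber) elastic coefficients (um^2)
#'   multiplying the Laplacians of strain and dilatation.
#' @param kappa cell traction strength (Pa um^3/ng); traction stress is
#'   `kappa * rho` at cell-occupied sites.
#' @param rho0 initial gel density (ng/um^3).
#' @param h0 initial gel thickness (um).
#' @param h_min floor on the local thickness (um). The linearized
#'   thickness-density relation extrapolates to nonphysical values away from
#'   `rho0`; the dish-friction term divides by `h^2`, so `h` is clamped from
#'   below. Default one tenth of `h0`.
#' @return a named list of class `gel_params`.
#' @export
gel_params <- function(E = 2.0e4, nu = 0.48, mu1 = 7.4e5, mu2 = 1.0e7,
                       beta1 = 1.0e4, beta2 = 1.0e4, kappa = 4.0e9,
                       rho0 = 1.0e-5, h0 = 3.0e2, h_min = h0 / 10) {
  stopifnot(E > 0, nu > 0, nu < 0.5, mu1 >= 0, mu2 >= 0,
            beta1 >= 0, beta2 >= 0, kappa >= 0, rho0 > 0, h0 > 0, h_min > 0)
  structure(list(E = E, nu = nu, mu1 = mu1, mu2 = mu2, beta1 = beta1,
                 beta2 = beta2, kappa = kappa, rho0 = rho0, h0 = h0,
                 h_min = h_min),
            class = "gel_params")
}

#' VEGF transport parameters
#'
#' @param D_c diffusivity of soluble VEGF (um^2/s).
#' @param k_on,k_off binding and unbinding rates between VEGF and the gel
#'   binding sites (um^3/(ng s) and 1/s).
#' @param gamma mass ratio of VEGF binding sites (fibronectin) in the gel.
#' @param c0 initial soluble VEGF concentration (ng/um^3).
#' @param mw_ratio molecular-weight ratio of fibronectin to VEGF, converting
#'   bound VEGF mass into occupied binding-site mass. Default 440/45
#'   (standard molecular weights in kDa).
#' @return a named list of class `vegf_params`.
#' @export
vegf_params <- function(D_c = 5.9e1, k_on = 8.6e5, k_off = 3.6e-3,
                        gamma = 5.0e-6, c0 = 2.0e-11, mw_ratio = 440 / 45) {
  stopifnot(D_c > 0, k_on > 0, k_off > 0, gamma > 0, c0 >= 0, mw_ratio > 0)
  structure(list(D_c = D_c, k_on = k_on, k_off = k_off, gamma = gamma,
                 c0 = c0, mw_ratio = mw_ratio),
            class = "vegf_params")
}

#' Simulation configuration
#'
#' Bundles the lattice geometry, schedule, toggles and the three parameter
#' groups into a single validated configuration.
#'
#' @param grid lattice dimensions (sites), default `c(170, 170)`.
#' @param dx lattice spacing (um).
#' @param mcs_minutes simulated minutes per Monte-Carlo step.
#' @param n_cells number of cells seeded at t = 0.
#' @param duration run length in Monte-Carlo steps (720 MCS = 24 h).
#' @param seed RNG seed for the run.
#' @param morphology_on,haptotaxis_on factorial toggles. Off is implemented as
#'   `mu_m = 0` / `mu_h = 0` respectively.
#' @param snapshot_every snapshot cadence in MCS (default 30 MCS = 1 h).
#' @param potts,gel,vegf parameter groups; see [potts_params()],
#'   [gel_params()], [vegf_params()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(grid = c(170, 170), dx = 10, mcs_minutes = 2,
                       n_cells = 400, duration = 720, seed = 1,
                       morphology_on = TRUE, haptotaxis_on = TRUE,
                       snapshot_every = 30,
                       potts = potts_params(), gel = gel_params(),
                       vegf = vegf_params()) {
  stopifnot(length(grid) == 2, grid >= 4, dx > 0, mcs_minutes > 0,
            n_cells >= 0, duration >= 0, snapshot_every >= 1)
  stopifnot(inherits(potts, "potts_params"), inherits(gel, "gel_params"),
            inherits(vegf, "vegf_params"))
  structure(list(grid = as.integer(grid), dx = dx, mcs_minutes = mcs_minutes,
                 n_cells = as.integer(n_cells), duration = as.integer(duration),
                 seed = as.integer(seed), morphology_on = isTRUE(morphology_on),
                 haptotaxis_on = isTRUE(haptotaxis_on),
                 snapshot_every = as.integer(snapshot_every),
                 potts = potts, gel = gel, vegf = vegf),
            class = "sim_config")
}

#' Convert between Monte-Carlo steps and simulated hours
#'
#' One MCS is `mcs_minutes` simulated minutes (default 2, so 540 MCS = 18 h
#' and a 2-hour migration window = 60 MCS).
#'
#' @param mcs,hours value to convert.
#' @param mcs_minutes minutes per MCS.
#' @return the converted value.
#' @export
mcs_to_hours <- function(mcs, mcs_minutes = 2) mcs * mcs_minutes / 60

#' @rdname mcs_to_hours
#' @export
hours_to_mcs <- function(hours, mcs_minutes = 2) {
  m <- hours * 60 / mcs_minutes
  if (any(abs(m - round(m)) > 1e-9)) stop("duration is not a whole number of MCS")
  as.integer(round(m))
}

# flatten a sim_config to key=value pairs (Table-1 style symbol names)
.config_flat_map <- c(
  J11 = "potts.J11", J10 = "potts.J10", J01 = "potts.J01", J00 = "potts.J00",
  lambda_a = "potts.lambda_a", lambda_p = "potts.lambda_p",
  lambda_l = "potts.lambda_l", a0 = "potts.a0", mu_m = "potts.mu_m",
  mu_h = "potts.mu_h", neighbor_weight_order2 = "potts.neighbor_weight_order2",
  E = "gel.E", nu = "gel.nu", mu1 = "gel.mu1", mu2 = "gel.mu2",
  beta1 = "gel.beta1", beta2 = "gel.beta2", kappa = "gel.kappa",
  rho0 = "gel.rho0", h0 = "gel.h0", h_min = "gel.h_min",
  D_c = "vegf.D_c", k_on = "vegf.k_on", k_off = "vegf.k_off",
  gamma = "vegf.gamma", c0 = "vegf.c0", mw_ratio = "vegf.mw_ratio")

#' Read or write a flat key-value configuration file
#'
#' The file format is one `key = value` pair per line with `#` comments.
#' Parameter keys use the model symbol names (`J11`, `lambda_a`, `mu_h`,
#' `kappa`, ...); schedule keys are `nx`, `ny`, `dx`, `mcs_minutes`,
#' `n_cells`, `duration`, `seed`, `morphology_on`, `haptotaxis_on`,
#' `snapshot_every`.
#'
#' @param path file path.
#' @param config a [sim_config()] object (for writing).
#' @return `read_config` returns a `sim_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  named <- setNames(as.list(vals), keys)
  cfg <- sim_config()
  num <- function(key, default) if (key %in% keys) as.numeric(named[[key]]) else default
  flag <- function(key, default) {
    if (key %in% keys) tolower(named[[key]]) %in% c("true", "1", "yes") else default
  }
  pot <- as.list(cfg$potts); gl <- as.list(cfg$gel); vg <- as.list(cfg$vegf)
  for (sym in names(.config_flat_map)) {
    if (!sym %in% keys) next
    dest <- strsplit(.config_flat_map[[sym]], ".", fixed = TRUE)[[1]]
    val <- as.numeric(named[[sym]])
    if (dest[1] == "potts") pot[[dest[2]]] <- val
    if (dest[1] == "gel") gl[[dest[2]]] <- val
    if (dest[1] == "vegf") vg[[dest[2]]] <- val
  }
  sim_config(grid = c(num("nx", cfg$grid[1]), num("ny", cfg$grid[2])),
             dx = num("dx", cfg$dx),
             mcs_minutes = num("mcs_minutes", cfg$mcs_minutes),
             n_cells = num("n_cells", cfg$n_cells),
             duration = num("duration", cfg$duration),
             seed = num("seed", cfg$seed),
             morphology_on = flag("morphology_on", cfg$morphology_on),
             haptotaxis_on = flag("haptotaxis_on", cfg$haptotaxis_on),
             snapshot_every = num("snapshot_every", cfg$snapshot_every),
             potts = do.call(potts_params, pot),
             gel = do.call(gel_params, gl),
             vegf = do.call(vegf_params, vg))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  groups <- list(potts = config$potts, gel = config$gel, vegf = config$vegf)
  lines <- c(sprintf("nx = %d", config$grid[1]),
             sprintf("ny = %d", config$grid[2]),
             sprintf("dx = %.17g", config$dx),
             sprintf("mcs_minutes = %.17g", config$mcs_minutes),
             sprintf("n_cells = %d", config$n_cells),
             sprintf("duration = %d", config$duration),
             sprintf("seed = %d", config$seed),
             sprintf("morphology_on = %s", tolower(config$morphology_on)),
             sprintf("haptotaxis_on = %s", tolower(config$haptotaxis_on)),
             sprintf("snapshot_every = %d", config$snapshot_every))
  for (sym in names(.config_flat_map)) {
    dest <- strsplit(.config_flat_map[[sym]], ".", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("%s = %.17g", sym, groups[[dest[1]]][[dest[2]]]))
  }
  writeLines(lines, path)
  invisible(path)
}

# fold toggles into effective parameter lists for the engine
.effective_potts <- function(config) {
  p <- config$potts
  if (!config$haptotaxis_on) p$mu_h <- 0
  if (!config$morphology_on) p$mu_m <- 0
  p
}

# parameter list handed to the C++ engine
.engine_par <- function(potts, dx) {
  list(J11 = potts$J11, J10 = potts$J10, J00 = potts$J00,
       lambda_a = potts$lambda_a, lambda_p = potts$lambda_p,
       lambda_l = potts$lambda_l, a0 = potts$a0, mu_h = potts$mu_h,
       dx = dx, neighbor_weight_order2 = potts$neighbor_weight_order2,
       connectivity = as.integer(isTRUE(potts$connectivity)))
}
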