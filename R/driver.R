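#' Run a coupled Cellular Potts / continuum simulation
#'
#' Advances the full hybrid model. Each Monte-Carlo step (2 simulated
#' minutes by default) performs, in order: the soluble-VEGF-driven morphology
#' switch, one Potts sweep with haptotaxis read from the current bound-VEGF
#' field, one implicit gel-mechanics step (displacement, density advection,
#' thickness), and one VEGF transport step. All randomness flows through R's
#' RNG seeded from `config$seed`, so runs are bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param progress print a line every 60 MCS.
#' @param swap_pde_order if `TRUE`, the VEGF step runs before the mechanics
#'   step inside each MCS (using the previous step's displacement rate for
#'   the bound-VEGF advection). The default order is mechanics first; the
#'   endpoint metrics are insensitive to the choice (see the vignette), and
#'   the switch exists to demonstrate that.
#' @return an object of class `vasc_trajectory`: a list with
#'   \describe{
#'     \item{config}{the configuration as run}
#'     \item{centroids}{array `n_cells x 2 x (duration + 1)` of per-MCS cell
#'       centroids (um), including the initial state}
#'     \item{phi_history}{matrix `n_cells x (duration + 1)` of morphology flags}
#'     \item{snapshots}{list of per-snapshot states (`time_mcs`, `grid`,
#'       `phi`, `rho`, `c`, `b`, `h`, `u`)}
#'     \item{ledger}{data.frame of conservation and solver diagnostics per
#'       snapshot}
#'   }
#' @export
run_simulation <- function(config = sim_config(), progress = FALSE,
                           swap_pde_order = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nx <- config$grid[1]; ny <- config$grid[2]; dx <- config$dx
  dt <- config$mcs_minutes * 60
  pot <- .effective_potts(config)
  gl <- config$gel; vg <- config$vegf
  init <- initialize_cells(config$n_cells, config$grid, dx)
  lattice <- init$lattice
  grid <- lattice$grid  # engine mutates this matrix in place
  phi <- init$phi
  n <- config$n_cells
  rho <- matrix(gl$rho0, nx, ny)
  u <- list(x = matrix(0, nx, ny), y = matrix(0, nx, ny))
  cfield <- matrix(vg$c0, nx, ny)
  bfield <- matrix(0, nx, ny)
  du_prev <- list(x = matrix(0, nx, ny), y = matrix(0, nx, ny))
  mass0 <- sum(rho); vegf0 <- sum(cfield) + sum(bfield)

  centroids <- array(NA_real_, dim = c(max(n, 1), 2, config$duration + 1))
  phi_hist <- matrix(0L, max(n, 1), config$duration + 1)
  if (n > 0) {
    st <- cpp_cell_stats(grid, n, dx, NULL)
    centroids[, , 1] <- cbind(st$cx, st$cy)
    phi_hist[, 1] <- phi
  }
  snapshots <- list()
  ledger <- NULL
  clipped_total <- 0; clamped_last <- 0; iter_last <- 0; resid_last <- 0

  strip <- function(m) array(as.vector(m), dim(m))
  take_snapshot <- function(t_mcs) {
    h <- thickness(rho, gl)
    snapshots[[length(snapshots) + 1]] <<- list(
      time_mcs = t_mcs, grid = grid + 0L, phi = phi, rho = strip(rho),
      c = cfield, b = bfield, h = strip(h), u = u)
    ledger <<- rbind(ledger, data.frame(
      time_mcs = t_mcs,
      mass_drift = (sum(rho) - mass0) / mass0,
      vegf_drift = (sum(cfield) + sum(bfield) - vegf0) / vegf0,
      clipped_mass = clipped_total,
      clamped_sites = clamped_last,
      solver_iterations = iter_last,
      solver_residual = resid_last,
      fragmented_cells = NA_integer_))
  }
  take_snapshot(0L)

  par_engine <- .engine_par(pot, dx)
  for (t in seq_len(config$duration)) {
    # 1. morphology switch driven by soluble VEGF
    if (n > 0) {
      phi <- morphology_update(lattice_state(grid, dx), phi, cfield, pot)
    }
    # 2. Potts sweep with haptotaxis bias from bound VEGF
    if (n > 0) {
      res <- cpp_mcs(grid, phi, bfield, par_engine, 1L)
      centroids[, , t + 1] <- cbind(res$cx[, 1], res$cy[, 1])
      phi_hist[, t + 1] <- phi
    }
    if (swap_pde_order) {
      # VEGF first, advected with the previous step's displacement rate
      vs <- step_vegf(cfield, bfield, rho, du_prev, dt, dx, vg)
      cfield <- vs$c; bfield <- vs$b
    }
    # 3. gel mechanics: displacement, density, thickness
    h <- thickness(rho, gl)
    clamped_last <- attr(h, "clamped")
    mech <- solve_displacement_step(u, rho, grid > 0L, dt, dx, gl, h = h)
    u <- mech$u
    du_prev <- mech$du_dt
    iter_last <- mech$iterations; resid_last <- mech$residual
    rho <- update_density(rho, mech$du_dt, dt, dx)
    clipped_total <- clipped_total + attr(rho, "clipped_mass")
    if (!swap_pde_order) {
      # 4. VEGF transport with the same displacement rate
      vs <- step_vegf(cfield, bfield, rho, mech$du_dt, dt, dx, vg)
      cfield <- vs$c; bfield <- vs$b
    }

    if (t %% config$snapshot_every == 0 || t == config$duration) take_snapshot(t)
    if (progress && t %% 60 == 0) {
      message(sprintf("MCS %d / %d (%.1f h): phi-fraction %.2f", t,
                      config$duration, mcs_to_hours(t, config$mcs_minutes),
                      mean(phi)))
    }
  }
  structure(list(config = config, centroids = centroids,
                 phi_history = phi_hist, snapshots = snapshots,
                 ledger = ledger),
            class = "vasc_trajectory")
}

#' @export
print.vasc_trajectory <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("vasc_trajectory: %d cells on %dx%d lattice, %d MCS (%.1f h), seed %d\n",
              cfg$n_cells, cfg$grid[1], cfg$grid[2], cfg$duration,
              mcs_to_hours(cfg$duration, cfg$mcs_minutes), cfg$seed))
  cat(sprintf("  morphology %s, haptotaxis %s, %d snapshots\n",
              if (cfg$morphology_on) "on" else "off",
              if (cfg$haptotaxis_on) "on" else "off", length(x$snapshots)))
  led <- x$ledger[nrow(x$ledger), ]
  cat(sprintf("  final drift: gel %.2e, VEGF %.2e; phi-fraction %.2f\n",
              led$mass_drift, led$vegf_drift,
              mean(x$snapshots[[length(x$snapshots)]]$phi)))
  invisible(x)
}

#' Network, shape and modality metrics along a trajectory
#'
#' @param traj a `vasc_trajectory`.
#' @param min_segment_um segment threshold for the network extraction (um).
#' @return a list with `network` (junctions/segments/total length per
#'   snapshot), `shape` (per-cell roundness and aspect ratio at the final
#'   snapshot), and `modality` (per-window modality census).
#' @export
analyze_trajectory <- function(traj, min_segment_um = 100) {
  dx <- traj$config$dx
  net <- do.call(rbind, lapply(traj$snapshots, function(sn) {
    m <- extract_network(sn$grid, dx, min_segment_um)
    data.frame(time_mcs = sn$time_mcs, junctions = m$junction_count,
               segments = m$segment_count, total_length = m$total_length)
  }))
  last <- traj$snapshots[[length(traj$snapshots)]]
  shape <- shape_table(last$grid, dx)
  shape$phi <- last$phi[shape$id]
  modality <- modality_census(traj$centroids, traj$config)
  list(network = net, shape = shape, modality = modality)
}

#' Parameter sweep with replicate seeds
#'
#' Runs the coupled model over `multipliers` times the typical value of one
#' parameter, with `replicates` seeds per value, and tabulates the endpoint
#' network metrics. Matches the single-factor sweep design: all other
#' parameters stay at their typical values.
#'
#' @param base_config a [sim_config()].
#' @param parameter symbol name of the swept parameter: one of `"mu_m"`,
#'   `"mu_h"`, `"c0"`, `"kon_koff"` (binding/unbinding ratio, scaling `k_on`
#'   up), `"kappa"`, `"gamma"`, `"h0"`.
#' @param multipliers numeric multipliers applied to the typical value.
#' @param replicates replicate seeds per multiplier (seeds
#'   `base_config$seed + 0:(replicates-1)`).
#' @param endpoint_only if `FALSE`, also return the junction count per
#'   snapshot time for each run.
#' @param min_segment_um network segment threshold (um).
#' @return a data.frame with one row per run: `parameter`, `multiplier`,
#'   `seed`, `junctions`, `segments`, `total_length` (endpoint values), plus
#'   a `"timecourse"` attribute when `endpoint_only = FALSE`.
#' @export
sweep_parameter <- function(base_config, parameter, multipliers, replicates = 3,
                            endpoint_only = TRUE, min_segment_um = 100) {
  if (length(multipliers) == 0) {
    return(data.frame(parameter = character(), multiplier = numeric(),
                      seed = integer(), junctions = integer(),
                      segments = integer(), total_length = numeric()))
  }
  rows <- NULL; tc <- NULL
  for (m in multipliers) {
    for (r in seq_len(replicates)) {
      cfg <- .scale_parameter(base_config, parameter, m)
      cfg$seed <- as.integer(base_config$seed + (r - 1))
      traj <- run_simulation(cfg)
      dx <- cfg$dx
      if (endpoint_only) {
        last <- traj$snapshots[[length(traj$snapshots)]]
        met <- extract_network(last$grid, dx, min_segment_um)
        rows <- rbind(rows, data.frame(parameter = parameter, multiplier = m,
                                       seed = cfg$seed,
                                       junctions = met$junction_count,
                                       segments = met$segment_count,
                                       total_length = met$total_length))
      } else {
        ana <- analyze_trajectory(traj, min_segment_um)
        last <- ana$network[nrow(ana$network), ]
        rows <- rbind(rows, data.frame(parameter = parameter, multiplier = m,
                                       seed = cfg$seed,
                                       junctions = last$junctions,
                                       segments = last$segments,
                                       total_length = last$total_length))
        tci <- ana$network
        tci$parameter <- parameter; tci$multiplier <- m; tci$seed <- cfg$seed
        tc <- rbind(tc, tci)
      }
    }
  }
  if (!endpoint_only) attr(rows, "timecourse") <- tc
  rows
}

# apply a multiplier to one Table-style parameter of a sim_config
.scale_parameter <- function(config, parameter, multiplier) {
  cfg <- config
  switch(parameter,
    mu_m = { cfg$potts$mu_m <- cfg$potts$mu_m * multiplier },
    mu_h = { cfg$potts$mu_h <- cfg$potts$mu_h * multiplier },
    c0 = { cfg$vegf$c0 <- cfg$vegf$c0 * multiplier },
    kon_koff = { cfg$vegf$k_on <- cfg$vegf$k_on * multiplier },
    k_on = { cfg$vegf$k_on <- cfg$vegf$k_on * multiplier },
    k_off = { cfg$vegf$k_off <- cfg$vegf$k_off * multiplier },
    kappa = { cfg$gel$kappa <- cfg$gel$kappa * multiplier },
    gamma = { cfg$vegf$gamma <- cfg$vegf$gamma * multiplier },
    h0 = {
      cfg$gel$h_min <- cfg$gel$h_min * multiplier
      cfg$gel$h0 <- cfg$gel$h0 * multiplier
    },
    stop("unknown sweep parameter: ", parameter))
  cfg
}

#' Summarize a sweep as mean and standard deviation per condition
#'
#' @param sweep_table output of [sweep_parameter()].
#' @return a data.frame with `multiplier`, `mean_junctions`, `sd_junctions`,
#'   `n`.
#' @export
summarize_sweep <- function(sweep_table) {
  sp <- split(sweep_table, sweep_table$multiplier)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(multiplier = d$multiplier[1],
               mean_junctions = mean(d$junctions),
               sd_junctions = if (nrow(d) > 1) sd(d$junctions) else 0,
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$multiplier), ]
}
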