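#' Lattice state for the Cellular Potts model
#'
#' Wraps an integer label grid (0 = medium, n >= 1 = n-th cell) with its
#' periodic geometry. The grid is stored column-major; site (i, j) is row i,
#' column j, with 1-based indices in R.
#'
#' @param grid integer matrix of cell indices.
#' @param dx lattice spacing (um).
#' @return a list of class `lattice_state` with elements `grid`, `nx`, `ny`,
#'   `dx`, `ncell`.
#' @export
lattice_state <- function(grid, dx = 10) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (any(grid < 0)) stop("cell indices must be non-negative")
  structure(list(grid = grid, nx = nrow(grid), ny = ncol(grid), dx = dx,
                 ncell = max(grid, 0L)),
            class = "lattice_state")
}

# the 21-site quasi-disk footprint: row widths 3/5/5/5/3 around the centre
.footprint_offsets <- function() {
  off <- NULL
  for (j in -2:2) {
    w <- if (abs(j) == 2) 1 else 2
    off <- rbind(off, cbind(seq(-w, w), j))
  }
  off
}

#' Seed round cells at random non-overlapping positions
#'
#' Each cell is stamped as the fixed 21-site quasi-disk footprint (2100 um^2
#' at 10 um spacing) at a uniformly random position, rejecting overlaps.
#' All cells start in the round state (`phi = 0`).
#'
#' @param n_cells number of cells to place.
#' @param lattice_shape `c(nx, ny)` site counts.
#' @param dx lattice spacing (um).
#' @param max_tries rejection-sampling budget; placement failure raises an
#'   error reporting that the requested density is too high.
#' @return a list with `lattice` (a [lattice_state()]) and `phi` (integer
#'   morphology flags, all zero).
#' @export
initialize_cells <- function(n_cells, lattice_shape = c(170, 170), dx = 10,
                             max_tries = 500 * max(n_cells, 1)) {
  nx <- lattice_shape[1]; ny <- lattice_shape[2]
  grid <- matrix(0L, nx, ny)
  off <- .footprint_offsets()
  placed <- 0L
  tries <- 0L
  while (placed < n_cells) {
    if (tries >= max_tries) {
      stop(sprintf("placed %d of %d cells in %d attempts: cell density too high",
                   placed, n_cells, tries))
    }
    tries <- tries + 1L
    ci <- sample.int(nx, 1); cj <- sample.int(ny, 1)
    ii <- ((ci - 1 + off[, 1]) %% nx) + 1
    jj <- ((cj - 1 + off[, 2]) %% ny) + 1
    idx <- cbind(ii, jj)
    if (any(grid[idx] != 0L)) next
    placed <- placed + 1L
    grid[idx] <- placed
  }
  list(lattice = lattice_state(grid, dx), phi = integer(n_cells))
}

#' Cell geometry on the periodic lattice
#'
#' Area is the site count times `dx^2`; perimeter counts first-order lattice
#' edges between the cell and anything that is not the same cell; the
#' head-to-tail length is the maximum pairwise distance between occupied site
#' centres under the periodic minimal image; `r` is the fraction of boundary
#' edges that face empty medium (the no-cell-contact ratio used by the
#' morphology switch); the centroid is the periodic (circular-mean) average
#' of site centres.
#'
#' @param lattice a [lattice_state()].
#' @param sigma cell index (omit for all cells).
#' @return a data.frame with columns `id`, `area`, `perimeter`, `length`,
#'   `r`, `cx`, `cy`.
#' @export
cell_geometry <- function(lattice, sigma = NULL) {
  st <- cpp_cell_stats(lattice$grid, lattice$ncell, lattice$dx, NULL)
  out <- data.frame(id = seq_len(lattice$ncell),
                    area = st$nsites * lattice$dx^2,
                    perimeter = st$edges * lattice$dx,
                    length = st$lmax,
                    r = ifelse(st$edges > 0, st$empty_edges / st$edges, NA_real_),
                    cx = st$cx, cy = st$cy)
  if (!is.null(sigma)) {
    if (any(sigma < 1 | sigma > lattice$ncell) || any(st$nsites[sigma] == 0)) {
      stop("cell index missing from the lattice: registry corrupted")
    }
    out <- out[sigma, , drop = FALSE]
  }
  out
}

#' System energy of a Cellular Potts configuration
#'
#' Sums the interface energy over first- and second-order neighbour pairs
#' (second order down-weighted, same-cell pairs excluded) and the per-cell
#' restraints for area, perimeter and, for elongated cells, head-to-tail
#' length.
#'
#' @param lattice a [lattice_state()].
#' @param phi integer morphology flags, one per cell.
#' @param params a [potts_params()].
#' @return energy in a.e.u.
#' @export
hamiltonian <- function(lattice, phi, params) {
  stopifnot(length(phi) == lattice$ncell)
  cpp_hamiltonian(lattice$grid, as.integer(phi), .engine_par(params, lattice$dx))
}

#' Energy change of a single copy attempt
#'
#' Proposes copying the state of site `x` onto the neighbouring site `xp` and
#' returns the resulting energy change, computed incrementally from the
#' locally affected interface pairs and the restraints of the (at most two)
#' affected cells. A move that would remove a cell's last site returns `Inf`
#' (the engine rejects it before any energy evaluation).
#'
#' @param lattice a [lattice_state()].
#' @param phi morphology flags.
#' @param params a [potts_params()].
#' @param x,xp source and target sites as `c(i, j)` 1-based indices.
#' @return energy change in a.e.u.
#' @export
delta_h <- function(lattice, phi, params, x, xp) {
  from <- (x[1] - 1) + lattice$nx * (x[2] - 1)
  to <- (xp[1] - 1) + lattice$nx * (xp[2] - 1)
  cpp_delta_h(lattice$grid, as.integer(phi), as.integer(from), as.integer(to),
              .engine_par(params, lattice$dx))
}

#' Haptotaxis-biased energy change
#'
#' Subtracts the bound-VEGF bias `mu_h * (b(xp) - b(x))` from the energy
#' change of a copy attempt. The bias applies only when the two sites differ
#' in occupancy state (cell vs medium), which switches haptotaxis off between
#' two cell-occupied sites (contact inhibition) and between two empty sites.
#'
#' @param dh unbiased energy change (a.e.u.).
#' @param b_field bound-VEGF concentration field (ng/um^3) on the same grid.
#' @param lattice a [lattice_state()].
#' @param params a [potts_params()].
#' @param x,xp source and target sites as `c(i, j)` indices.
#' @return biased energy change in a.e.u.
#' @export
haptotaxis_bias <- function(dh, b_field, lattice, params, x, xp) {
  tau_x <- lattice$grid[x[1], x[2]] > 0
  tau_xp <- lattice$grid[xp[1], xp[2]] > 0
  if (tau_x == tau_xp) return(dh)
  dh - params$mu_h * (b_field[xp[1], xp[2]] - b_field[x[1], x[2]])
}

#' Metropolis acceptance probability
#'
#' `p = 1` for non-positive energy changes and `exp(-dhm)` otherwise (unit
#' temperature, no fluctuation parameter).
#'
#' @param dhm (biased) energy change in a.e.u.; vectorized.
#' @return acceptance probability in `[0, 1]`.
#' @export
acceptance_probability <- function(dhm) {
  ifelse(dhm <= 0, 1, exp(-dhm))
}

#' One Monte-Carlo step of the Cellular Potts dynamics
#'
#' Performs `nx * ny` copy attempts: a source site is picked uniformly, a
#' target among its first/second-order neighbours (second order down-weighted
#' by the configured factor), and the copy is accepted with the Metropolis
#' probability of the haptotaxis-biased energy change. Uses R's RNG stream,
#' so runs are reproducible under `set.seed()`.
#'
#' @param lattice a [lattice_state()].
#' @param phi morphology flags.
#' @param b_field bound-VEGF field for the haptotaxis bias (a zero matrix
#'   disables it).
#' @param params a [potts_params()].
#' @param nsweeps number of Monte-Carlo steps to perform.
#' @return a list with the updated `lattice`, per-sweep cell `centroids`
#'   (array `ncell x 2 x nsweeps`, um) and `accepted` counts.
#' @export
monte_carlo_step <- function(lattice, phi, b_field = NULL, params = potts_params(),
                             nsweeps = 1) {
  grid <- lattice$grid + 0L  # private copy; the engine flips sites in place
  if (is.null(b_field)) b_field <- matrix(0, lattice$nx, lattice$ny)
  res <- cpp_mcs(grid, as.integer(phi), b_field,
                 .engine_par(params, lattice$dx), as.integer(nsweeps))
  cent <- array(c(res$cx, res$cy), dim = c(lattice$ncell, nsweeps, 2))
  cent <- aperm(cent, c(1, 3, 2))
  list(lattice = lattice_state(grid, lattice$dx), centroids = cent,
       accepted = res$accepted)
}

#' Morphology switching driven by soluble VEGF
#'
#' Each round cell (`phi = 0`) switches irreversibly to the elongated state
#' with per-MCS probability `min(1, mu_m * c_sigma * r_sigma)`, where
#' `c_sigma` is the soluble VEGF concentration averaged over the cell's sites
#' and `r_sigma` the fraction of its boundary not contacting other cells. A
#' cell fully surrounded by other cells (`r` of zero) cannot elongate.
#'
#' @param lattice a [lattice_state()].
#' @param phi current morphology flags.
#' @param c_field soluble VEGF field (ng/um^3).
#' @param params a [potts_params()].
#' @return updated integer `phi` vector.
#' @export
morphology_update <- function(lattice, phi, c_field, params) {
  st <- cpp_cell_stats(lattice$grid, lattice$ncell, lattice$dx, c_field)
  if (any(st$nsites > 0 & st$edges == 0)) {
    stop("internal error: live cell with zero perimeter")
  }
  cbar <- ifelse(st$nsites > 0, st$field_sum / st$nsites, 0)
  r <- ifelse(st$edges > 0, st$empty_edges / st$edges, 0)
  p <- pmin(1, pmax(0, params$mu_m * cbar * r))
  draws <- runif(lattice$ncell)
  switch_now <- phi == 0L & draws < p
  phi[switch_now] <- 1L
  as.integer(phi)
}

# count fragmented cells (diagnostic): cells whose sites form more than one
# 8-connected component under periodic wrapping (8-connectivity matches the
# engine's retraction guard)
.count_fragmented <- function(grid) {
  nx <- nrow(grid); ny <- ncol(grid)
  ncell <- max(grid, 0L)
  if (ncell == 0) return(0L)
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  frag <- 0L
  for (s in seq_len(ncell)) {
    w <- which(grid == s)
    if (length(w) <= 1) next
    idx <- integer(nx * ny); idx[w] <- seq_along(w)
    i <- (w - 1) %% nx; j <- (w - 1) %/% nx
    seen <- logical(length(w))
    stack <- 1L; seen[1] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      ni <- (i[p] + off$di) %% nx; nj <- (j[p] + off$dj) %% ny
      q <- idx[ni + nx * nj + 1L]
      q <- q[q > 0 & !seen[q]]
      if (length(q)) { seen[q] <- TRUE; stack <- c(stack, q) }
    }
    if (!all(seen)) frag <- frag + 1L
  }
  frag
}
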