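# Continuum biogel mechanics on the periodic grid.
#
# The quasi-static force balance
#   div(sigma_cell + sigma_vis + sigma_ela,linear + sigma_ela,long-range) = R_ext
# is advanced in time with a backward-difference (implicit) treatment of the
# rate terms. Spatial operators are second-order central differences; the
# fourth-order long-range terms are nested Laplacians. The resulting linear
# system is solved spectrally: the constant-coefficient part (all stresses
# plus the friction at the mean 1/h^2) is diagonal per Fourier mode as a 2x2
# block and serves as preconditioner; the deviation of the dish friction from
# its mean (the only spatially varying coefficient) is handled by BiCGSTAB.

.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) Re(stats::fft(m, inverse = TRUE)) / length(m)

# periodic shifts along rows (i) and columns (j)
.shift_ip <- function(m) m[c(2:nrow(m), 1), , drop = FALSE]
.shift_im <- function(m) m[c(nrow(m), 1:(nrow(m) - 1)), , drop = FALSE]
.shift_jp <- function(m) m[, c(2:ncol(m), 1), drop = FALSE]
.shift_jm <- function(m) m[, c(ncol(m), 1:(ncol(m) - 1)), drop = FALSE]

# central first differences and 5-point Laplacian
.ddx <- function(m, dx) (.shift_ip(m) - .shift_im(m)) / (2 * dx)
.ddy <- function(m, dx) (.shift_jp(m) - .shift_jm(m)) / (2 * dx)
.lap <- function(m, dx) {
  (.shift_ip(m) + .shift_im(m) + .shift_jp(m) + .shift_jm(m) - 4 * m) / dx^2
}

#' Cell traction stress field
#'
#' Isotropic stress `kappa * rho` at cell-occupied sites, zero elsewhere.
#'
#' @param cell_mask logical or 0/1 matrix of cell occupancy (the tau image
#'   derived from the Potts grid).
#' @param rho gel density field (ng/um^3).
#' @param kappa traction strength (Pa um^3/ng).
#' @return the scalar stress magnitude field (Pa); the tensor is this value
#'   times the identity.
#' @export
traction_field <- function(cell_mask, rho, kappa) {
  kappa * rho * (cell_mask > 0)
}

#' Gel thickness from local density
#'
#' Linearized volume-conservation relation
#' `h = h0 * ((1 - 3 nu)/(1 - 2 nu) + nu/(1 - 2 nu) * rho/rho0)`, whose
#' grouping is fixed by the consistency condition `h(rho0) = h0`. The result
#' is floored at `h_min` because the relation is a linearization around
#' `rho0` and the dish-friction term divides by `h^2`; the number of clamped
#' sites is attached as attribute `clamped`.
#'
#' @param rho density field (ng/um^3).
#' @param params a [gel_params()].
#' @return thickness field (um) with attribute `clamped`.
#' @export
thickness <- function(rho, params) {
  nu <- params$nu
  h <- params$h0 * ((1 - 3 * nu) / (1 - 2 * nu) +
                    nu / (1 - 2 * nu) * rho / params$rho0)
  clamped <- sum(h < params$h_min)
  h <- pmax(h, params$h_min)
  attr(h, "clamped") <- clamped
  h
}

.mech_cache <- new.env(parent = emptyenv())

# Fourier symbols of the discrete operators for an nx x ny grid
.mech_symbols <- function(nx, ny, dx) {
  key <- sprintf("sym_%d_%d_%.8g", nx, ny, dx)
  if (!is.null(.mech_cache[[key]])) return(.mech_cache[[key]])
  tx <- 2 * pi * (seq_len(nx) - 1) / nx
  ty <- 2 * pi * (seq_len(ny) - 1) / ny
  s1 <- matrix(sin(tx) / dx, nx, ny)
  s2 <- matrix(rep(sin(ty) / dx, each = nx), nx, ny)
  q1 <- matrix((2 - 2 * cos(tx)) / dx^2, nx, ny)
  q2 <- matrix(rep((2 - 2 * cos(ty)) / dx^2, each = nx), nx, ny)
  out <- list(s1 = s1, s2 = s2, Q = q1 + q2)
  .mech_cache[[key]] <- out
  out
}

# 2x2 symbol blocks of the implicit operator with friction coefficient cbar;
# the operator is written in negated (positive-definite) form, see vignette.
# Plans are cached; a cached plan is reused while the mean friction stays
# within 5% (the difference is absorbed by the varying-coefficient part).
.mech_plan_cached <- function(nx, ny, dx, params, dt, cbar) {
  key <- sprintf("plan_%d_%d_%.8g_%.8g_%s", nx, ny, dx, dt,
                 paste(sprintf("%.8g", unlist(params)), collapse = "_"))
  pl <- .mech_cache[[key]]
  if (!is.null(pl) && abs(pl$cbar - cbar) <= 0.05 * pl$cbar) return(pl)
  pl <- .mech_plan(nx, ny, dx, params, dt, cbar)
  .mech_cache[[key]] <- pl
  pl
}

.mech_plan <- function(nx, ny, dx, params, dt, cbar) {
  sy <- .mech_symbols(nx, ny, dx)
  Ep <- params$E / (1 + params$nu)
  nup <- params$nu / (1 - 2 * params$nu)
  b1 <- params$mu1 / (2 * dt) + Ep / 2 + Ep * params$beta1 * sy$Q / 2
  b2 <- params$mu2 / dt + Ep * nup + Ep * nup * params$beta2 * sy$Q
  cc <- cbar * (Ep * (1 + params$beta1 * sy$Q) + params$mu1 / dt)
  B11 <- b1 * (sy$Q + sy$s1^2) + b2 * sy$s1^2 + cc
  B12 <- (b1 + b2) * sy$s1 * sy$s2
  B22 <- b1 * (sy$Q + sy$s2^2) + b2 * sy$s2^2 + cc
  det <- B11 * B22 - B12^2
  # viscous-only symbol (for the explicit part of the rate terms)
  v1 <- params$mu1 / (2 * dt)
  v2 <- params$mu2 / dt
  V11 <- v1 * (sy$Q + sy$s1^2) + v2 * sy$s1^2
  V12 <- (v1 + v2) * sy$s1 * sy$s2
  V22 <- v1 * (sy$Q + sy$s2^2) + v2 * sy$s2^2
  list(B11 = B11, B12 = B12, B22 = B22,
       I11 = B22 / det, I12 = -B12 / det, I22 = B11 / det,
       V11 = V11, V12 = V12, V22 = V22,
       Ep = Ep, cbar = cbar, dt = dt, dx = dx, params = params)
}

# Apply a 2x2 symbol block to a vector field via FFT. The two real
# components are packed into one complex transform (the symbols are even in
# k, so each component's spectrum is recovered by Hermitian splitting).
.sym_apply <- function(S11, S12, S22, ux, uy) {
  F <- stats::fft(ux + 1i * uy)
  Fr <- Conj(F[c(1, rev(seq_len(nrow(F))[-1])), c(1, rev(seq_len(ncol(F))[-1])),
               drop = FALSE])
  fx <- (F + Fr) / 2
  fy <- (F - Fr) / 2i
  out <- stats::fft(S11 * fx + S12 * fy + 1i * (S12 * fx + S22 * fy),
                    inverse = TRUE) / length(ux)
  list(x = Re(out), y = Im(out))
}

# full (negated) implicit operator: constant symbol part + varying friction
.mech_apply <- function(plan, dc, ux, uy) {
  con <- .sym_apply(plan$B11, plan$B12, plan$B22, ux, uy)
  diagc <- dc * (plan$Ep + plan$params$mu1 / plan$dt)
  bl <- plan$Ep * plan$params$beta1
  list(x = con$x + diagc * ux - dc * bl * .lap(ux, plan$dx),
       y = con$y + diagc * uy - dc * bl * .lap(uy, plan$dx))
}

.mech_precond <- function(plan, rx, ry) .sym_apply(plan$I11, plan$I12, plan$I22, rx, ry)

#' Advance the gel displacement by one implicit step
#'
#' Solves the discretized force balance for the displacement at the end of
#' the interval, treating the viscous and dish-friction rate terms with a
#' backward difference. The friction coefficient `1/h^2` is evaluated from
#' the current thickness field.
#'
#' @param u list with matrices `x`, `y`: current displacement (um).
#' @param rho density field (ng/um^3).
#' @param h thickness field (um); computed from `rho` via [thickness()] when
#'   omitted.
#' @param cell_mask cell occupancy image.
#' @param dt time step (s).
#' @param dx lattice spacing (um).
#' @param params a [gel_params()].
#' @param tol relative residual tolerance of the iterative solve.
#' @param maxit iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return list with the updated `u`, the rate `du_dt` (um/s, the consistent
#'   backward difference), `iterations` and `residual`.
#' @export
solve_displacement_step <- function(u, rho, cell_mask, dt, dx, params,
                                    h = NULL, tol = 1e-9, maxit = 400) {
  nx <- nrow(rho); ny <- ncol(rho)
  if (is.null(h)) h <- thickness(rho, params)
  cfield <- array(1 / as.vector(h)^2, dim(h))  # drop thickness attributes
  plan <- .mech_plan_cached(nx, ny, dx, params, dt, mean(cfield))
  dc <- cfield - plan$cbar
  # right-hand side in negated form: div(traction) - L_vis(u)/dt + c*mu1*u/dt
  s <- traction_field(cell_mask, rho, params$kappa)
  vis <- .sym_apply(plan$V11, plan$V12, plan$V22, u$x, u$y)  # = -L_vis(u)/dt
  rx <- .ddx(s, dx) + vis$x + cfield * params$mu1 * u$x / dt
  ry <- .ddy(s, dx) + vis$y + cfield * params$mu1 * u$y / dt
  sol <- .mech_solve(plan, dc, rx, ry, x0 = u, tol = tol, maxit = maxit)
  du <- list(x = (sol$u$x - u$x) / dt, y = (sol$u$y - u$y) / dt)
  list(u = sol$u, du_dt = du, iterations = sol$iterations,
       residual = sol$residual)
}

# varying (real-space) part of the operator: dc * friction
.mech_var <- function(plan, dc, ux, uy) {
  diagc <- dc * (plan$Ep + plan$params$mu1 / plan$dt)
  bl <- plan$Ep * plan$params$beta1
  list(x = diagc * ux - dc * bl * .lap(ux, plan$dx),
       y = diagc * uy - dc * bl * .lap(uy, plan$dx))
}

# Solve (C + D) u = b with C the constant-coefficient symbol block and D the
# varying friction: BiCGSTAB on the left-preconditioned operator
# u + C^{-1}(D u), with a direct spectral solve when D vanishes. The true
# residual of the untransformed system is verified on exit.
.mech_solve <- function(plan, dc, bx, by, x0, tol = 1e-9, maxit = 400) {
  if (max(abs(dc)) == 0) {
    u <- .mech_precond(plan, bx, by)
    return(list(u = u, iterations = 0L, residual = 0))
  }
  op <- function(ux, uy) {
    v <- .mech_var(plan, dc, ux, uy)
    p <- .mech_precond(plan, v$x, v$y)
    list(x = ux + p$x, y = uy + p$y)
  }
  bt <- .mech_precond(plan, bx, by)
  sol <- .bicgstab2(op, bt$x, bt$y, x0, tol, maxit)
  # verify against the untransformed system
  au <- .mech_apply(plan, dc, sol$u$x, sol$u$y)
  true_res <- sqrt(sum((au$x - bx)^2) + sum((au$y - by)^2)) /
    max(sqrt(sum(bx^2) + sum(by^2)), .Machine$double.xmin)
  if (true_res > 1e-6) {
    stop(sprintf("displacement solve did not converge: relative residual %.3e after %d iterations",
                 true_res, sol$iterations))
  }
  list(u = sol$u, iterations = sol$iterations, residual = true_res)
}

# plain BiCGSTAB on a generic operator over stacked (x, y) fields
.bicgstab2 <- function(op, bx, by, x0, tol, maxit) {
  dot <- function(ax, ay, cx, cy) sum(ax * cx) + sum(ay * cy)
  nb <- sqrt(dot(bx, by, bx, by))
  if (nb == 0) {
    return(list(u = list(x = bx * 0, y = by * 0), iterations = 0L, residual = 0))
  }
  xx <- x0$x; xy <- x0$y
  ax <- op(xx, xy)
  rx <- bx - ax$x; ry <- by - ax$y
  r0x <- rx; r0y <- ry
  rho_old <- 1; alpha <- 1; omega <- 1
  vx <- vy <- px <- py <- rx * 0
  it_done <- 0L
  for (it in seq_len(maxit)) {
    res <- sqrt(dot(rx, ry, rx, ry)) / nb
    if (res < tol) break
    rho_new <- dot(r0x, r0y, rx, ry)
    if (rho_new == 0) break
    beta <- (rho_new / rho_old) * (alpha / omega)
    px <- rx + beta * (px - omega * vx)
    py <- ry + beta * (py - omega * vy)
    av <- op(px, py)
    vx <- av$x; vy <- av$y
    alpha <- rho_new / dot(r0x, r0y, vx, vy)
    sx <- rx - alpha * vx; sy2 <- ry - alpha * vy
    at <- op(sx, sy2)
    tn <- dot(at$x, at$y, at$x, at$y)
    omega <- if (tn > 0) dot(at$x, at$y, sx, sy2) / tn else 0
    xx <- xx + alpha * px + omega * sx
    xy <- xy + alpha * py + omega * sy2
    rx <- sx - omega * at$x
    ry <- sy2 - omega * at$y
    rho_old <- rho_new
    it_done <- it
  }
  list(u = list(x = xx, y = xy), iterations = it_done,
       residual = sqrt(dot(rx, ry, rx, ry)) / nb)
}

#' Advect the gel density with the displacement rate
#'
#' Conservative first-order upwind update of `drho/dt = -div(rho du/dt)`.
#' Face velocities are neighbour averages; the step is internally sub-stepped
#' to respect the CFL limit. Total mass is conserved by construction; any
#' negative values produced by round-off are clipped with the clipped mass
#' reported in attribute `clipped_mass`.
#'
#' @param rho density field (ng/um^3).
#' @param du_dt list with matrices `x`, `y` (um/s).
#' @param dt time step (s).
#' @param dx lattice spacing (um).
#' @return updated density field with attributes `clipped_mass` and
#'   `substeps`.
#' @export
update_density <- function(rho, du_dt, dt, dx) {
  .advect_upwind(rho, du_dt$x, du_dt$y, dt, dx)
}

.advect_upwind <- function(f, vx, vy, dt, dx) {
  vmax <- max(abs(vx) + abs(vy), 0)
  nsub <- max(1L, ceiling(vmax * dt / (0.8 * dx)))
  dts <- dt / nsub
  clipped <- 0
  for (k in seq_len(nsub)) {
    # x faces between i and i+1 (periodic)
    vfx <- (vx + .shift_ip(vx)) / 2
    fup_x <- ifelse(vfx > 0, f, .shift_ip(f))
    Fx <- vfx * fup_x
    vfy <- (vy + .shift_jp(vy)) / 2
    fup_y <- ifelse(vfy > 0, f, .shift_jp(f))
    Fy <- vfy * fup_y
    f <- f - dts / dx * (Fx - .shift_im(Fx) + Fy - .shift_jm(Fy))
    neg <- f < 0
    if (any(neg)) {
      mass_before <- sum(f)
      clipped <- clipped + sum(-f[neg])
      f[neg] <- 0
      # renormalize so clipping does not create mass
      if (sum(f) > 0 && mass_before > 0) f <- f * mass_before / sum(f)
    }
  }
  attr(f, "clipped_mass") <- clipped
  attr(f, "substeps") <- nsub
  f
}
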