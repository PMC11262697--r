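# Two-species VEGF dynamics: soluble VEGF diffuses and exchanges with a
# finite pool of gel binding sites; bound VEGF rides with the deforming gel.
#
#   dc/dt = D_c lap(c) - k_on c (gamma rho - mw b) + k_off b
#   db/dt = -div(b du/dt) + k_on c (gamma rho - mw b) - k_off b
#
# Operator splitting per step: implicit (spectral) diffusion of c, upwind
# advection of b, then the pointwise exchange kinetics integrated exactly
# (the local ODE with c + b fixed is a constant-coefficient Riccati equation
# with a closed-form solution), so the step is unconditionally stable and
# conserves total VEGF to round-off.

#' Well-mixed binding equilibrium
#'
#' Solves `k_on c (gamma rho - mw b) = k_off b` with `c = total - b` for the
#' physically admissible root (`0 <= b <= min(total, gamma rho / mw)`).
#'
#' @param total total VEGF concentration `c + b` (ng/um^3); vectorized.
#' @param rho gel density (ng/um^3); vectorized.
#' @param params a [vegf_params()].
#' @return list with `c_eq` and `b_eq`.
#' @export
equilibrium_binding <- function(total, rho, params) {
  S <- params$gamma * rho
  mw <- params$mw_ratio
  A <- params$k_on * mw
  B <- params$k_on * (S + mw * total) + params$k_off
  C <- params$k_on * total * S
  disc <- pmax(B^2 - 4 * A * C, 0)
  b_eq <- ifelse(C > 0, 2 * C / (B + sqrt(disc)), 0)  # stable smaller root
  list(c_eq = total - b_eq, b_eq = b_eq)
}

# exact pointwise integration of the exchange kinetics over dt with the local
# total T = c + b held fixed: db/dt = A (b - r1)(b - r2), r1 < r2
.kinetics_exact <- function(b, total, S, params, dt) {
  mw <- params$mw_ratio
  A <- params$k_on * mw
  B <- params$k_on * (S + mw * total) + params$k_off
  C <- params$k_on * total * S
  disc <- pmax(B^2 - 4 * A * C, 0)
  sq <- sqrt(disc)
  r1 <- ifelse(C > 0, 2 * C / (B + sq), 0)
  r2 <- (B + sq) / (2 * A)
  # w = (b - r1)/(b - r2) decays as exp(-sq * dt); b - r2 < 0 always holds
  # for admissible states since r2 exceeds both T and the site capacity
  w <- (b - r1) / (b - r2) * exp(-sq * dt)
  bn <- (r1 - r2 * w) / (1 - w)
  # double-root limit (sq == 0): db/dt = A (b - r)^2
  dbl <- sq <= .Machine$double.eps * B
  if (any(dbl)) {
    br <- b - r1
    bn[dbl] <- (r1 + br / (1 - A * br * dt))[dbl]
  }
  pmin(pmax(bn, 0), total)
}

#' Advance the VEGF fields by one step
#'
#' Implicit spectral diffusion of the soluble species, conservative upwind
#' advection of the bound species with the gel displacement rate, and exact
#' pointwise binding/unbinding kinetics against the free sites
#' `gamma rho - mw b`. The exchange is equal and opposite, so
#' `sum(c) + sum(b)` is conserved to round-off.
#'
#' @param c soluble concentration field (ng/um^3).
#' @param b bound concentration field (ng/um^3).
#' @param rho gel density field (ng/um^3).
#' @param du_dt displacement rate, list with `x`, `y` (um/s); `NULL` for no
#'   advection.
#' @param dt time step (s).
#' @param dx lattice spacing (um).
#' @param params a [vegf_params()].
#' @return list with updated `c` and `b`.
#' @export
step_vegf <- function(c, b, rho, du_dt, dt, dx, params) {
  # implicit diffusion (backward Euler in Fourier space, 5-point Laplacian)
  nx <- nrow(c); ny <- ncol(c)
  tx <- (2 - 2 * cos(2 * pi * (seq_len(nx) - 1) / nx)) / dx^2
  ty <- (2 - 2 * cos(2 * pi * (seq_len(ny) - 1) / ny)) / dx^2
  Q <- outer(tx, ty, `+`)
  c <- .ifft2(.fft2(c) / (1 + params$D_c * Q * dt))
  if (!is.null(du_dt)) {
    b <- .advect_upwind(b, du_dt$x, du_dt$y, dt, dx)
  }
  total <- c + as.vector(b)
  dim(total) <- dim(c)
  b <- .kinetics_exact(as.vector(b), total, params$gamma * rho, params, dt)
  dim(b) <- dim(c)
  list(c = total - b, b = b)
}
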