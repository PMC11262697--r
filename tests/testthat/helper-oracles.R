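# Independent R-only oracles, written from the model definitions and kept
# free of the package's C++ code paths.

# full Hamiltonian by exhaustive enumeration of every neighbour pair and
# from-scratch cell geometry
oracle_hamiltonian <- function(grid, phi, params, dx) {
  nx <- nrow(grid); ny <- ncol(grid)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  J <- function(ta, tb) {
    if (ta && tb) params$J11 else if (ta || tb) params$J10 else params$J00
  }
  H <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    s <- grid[i, j]
    # right, up (weight 1); two diagonals (weight w2): each pair once
    pairs <- list(list(wrap(i + 1, nx), j, 1),
                  list(i, wrap(j + 1, ny), 1),
                  list(wrap(i + 1, nx), wrap(j + 1, ny), params$neighbor_weight_order2),
                  list(wrap(i + 1, nx), wrap(j - 1, ny), params$neighbor_weight_order2))
    for (p in pairs) {
      s2 <- grid[p[[1]], p[[2]]]
      if (s != s2) H <- H + p[[3]] * dx * J(s > 0, s2 > 0)
    }
  }
  for (s in seq_along(phi)) {
    w <- which(grid == s)
    if (length(w) == 0) next
    a <- length(w) * dx^2
    H <- H + params$lambda_a * (a - params$a0)^2
    # perimeter: first-order edges facing anything not the same cell
    ii <- (w - 1) %% nx + 1; jj <- (w - 1) %/% nx + 1
    edges <- 0
    for (k in seq_along(w)) {
      nb <- rbind(c(wrap(ii[k] + 1, nx), jj[k]), c(wrap(ii[k] - 1, nx), jj[k]),
                  c(ii[k], wrap(jj[k] + 1, ny)), c(ii[k], wrap(jj[k] - 1, ny)))
      edges <- edges + sum(grid[nb] != s)
    }
    H <- H + params$lambda_p * edges * dx
    if (phi[s] == 1) {
      l <- oracle_max_pairwise(ii, jj, nx, ny) * dx
      H <- H + params$lambda_l / max(l, dx)
    }
  }
  H
}

oracle_max_pairwise <- function(ii, jj, nx, ny) {
  best <- 0
  n <- length(ii)
  if (n < 2) return(0)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    di <- abs(ii[a] - ii[b]); di <- min(di, nx - di)
    dj <- abs(jj[a] - jj[b]); dj <- min(dj, ny - dj)
    best <- max(best, sqrt(di^2 + dj^2))
  }
  best
}

# dense periodic finite-difference assembly of the implicit displacement
# operator, built independently from 1-D difference matrices via Kronecker
# products (requires Matrix). Returns the solved displacement for the given
# state, mirroring one backward-difference step.
oracle_mech_solve <- function(u, rho, cell_mask, dt, dx, params, h = NULL) {
  requireNamespace("Matrix", quietly = TRUE)
  nx <- nrow(rho); ny <- ncol(rho)
  N <- nx * ny
  Ix <- Matrix::Diagonal(nx); Iy <- Matrix::Diagonal(ny)
  circ <- function(n, offs, vals) {
    M <- Matrix::Matrix(0, n, n, sparse = TRUE)
    for (k in seq_along(offs)) {
      idx <- cbind(seq_len(n), ((seq_len(n) - 1 + offs[k]) %% n) + 1)
      M[idx] <- M[idx] + vals[k]
    }
    M
  }
  D1x <- kronecker(Iy, circ(nx, c(1, -1), c(1, -1) / (2 * dx)))
  D1y <- kronecker(circ(ny, c(1, -1), c(1, -1) / (2 * dx)), Ix)
  D2x <- kronecker(Iy, circ(nx, c(1, 0, -1), c(1, -2, 1) / dx^2))
  D2y <- kronecker(circ(ny, c(1, 0, -1), c(1, -2, 1) / dx^2), Ix)
  Lap <- D2x + D2y
  Ep <- params$E / (1 + params$nu)
  nup <- params$nu / (1 - 2 * params$nu)
  if (is.null(h)) {
    nu <- params$nu
    h <- params$h0 * ((1 - 3 * nu) / (1 - 2 * nu) + nu / (1 - 2 * nu) * rho / params$rho0)
    h <- pmax(h, params$h_min)
  }
  Cdiag <- Matrix::Diagonal(N, x = as.vector(1 / h^2))
  I2 <- Matrix::Diagonal(N)
  S11 <- Lap + D1x %*% D1x; S12 <- D1x %*% D1y
  S22 <- Lap + D1y %*% D1y
  P11 <- D1x %*% D1x; P12 <- D1x %*% D1y; P22 <- D1y %*% D1y
  blk <- function(A11, A12, A21, A22) rbind(cbind(A11, A12), cbind(A21, A22))
  Avis <- blk(params$mu1 / 2 * S11 + params$mu2 * P11,
              params$mu1 / 2 * S12 + params$mu2 * P12,
              params$mu1 / 2 * S12 + params$mu2 * P12,
              params$mu1 / 2 * S22 + params$mu2 * P22) / dt
  Ael <- blk(Ep * (S11 / 2 + nup * P11), Ep * (S12 / 2 + nup * P12),
             Ep * (S12 / 2 + nup * P12), Ep * (S22 / 2 + nup * P22))
  LapB <- blk(Lap, Matrix::Matrix(0, N, N), Matrix::Matrix(0, N, N), Lap)
  Alr <- -Ep * (params$beta1 / 2 * (LapB %*% blk(S11, S12, S12, S22)) +
                nup * params$beta2 * (LapB %*% blk(P11, P12, P12, P22)))
  CdB <- blk(Cdiag, Matrix::Matrix(0, N, N), Matrix::Matrix(0, N, N), Cdiag)
  Afric <- -(Ep * (CdB - params$beta1 * (CdB %*% LapB)) + params$mu1 / dt * CdB)
  A <- Avis + Ael + Alr + Afric
  s <- as.vector(params$kappa * rho * (cell_mask > 0))
  uv <- c(as.vector(u$x), as.vector(u$y))
  rhs <- -c(as.vector(D1x %*% s), as.vector(D1y %*% s)) +
    as.vector(Avis %*% uv) -
    as.vector((params$mu1 / dt) * (CdB %*% uv))
  sol <- Matrix::solve(A, rhs)
  list(x = matrix(sol[1:N], nx, ny), y = matrix(sol[N + 1:N], nx, ny),
       A = A, rhs = rhs)
}
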