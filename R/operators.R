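#' Cell-centred gradient of a field
#'
#' Second-order central differences in the interior, second-order one-sided
#' stencils at boundary cells. Works on both axisymmetric (r, z) and planar
#' (x, z) grids; `dir = "r"` is the first coordinate.
#'
#' @param grid A `structured_grid`.
#' @param phi Matrix (`nr` x `nz`) of cell values.
#' @param dir `"r"` or `"z"`.
#' @return Matrix of the same shape with d(phi)/d(dir).
#' @export
field_gradient <- function(grid, phi, dir = c("r", "z")) {
  dir <- match.arg(dir)
  n1 <- grid$nr; n2 <- grid$nz
  if (dir == "r") {
    h <- grid$dr
    if (n1 < 3L) stop("degenerate grid spacing: need >= 3 cells")
    g <- matrix(0, n1, n2)
    g[2:(n1 - 1L), ] <- (phi[3:n1, ] - phi[1:(n1 - 2L), ]) / (2 * h)
    g[1L, ] <- (-3 * phi[1L, ] + 4 * phi[2L, ] - phi[3L, ]) / (2 * h)
    g[n1, ] <- (3 * phi[n1, ] - 4 * phi[n1 - 1L, ] + phi[n1 - 2L, ]) / (2 * h)
  } else {
    h <- grid$dz
    if (n2 < 3L) stop("degenerate grid spacing: need >= 3 cells")
    g <- matrix(0, n1, n2)
    g[, 2:(n2 - 1L)] <- (phi[, 3:n2] - phi[, 1:(n2 - 2L)]) / (2 * h)
    if (isTRUE(grid$periodic_z)) {
      g[, 1L] <- (phi[, 2L] - phi[, n2]) / (2 * h)
      g[, n2] <- (phi[, 1L] - phi[, n2 - 1L]) / (2 * h)
    } else {
      g[, 1L] <- (-3 * phi[, 1L] + 4 * phi[, 2L] - phi[, 3L]) / (2 * h)
      g[, n2] <- (3 * phi[, n2] - 4 * phi[, n2 - 1L] + phi[, n2 - 2L]) / (2 * h)
    }
  }
  g
}

# gradient that never differences across solid (impeller) cells: stencil
# neighbours inside the solid are replaced by a one-sided difference on the
# fluid side. Solid cells themselves get zero gradient.
.masked_gradient <- function(grid, phi, dir, solid) {
  g <- field_gradient(grid, phi, dir)
  if (is.null(solid) || !any(solid)) return(g)
  n1 <- grid$nr; n2 <- grid$nz
  interior <- matrix(FALSE, n1, n2)
  if (dir == "r") {
    h <- grid$dr
    interior[2:(n1 - 1), ] <- TRUE
    solE <- rbind(solid[-1, , drop = FALSE], rep(FALSE, n2))
    solW <- rbind(rep(FALSE, n2), solid[-n1, , drop = FALSE])
    useW <- interior & !solid & solE & !solW  # east neighbour solid
    useE <- interior & !solid & solW & !solE
    iW <- which(useW); iE <- which(useE)
    if (length(iW)) g[iW] <- (phi[iW] - phi[iW - 1L]) / h
    if (length(iE)) g[iE] <- (phi[iE + 1L] - phi[iE]) / h
    g[interior & !solid & solE & solW] <- 0
    if (n1 >= 3) {
      b1 <- !solid[1, ] & (solid[2, ] | solid[3, ])
      if (any(b1))
        g[1, b1] <- ifelse(solid[2, b1], 0,
                           (phi[2, b1] - phi[1, b1]) / h)
      bn <- !solid[n1, ] & (solid[n1 - 1, ] | solid[n1 - 2, ])
      if (any(bn))
        g[n1, bn] <- ifelse(solid[n1 - 1, bn], 0,
                            (phi[n1, bn] - phi[n1 - 1, bn]) / h)
    }
  } else {
    h <- grid$dz
    interior[, 2:(n2 - 1)] <- TRUE
    solN <- cbind(solid[, -1, drop = FALSE], rep(FALSE, n1))
    solS <- cbind(rep(FALSE, n1), solid[, -n2, drop = FALSE])
    useS <- interior & !solid & solN & !solS
    useN <- interior & !solid & solS & !solN
    iS <- which(useS); iN <- which(useN)
    if (length(iS)) g[iS] <- (phi[iS] - phi[iS - n1]) / h
    if (length(iN)) g[iN] <- (phi[iN + n1] - phi[iN]) / h
    g[interior & !solid & solN & solS] <- 0
    # boundary rows: the one-sided 3-point stencil may reach a solid cell
    # two rows in; fall back to first-order using the nearest fluid cell
    if (n2 >= 3) {
      b1 <- !solid[, 1] & (solid[, 2] | solid[, 3])
      if (any(b1))
        g[b1, 1] <- ifelse(solid[b1, 2], 0,
                           (phi[b1, 2] - phi[b1, 1]) / h)
      bn <- !solid[, n2] & (solid[, n2 - 1] | solid[, n2 - 2])
      if (any(bn))
        g[bn, n2] <- ifelse(solid[bn, n2 - 1], 0,
                            (phi[bn, n2] - phi[bn, n2 - 1]) / h)
    }
  }
  g[solid] <- 0
  g
}

# strain-rate tensor invariants on the grid.
# Returns S2 = S_ij S_ij, W3 = S_ij S_jk S_ki, Om2 = Omega_ij Omega_ij.
# Axisymmetric grids include the hoop component S_tt = u/r.
.strain_invariants <- function(grid, u, w) {
  dudr <- field_gradient(grid, u, "r")
  dudz <- field_gradient(grid, u, "z")
  dwdr <- field_gradient(grid, w, "r")
  dwdz <- field_gradient(grid, w, "z")
  Srz <- 0.5 * (dudz + dwdr)
  Orz <- 0.5 * (dudz - dwdr)
  if (grid$planar) {
    Stt <- matrix(0, grid$nr, grid$nz)
  } else {
    Stt <- sweep(u, 1L, grid$r, "/")
  }
  S2 <- dudr^2 + dwdz^2 + Stt^2 + 2 * Srz^2
  W3 <- dudr^3 + dwdz^3 + Stt^3 + 3 * Srz^2 * (dudr + dwdz)
  Om2 <- 2 * Orz^2
  list(S2 = S2, W3 = W3, Om2 = Om2,
       dudr = dudr, dudz = dudz, dwdr = dwdr, dwdz = dwdz, Stt = Stt)
}
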