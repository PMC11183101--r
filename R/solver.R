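# Finite-volume SIMPLE solver on collocated structured grids.
#
# Discretisation: hybrid (central/upwind) convection, central diffusion,
# Rhie-Chow face interpolation for pressure-velocity coupling, implicit
# under-relaxation. Axisymmetric grids carry annular face areas and the
# -mu u/r^2 radial-momentum term; extra variable-viscosity cross terms are
# neglected (thin-shear-layer approximation).

.VK  <- 0.4187   # von Karman constant
.EWF <- 9.793    # log-law roughness constant, smooth wall
.YPL <- 11.06    # viscous/log-layer switch in y+

# wall-function momentum coefficient: tau_w = cw * (U_t - U_wall)
.wall_coef <- function(k_strip, y, fluid, turbulence) {
  if (!turbulence) return(rep(fluid$mu / y, length(k_strip)))
  ustar <- 0.09^0.25 * sqrt(pmax(k_strip, 1e-14))
  yplus <- fluid$rho * ustar * y / fluid$mu
  ifelse(yplus > .YPL,
         fluid$rho * ustar * .VK / log(.EWF * yplus),
         fluid$mu / y)
}

# boundary contributions folded into aP/b for one variable.
# var: "u" (first-coordinate velocity), "w" (axial velocity),
#      "k", "eps" (zero-flux), or "dirichlet" with bc_values per side.
.bc_contrib <- function(g, ar, Gam, var, fluid = NULL, k_field = NULL,
                        turbulence = FALSE, bc_values = NULL) {
  nr <- g$nr; nz <- g$nz
  aPx <- matrix(0, nr, nz); bx <- matrix(0, nr, nz)
  tags <- g$boundary_tags
  wall_w <- g$wall_w %||% c(west = 0, east = 0)
  wall_u <- g$wall_u %||% c(south = 0, north = 0)

  add_dir <- function(side, cond, value) {
    if (side == "west")  { aPx[1, ]  <<- aPx[1, ] + cond;  bx[1, ]  <<- bx[1, ]  + cond * value }
    if (side == "east")  { aPx[nr, ] <<- aPx[nr, ] + cond; bx[nr, ] <<- bx[nr, ] + cond * value }
    if (side == "south") { aPx[, 1]  <<- aPx[, 1] + cond;  bx[, 1]  <<- bx[, 1]  + cond * value }
    if (side == "north") { aPx[, nz] <<- aPx[, nz] + cond; bx[, nz] <<- bx[, nz] + cond * value }
  }
  strip <- function(side) switch(side,
    west = list(A = ar$Aw[1, ], h = g$dr / 2, G = Gam[1, ],  k = if (!is.null(k_field)) k_field[1, ]),
    east = list(A = ar$Ae[nr, ], h = g$dr / 2, G = Gam[nr, ], k = if (!is.null(k_field)) k_field[nr, ]),
    south = list(A = ar$As[, 1], h = g$dz / 2, G = Gam[, 1],  k = if (!is.null(k_field)) k_field[, 1]),
    north = list(A = ar$An[, nz], h = g$dz / 2, G = Gam[, nz], k = if (!is.null(k_field)) k_field[, nz]))

  for (side in c("west", "east", "south", "north")) {
    tag <- tags[[side]]
    if (tag == "periodic") next  # not a boundary; handled by wrap links
    s <- strip(side)
    if (var == "dirichlet") {
      v <- bc_values[[side]]
      if (!is.null(v)) add_dir(side, s$G * s$A / s$h, v)
      next
    }
    if (var %in% c("k", "eps")) next  # zero-flux everywhere
    normal <- (var == "u" && side %in% c("west", "east")) ||
              (var == "w" && side %in% c("south", "north"))
    if (normal) {
      # closed boundaries: zero normal velocity (axis, walls, free surface)
      add_dir(side, s$G * s$A / s$h, 0)
    } else {
      # tangential component
      if (tag == "wall") {
        uw <- if (var == "w") wall_w[[side]] %||% 0 else wall_u[[side]] %||% 0
        if (turbulence && !is.null(s$k)) {
          cw <- .wall_coef(s$k, s$h, fluid, TRUE)
          add_dir(side, cw * s$A, uw)
        } else {
          add_dir(side, s$G * s$A / s$h, uw)
        }
      }
      # axis / symmetry / slip / liquid_surface / outflow: zero shear, no link
    }
  }
  list(aP = aPx, b = bx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble and solve one transport equation.
# De/Dn: interior diffusion conductances; Fe/Fn: interior mass fluxes.
# Returns list(phi, aP, res) with res the normalized unrelaxed residual
# evaluated at phi_old.
.solve_transport <- function(g, De, Dn, Fe, Fn, SpV, ScV, bcc, phi_old,
                             relax, solid = NULL, solid_value = NULL,
                             fix_mask = NULL, fix_value = NULL,
                             phi_scale = 0) {
  nr <- g$nr; nz <- g$nz; N <- nr * nz
  per <- isTRUE(g$periodic_z)
  aE <- matrix(0, nr, nz); aW <- matrix(0, nr, nz)
  aN <- matrix(0, nr, nz); aS <- matrix(0, nr, nz)
  if (nr > 1L) {
    aE[1:(nr - 1), ] <- pmax(-Fe, De - Fe / 2, 0)
    aW[2:nr, ]       <- pmax(Fe, De + Fe / 2, 0)
  }
  ji <- 1:(nz - 1)  # interior z-face columns of Dn/Fn
  if (nz > 1L) {
    aN[, ji] <- pmax(-Fn[, ji], Dn[, ji] - Fn[, ji] / 2, 0)
    aS[, 2:nz] <- pmax(Fn[, ji], Dn[, ji] + Fn[, ji] / 2, 0)
  }
  # periodic wrap face between columns nz and 1 (stored as column nz)
  aNw <- aSw <- rep(0, nr)
  if (per) {
    aNw <- pmax(-Fn[, nz], Dn[, nz] - Fn[, nz] / 2, 0)  # (i,nz) -> (i,1)
    aSw <- pmax(Fn[, nz], Dn[, nz] + Fn[, nz] / 2, 0)   # (i,1) -> (i,nz)
  }
  netF <- matrix(0, nr, nz)
  if (nr > 1L) {
    netF[1:(nr - 1), ] <- netF[1:(nr - 1), ] + Fe
    netF[2:nr, ]       <- netF[2:nr, ] - Fe
  }
  if (nz > 1L) {
    netF[, ji] <- netF[, ji] + Fn[, ji]
    netF[, 2:nz] <- netF[, 2:nz] - Fn[, ji]
  }
  if (per) {
    netF[, nz] <- netF[, nz] + Fn[, nz]
    netF[, 1] <- netF[, 1] - Fn[, nz]
  }
  aP <- aE + aW + aN + aS + SpV + bcc$aP + pmax(netF, 0)
  if (per) aP[, nz] <- aP[, nz] + aNw
  if (per) aP[, 1] <- aP[, 1] + aSw
  b  <- ScV + bcc$b
  fixed <- matrix(FALSE, nr, nz)
  fixv  <- matrix(0, nr, nz)
  if (!is.null(solid) && any(solid)) { fixed[solid] <- TRUE; fixv[solid] <- solid_value[solid] }
  if (!is.null(fix_mask) && any(fix_mask)) { fixed[fix_mask] <- TRUE; fixv[fix_mask] <- fix_value[fix_mask] }
  if (any(fixed)) {
    aE[fixed] <- 0; aW[fixed] <- 0; aN[fixed] <- 0; aS[fixed] <- 0
    if (per) { aNw[fixed[, nz]] <- 0; aSw[fixed[, 1]] <- 0 }
    aP[fixed] <- 1; b[fixed] <- fixv[fixed]
  }
  aP <- pmax(aP, 1e-300)

  idx <- matrix(seq_len(N), nr, nz)
  ii <- c(idx, idx[1:(nr - 1), ], idx[2:nr, ], idx[, 1:(nz - 1)], idx[, 2:nz])
  jj <- c(idx, idx[2:nr, ], idx[1:(nr - 1), ], idx[, 2:nz], idx[, 1:(nz - 1)])
  off <- c(-aE[1:(nr - 1), ], -aW[2:nr, ], -aN[, 1:(nz - 1)], -aS[, 2:nz])
  if (per) {
    ii <- c(ii, idx[, nz], idx[, 1])
    jj <- c(jj, idx[, 1], idx[, nz])
    off <- c(off, -aNw, -aSw)
  }

  # unrelaxed residual at phi_old (computed from coefficients, no matrix)
  ax <- aP * phi_old
  ax[, ] <- ax - aE * rbind(phi_old[-1, , drop = FALSE], 0) -
    aW * rbind(0, phi_old[-nr, , drop = FALSE]) -
    aN * cbind(phi_old[, -1, drop = FALSE], 0) -
    aS * cbind(0, phi_old[, -nz, drop = FALSE])
  if (per) {
    ax[, nz] <- ax[, nz] - aNw * phi_old[, 1]
    ax[, 1] <- ax[, 1] - aSw * phi_old[, nz]
  }
  r <- b - ax
  r[fixed] <- 0
  denom <- max(sum(abs(aP * phi_old)) + sum(abs(b)),
               sum(aP) * phi_scale, 1e-30)
  res <- sum(abs(r)) / denom

  # implicit under-relaxation
  if (relax < 1) {
    extra <- aP * (1 - relax) / relax
    extra[fixed] <- 0
    b <- b + extra * phi_old
    aP <- aP + extra
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = c(aP, off), dims = c(N, N))
  phi <- matrix(as.numeric(Matrix::solve(A, as.vector(b))), nr, nz)
  list(phi = phi, aP = aP, res = res)
}

# turbulent viscosity field from k, eps with realizable or constant C_mu
.mu_t_field <- function(k, eps, inv, fluid, closure) {
  if (!closure$turbulence) return(k * 0)
  if (closure$c_mu_mode == "constant") {
    cmu <- closure$c_mu
  } else {
    S2 <- inv$S2; Om2 <- inv$Om2
    Stil <- sqrt(S2)
    W <- inv$W3 / (Stil^3 + 1e-30)
    phi <- acos(pmin(pmax(sqrt(6) * W, -1), 1)) / 3
    As <- sqrt(6) * cos(phi)
    Ustar <- sqrt(S2 + Om2)
    cmu <- 1 / (4.04 + As * Ustar * k / pmax(eps, closure$eps_min))
    cmu <- pmin(pmax(cmu, 1e-4), 0.3)
  }
  mu_t <- cmu * fluid$rho * k^2 / pmax(eps, closure$eps_min)
  pmin(mu_t, closure$mu_t_ratio_max * fluid$mu)
}

# core SIMPLE driver. Returns fields + diagnostics.
.simple_solve <- function(g, fluid, closure, control,
                          mom_source = NULL, keps_source = NULL,
                          bc_values = NULL, freeze_velocity = NULL,
                          u_ref = NULL) {
  nr <- g$nr; nz <- g$nz
  ar <- .face_areas(g)
  V <- g$vol
  rho <- fluid$rho; mu <- fluid$mu
  solid <- g$solid %||% matrix(FALSE, nr, nz)
  has_solid <- any(solid)
  imp_w <- g$imp_w %||% matrix(0, nr, nz)
  zero <- matrix(0, nr, nz)

  # velocity scale for initialization and normalization
  if (is.null(u_ref)) {
    u_ref <- max(abs(imp_w),
                 abs(g$wall_w %||% 0), abs(g$wall_u %||% 0),
                 if (!is.null(freeze_velocity))
                   max(abs(freeze_velocity$u), abs(freeze_velocity$w)) else 0)
  }

  # initialization (deterministic)
  u <- zero; w <- zero; p <- zero
  k_scale <- closure$k_min; e_scale <- closure$eps_min
  if (closure$turbulence && u_ref > 0) {
    k0 <- 1e-3 * u_ref^2
    ell <- 0.07 * (if (g$planar) g$r_faces[nr + 1] / 2 else g$r_faces[nr + 1])
    e0 <- 0.09^0.75 * k0^1.5 / ell
    k <- matrix(max(k0, closure$k_min), nr, nz)
    eps <- matrix(max(e0, closure$eps_min), nr, nz)
    k_scale <- max(k0, closure$k_min); e_scale <- max(e0, closure$eps_min)
  } else {
    k <- matrix(closure$k_min, nr, nz)
    eps <- matrix(closure$eps_min, nr, nz)
  }
  if (!is.null(freeze_velocity)) { u <- freeze_velocity$u; w <- freeze_velocity$w }
  if (has_solid) { u[solid] <- 0; w[solid] <- imp_w[solid] }

  inv <- .strain_invariants(g, u, w)
  mu_t <- .mu_t_field(k, eps, inv, fluid, closure)

  # interior face geometry; with periodic z an extra wrap face (column nz)
  # connects columns nz and 1
  per <- isTRUE(g$periodic_z)
  jlo <- 1:(nz - 1); jhi <- 2:nz
  jz_a <- if (per) c(jlo, nz) else jlo   # "low" cell of each z-face
  jz_b <- if (per) c(jhi, 1) else jhi    # "high" cell of each z-face
  De_geom <- ar$Ae[1:(nr - 1), , drop = FALSE] / g$dr
  Dn_geom <- ar$An[, jz_a, drop = FALSE] / g$dz
  Ae_int <- ar$Ae[1:(nr - 1), , drop = FALSE]
  An_int <- ar$An[, jz_a, drop = FALSE]

  face_mu <- function(mm) list(
    e = (mm[1:(nr - 1), , drop = FALSE] + mm[2:nr, , drop = FALSE]) / 2,
    n = (mm[, jz_a, drop = FALSE] + mm[, jz_b, drop = FALSE]) / 2)

  # Rhie-Chow mass fluxes through interior faces
  dinv_u <- zero; dinv_w <- zero  # V/aP, updated after momentum solves
  face_flux <- function(u, w, p, dpdr, dpdz) {
    ub <- (u[1:(nr - 1), ] + u[2:nr, ]) / 2
    de <- (dinv_u[1:(nr - 1), ] + dinv_u[2:nr, ]) / 2
    pe <- (p[2:nr, ] - p[1:(nr - 1), ]) / g$dr
    pb <- (dpdr[1:(nr - 1), ] + dpdr[2:nr, ]) / 2
    uf <- ub - de * (pe - pb)
    if (has_solid) {
      sl <- solid[1:(nr - 1), ]; sr <- solid[2:nr, ]
      uf[sl | sr] <- 0  # disc is impermeable radially; u = 0 on the disc
    }
    fe <- rho * uf * Ae_int
    wb <- (w[, jz_a] + w[, jz_b]) / 2
    dn <- (dinv_w[, jz_a] + dinv_w[, jz_b]) / 2
    pn <- (p[, jz_b] - p[, jz_a]) / g$dz
    pbn <- (dpdz[, jz_a] + dpdz[, jz_b]) / 2
    wf <- wb - dn * (pn - pbn)
    if (has_solid) {
      sl <- solid[, jz_a]; sr <- solid[, jz_b]
      one <- xor(sl, sr); both <- sl & sr
      wlo <- w[, jz_a]; whi <- w[, jz_b]
      wf[one] <- ifelse(sl, wlo, whi)[one]  # disc surface moves with the disc
      wf[both] <- ((imp_w[, jz_a] + imp_w[, jz_b]) / 2)[both]
    }
    fn <- rho * wf * An_int
    list(Fe = fe, Fn = fn)
  }

  # epsilon wall-cell fixing mask (standard equilibrium wall treatment)
  eps_fix_mask <- matrix(FALSE, nr, nz)
  eps_y <- matrix(Inf, nr, nz)
  if (closure$turbulence && is.null(bc_values)) {
    tg <- g$boundary_tags
    if (tg[["east"]] == "wall") { eps_fix_mask[nr, ] <- TRUE; eps_y[nr, ] <- g$dr / 2 }
    if (tg[["west"]] == "wall") { eps_fix_mask[1, ] <- TRUE; eps_y[1, ] <- g$dz * 0 + g$dr / 2 }
    if (tg[["south"]] == "wall") { eps_fix_mask[, 1] <- TRUE; eps_y[, 1] <- pmin(eps_y[, 1], g$dz / 2) }
    if (tg[["north"]] == "wall") { eps_fix_mask[, nz] <- TRUE; eps_y[, nz] <- pmin(eps_y[, nz], g$dz / 2) }
    if (has_solid) {
      nb <- matrix(FALSE, nr, nz)
      nb[, 1:(nz - 1)] <- nb[, 1:(nz - 1)] | solid[, 2:nz]
      nb[, 2:nz] <- nb[, 2:nz] | solid[, 1:(nz - 1)]
      nb[1:(nr - 1), ] <- nb[1:(nr - 1), ] | solid[2:nr, ]
      nb[2:nr, ] <- nb[2:nr, ] | solid[1:(nr - 1), ]
      nb <- nb & !solid
      eps_fix_mask[nb] <- TRUE
      eps_y[nb] <- pmin(eps_y[nb], g$dz / 2)
    }
  }

  hist <- list()
  clip_count <- 0L
  res_min <- rep(Inf, 5)
  Fe <- matrix(0, max(nr - 1, 1), nz)
  Fn <- matrix(0, nr, length(jz_a))
  converged <- FALSE
  it <- 0L
  res <- c(continuity = 0, u = 0, w = 0, k = 0, eps = 0)

  for (it in seq_len(control$max_iter)) {
    mu_eff <- mu + mu_t
    fm <- face_mu(mu_eff)
    dpdr <- .masked_gradient(g, p, "r", if (has_solid) solid else NULL)
    dpdz <- .masked_gradient(g, p, "z", if (has_solid) solid else NULL)

    if (is.null(freeze_velocity)) {
      fl <- face_flux(u, w, p, dpdr, dpdz)
      Fe <- fl$Fe; Fn <- fl$Fn

      # u momentum
      Sp_u <- if (g$planar) zero else mu_eff / outer(g$r^2, rep(1, nz))
      Sc_u <- -dpdr + (if (!is.null(mom_source)) mom_source$Su else 0)
      bcc <- .bc_contrib(g, ar, mu_eff, if (is.null(bc_values)) "u" else "dirichlet",
                         fluid, k, closure$turbulence,
                         bc_values = bc_values$u)
      su <- .solve_transport(g, fm$e * De_geom, fm$n * Dn_geom, Fe, Fn,
                             Sp_u * V, Sc_u * V, bcc, u, control$relax_u,
                             solid = if (has_solid) solid else NULL,
                             solid_value = zero, phi_scale = u_ref)
      u_new <- su$phi
      dinv_u <- V / su$aP
      res["u"] <- su$res

      # w momentum
      Sc_w <- -dpdz + (if (!is.null(mom_source)) mom_source$Sw else 0)
      bcc <- .bc_contrib(g, ar, mu_eff, if (is.null(bc_values)) "w" else "dirichlet",
                         fluid, k, closure$turbulence,
                         bc_values = bc_values$w)
      sw <- .solve_transport(g, fm$e * De_geom, fm$n * Dn_geom, Fe, Fn,
                             zero, Sc_w * V, bcc, w, control$relax_u,
                             solid = if (has_solid) solid else NULL,
                             solid_value = imp_w, phi_scale = u_ref)
      w_new <- sw$phi
      dinv_w <- V / sw$aP
      res["w"] <- sw$res
      u <- u_new; w <- w_new

      # pressure correction
      fl <- face_flux(u, w, p, dpdr, dpdz)
      Fe <- fl$Fe; Fn <- fl$Fn
      imb <- matrix(0, nr, nz)
      imb[1:(nr - 1), ] <- imb[1:(nr - 1), ] + Fe
      imb[2:nr, ] <- imb[2:nr, ] - Fe
      imb[, jz_a] <- imb[, jz_a] + Fn
      imb[, jz_b] <- imb[, jz_b] - Fn
      flux_scale <- sum(abs(Fe)) + sum(abs(Fn)) + 1e-30
      res["continuity"] <- sum(abs(imb)) / flux_scale

      de_f <- rho * ((dinv_u[1:(nr - 1), ] + dinv_u[2:nr, ]) / 2) * Ae_int / g$dr
      dn_f <- rho * ((dinv_w[, jz_a] + dinv_w[, jz_b]) / 2) * An_int / g$dz
      if (has_solid) {
        de_f[solid[1:(nr - 1), ] | solid[2:nr, ]] <- 0
        dn_f[solid[, jz_a] | solid[, jz_b]] <- 0
      }
      aE <- matrix(0, nr, nz); aW <- matrix(0, nr, nz)
      aN <- matrix(0, nr, nz); aS <- matrix(0, nr, nz)
      aE[1:(nr - 1), ] <- de_f; aW[2:nr, ] <- de_f
      aN[, 1:(nz - 1)] <- dn_f[, 1:(nz - 1)]; aS[, 2:nz] <- dn_f[, 1:(nz - 1)]
      aNw <- aSw <- rep(0, nr)
      if (per) { aNw <- dn_f[, nz]; aSw <- dn_f[, nz] }
      aP <- aE + aW + aN + aS
      if (per) { aP[, nz] <- aP[, nz] + aNw; aP[, 1] <- aP[, 1] + aSw }
      bP <- -imb
      fixp <- solid | FALSE
      ref_cell <- which(!as.vector(solid))[1]
      N <- nr * nz
      idxm <- matrix(seq_len(N), nr, nz)
      fixv <- as.vector(fixp); fixv[ref_cell] <- TRUE
      aPv <- as.vector(aP); bv <- as.vector(bP)
      aPv[fixv] <- 1; bv[fixv] <- 0
      fixm <- matrix(fixv, nr, nz)
      aE[fixm] <- 0; aW[fixm] <- 0; aN[fixm] <- 0; aS[fixm] <- 0
      if (per) { aNw[fixm[, nz]] <- 0; aSw[fixm[, 1]] <- 0 }
      ii <- c(idxm, idxm[1:(nr - 1), ], idxm[2:nr, ], idxm[, 1:(nz - 1)], idxm[, 2:nz])
      jj <- c(idxm, idxm[2:nr, ], idxm[1:(nr - 1), ], idxm[, 2:nz], idxm[, 1:(nz - 1)])
      xx <- c(aPv, -aE[1:(nr - 1), ], -aW[2:nr, ], -aN[, 1:(nz - 1)], -aS[, 2:nz])
      if (per) {
        ii <- c(ii, idxm[, nz], idxm[, 1])
        jj <- c(jj, idxm[, 1], idxm[, nz])
        xx <- c(xx, -aNw, -aSw)
      }
      Ap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
      pc <- matrix(as.numeric(Matrix::solve(Ap, bv)), nr, nz)

      p <- p + control$relax_p * pc
      dpc_r <- .masked_gradient(g, pc, "r", if (has_solid) solid else NULL)
      dpc_z <- .masked_gradient(g, pc, "z", if (has_solid) solid else NULL)
      u <- u - dinv_u * dpc_r
      w <- w - dinv_w * dpc_z
      if (has_solid) { u[solid] <- 0; w[solid] <- imp_w[solid] }
      Fe <- Fe + de_f * (pc[1:(nr - 1), ] - pc[2:nr, ])
      Fn <- Fn + dn_f * (pc[, jz_a] - pc[, jz_b])
    } else {
      fl <- face_flux(u, w, p, dpdr, dpdz)
      Fe <- fl$Fe; Fn <- fl$Fn
      res["continuity"] <- 0; res["u"] <- 0; res["w"] <- 0
    }

    if (closure$turbulence) {
      k_prev <- k; eps_prev <- eps
      inv <- .strain_invariants(g, u, w)
      gam2 <- 2 * inv$S2
      S <- sqrt(gam2)
      mu_t <- .mu_t_field(k, eps, inv, fluid, closure)
      Pk <- pmin(mu_t * gam2, 10 * rho * eps)

      Gk <- mu + mu_t / closure$sigma_k
      fmk <- face_mu(Gk)
      Sp_k <- rho * eps / pmax(k, closure$k_min)
      Sc_k <- Pk + (if (!is.null(keps_source)) keps_source$Sk else 0)
      bcc <- .bc_contrib(g, ar, Gk, if (is.null(bc_values)) "k" else "dirichlet",
                         fluid, k, TRUE, bc_values = bc_values$k)
      sk <- .solve_transport(g, fmk$e * De_geom, fmk$n * Dn_geom, Fe, Fn,
                             Sp_k * V, Sc_k * V, bcc, k, control$relax_ke,
                             solid = if (has_solid) solid else NULL,
                             solid_value = matrix(closure$k_min, nr, nz),
                             phi_scale = k_scale)
      k_new <- sk$phi
      res["k"] <- sk$res

      Ge <- mu + mu_t / closure$sigma_eps
      fme <- face_mu(Ge)
      eta <- S * k / pmax(eps, closure$eps_min)
      C1 <- pmax(closure$c1_min, eta / (eta + 5))
      denom <- if (closure$eps_denominator_mode == "sqrt_nu_eps")
        k + sqrt(fluid$nu * eps) else k + sqrt(mu * eps)
      Sp_e <- rho * closure$c2 * eps / pmax(denom, 1e-30)
      Sc_e <- rho * C1 * S * eps +
        (if (!is.null(keps_source)) keps_source$Se else 0)
      epsfix_val <- 0.09^0.75 * pmax(k, closure$k_min)^1.5 / (.VK * eps_y)
      bcc <- .bc_contrib(g, ar, Ge, if (is.null(bc_values)) "eps" else "dirichlet",
                         fluid, k, TRUE, bc_values = bc_values$eps)
      se <- .solve_transport(g, fme$e * De_geom, fme$n * Dn_geom, Fe, Fn,
                             Sp_e * V, Sc_e * V, bcc, eps, control$relax_ke,
                             solid = if (has_solid) solid else NULL,
                             solid_value = matrix(closure$eps_min, nr, nz),
                             fix_mask = if (any(eps_fix_mask)) eps_fix_mask else NULL,
                             fix_value = epsfix_val, phi_scale = e_scale)
      eps_new <- se$phi
      res["eps"] <- se$res

      nclip <- sum(k_new < closure$k_min) + sum(eps_new < closure$eps_min)
      clip_count <- clip_count + nclip
      k <- pmax(k_new, closure$k_min)
      eps <- pmax(eps_new, closure$eps_min)
      # clipped iterate identical to the previous one: discrete fixed point
      if (identical(k, k_prev)) res["k"] <- 0
      if (identical(eps, eps_prev)) res["eps"] <- 0
      inv <- .strain_invariants(g, u, w)
      mu_t <- .mu_t_field(k, eps, inv, fluid, closure)
    } else {
      res["k"] <- 0; res["eps"] <- 0
    }

    hist[[it]] <- res
    if (control$verbose && (it %% 25L == 0L || it == 1L))
      message(sprintf("iter %4d  cont %.3e u %.3e w %.3e k %.3e eps %.3e",
                      it, res[1], res[2], res[3], res[4], res[5]))
    if (any(!is.finite(c(u, w, p, k, eps))))
      stop(.solver_error("non-finite field values (divergence)", it, hist))
    res_min <- pmin(res_min, res)
    if (it > 50L && any(res > control$diverge_factor * pmax(res_min, 1e-12) &
                        res > 1))
      stop(.solver_error("residual growth (divergence)", it, hist))
    if (all(res <= control$tol)) { converged <- TRUE; break }
  }

  diag <- structure(list(
    iterations = it,
    residuals = res,
    residual_history = do.call(rbind, hist),
    converged = converged,
    clip_count = clip_count,
    tolerance = control$tol), class = "solver_diagnostics")

  list(u = u, w = w, p = p, k = k, eps = eps, mu_t = mu_t,
       diagnostics = diag)
}

.solver_error <- function(msg, it, hist) {
  structure(class = c("turbtank_divergence", "error", "condition"),
            list(message = sprintf("%s at iteration %d", msg, it),
                 call = sys.call(-1),
                 diagnostics = list(iteration = it,
                                    residual_history = do.call(rbind, hist))))
}

#' @export
print.solver_diagnostics <- function(x, ...) {
  cat(sprintf("SIMPLE solve: %d iterations, %s (tol %.1e)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged", x$tolerance))
  cat("final residuals:",
      paste(sprintf("%s=%.2e", names(x$residuals), x$residuals),
            collapse = "  "), "\n")
  if (x$clip_count > 0)
    cat(sprintf("positivity floors applied %d times\n", x$clip_count))
  invisible(x)
}

#' Solve one quasi-steady impeller-position snapshot
#'
#' Runs the steady SIMPLE/RANS solve on the grid with the impeller discs
#' frozen at the given stroke position and moving with the instantaneous
#' reciprocating wall velocity (top of stroke moving down, bottom moving up
#' for the default two-snapshot triangular cycle). Free surface is a slip
#' plane, outer walls no-slip (equilibrium wall functions in turbulent mode).
#'
#' @param grid A `structured_grid` from [generate_grid()].
#' @param fluid A [fluid_properties()].
#' @param closure A [closure_config()].
#' @param motion A [motion_spec()]; defaults to the grid's tank motion.
#' @param position_index Snapshot index (1..n_snapshots).
#' @param control A [solver_control()].
#' @return An object of class `flow_state` with fields `u`, `w`, `p`, `k`,
#'   `eps`, `mu_t` (matrices), the positioned grid, impeller position and
#'   velocity, and `diagnostics`.
#' @export
solve_snapshot <- function(grid, fluid = fluid_properties(),
                           closure = closure_config(), motion = NULL,
                           position_index = 1L,
                           control = solver_control()) {
  gp <- grid_at_position(grid, motion, position_index)
  if (is.null(motion)) motion <- grid$tank$motion
  sol <- .simple_solve(gp, fluid, closure, control,
                       u_ref = motion$set_speed / 1000)
  structure(list(u = sol$u, w = sol$w, p = sol$p, k = sol$k, eps = sol$eps,
                 mu_t = sol$mu_t, grid = gp, solid = gp$solid,
                 swept = gp$swept,
                 impeller_position_mm = gp$impeller_position_mm,
                 impeller_velocity = gp$impeller_velocity,
                 fluid = fluid, closure = closure,
                 diagnostics = sol$diagnostics),
            class = "flow_state")
}

#' Run all impeller-position snapshots of a motion cycle
#'
#' One converged quasi-steady [solve_snapshot()] per sampled impeller
#' position; the grid is re-tagged at each position.
#'
#' @inheritParams solve_snapshot
#' @return An object of class `snapshot_ensemble`: list of `flow_state`s
#'   plus the shared tank/motion.
#' @export
run_snapshot_ensemble <- function(grid, fluid = fluid_properties(),
                                  closure = closure_config(), motion = NULL,
                                  control = solver_control()) {
  if (is.null(motion)) motion <- grid$tank$motion
  if (is.null(motion) || motion$n_snapshots < 2L)
    stop("motion with n_snapshots >= 2 required")
  states <- vector("list", motion$n_snapshots)
  for (i in seq_len(motion$n_snapshots)) {
    states[[i]] <- tryCatch(
      solve_snapshot(grid, fluid, closure, motion, i, control),
      error = function(e) stop(sprintf("snapshot %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  structure(list(states = states, tank = grid$tank, motion = motion),
            class = "snapshot_ensemble")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "flow_state: %d x %d cells, impeller at %+.1f mm moving %+.3f m/s\n",
    x$grid$nr, x$grid$nz, x$impeller_position_mm, x$impeller_velocity))
  cat(sprintf("  |u|max %.4g m/s, k in [%.3g, %.3g], eps in [%.3g, %.3g]\n",
              max(sqrt(x$u^2 + x$w^2)), min(x$k), max(x$k),
              min(x$eps), max(x$eps)))
  print(x$diagnostics)
  invisible(x)
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("snapshot_ensemble of %d impeller positions\n",
              length(x$states)))
  for (s in x$states)
    cat(sprintf("  position %+.1f mm, velocity %+.3f m/s, converged: %s\n",
                s$impeller_position_mm, s$impeller_velocity,
                s$diagnostics$converged))
  invisible(x)
}

#' Plot a flow-state field as a filled section map
#'
#' @param x A `flow_state`.
#' @param field Field name (`"k"`, `"eps"`, `"u"`, `"w"`, `"p"`, `"mu_t"`).
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.flow_state <- function(x, field = "k", ...) {
  f <- x[[field]]
  graphics::filled.contour(x$grid$r, x$grid$z, f,
                           xlab = "r (m)", ylab = "z (m)",
                           main = sprintf("%s, impeller at %+.0f mm",
                                          field, x$impeller_position_mm), ...)
  invisible(x)
}

#' Laminar channel verification solve (plane Couette / Poiseuille)
#'
#' Plane variant of the solver core on a planar grid: two parallel no-slip
#' walls normal to x, fully developed in z (zero-gradient ends). Couette is
#' driven by the moving east wall at speed `U`; Poiseuille by a constant
#' axial pressure gradient `dpdz`.
#'
#' @param type `"couette"` or `"poiseuille"`.
#' @param n Number of cells across the gap.
#' @param U Moving-wall speed (m/s), Couette.
#' @param h Gap width (m).
#' @param dpdz Axial pressure gradient (Pa/m, negative drives +z flow).
#' @param fluid [fluid_properties()].
#' @param control [solver_control()].
#' @return List with `x` (cell centres), `w` (computed axial velocity
#'   profile), `exact` (analytic profile), `rel_err` (max relative error
#'   against the profile maximum), and `diagnostics`.
#' @export
solve_channel <- function(type = c("couette", "poiseuille"), n = 64L,
                          U = 0.1, h = 0.01, dpdz = -1,
                          fluid = fluid_properties(),
                          control = solver_control(max_iter = 60L,
                                                   relax_u = 1.0,
                                                   relax_p = 0.7)) {
  type <- match.arg(type)
  g <- planar_grid(h, h, nx = n, nz = 4L,
                   tags = c(west = "wall", east = "wall",
                            south = "periodic", north = "periodic"))
  g$wall_w <- c(west = 0, east = if (type == "couette") U else 0)
  closure <- closure_config(turbulence = FALSE)
  src <- if (type == "poiseuille")
    list(Su = 0, Sw = matrix(-dpdz, n, 4L)) else NULL
  sol <- .simple_solve(g, fluid, closure, control, mom_source = src,
                       u_ref = max(abs(U), abs(dpdz) * h^2 / fluid$mu))
  x <- g$r
  wnum <- sol$w[, 2L]
  exact <- if (type == "couette") U * x / h
           else (-dpdz) / (2 * fluid$mu) * x * (h - x)
  rel_err <- max(abs(wnum - exact)) / max(abs(exact))
  list(x = x, w = wnum, exact = exact, rel_err = rel_err,
       diagnostics = sol$diagnostics)
}
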