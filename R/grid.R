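#' Generate a structured grid for a tank
#'
#' Builds a uniform 2D axisymmetric (r, z) cell-centred grid over the liquid
#' column. Cell volumes carry the annular weighting `2 pi r dr dz`, so their
#' sum equals the working volume exactly (up to round-off). Boundary faces
#' are tagged `axis` (r = 0), `wall` (outer wall and bottom) and
#' `liquid_surface` (top, treated as a shear-free slip plane). Impeller discs
#' are tagged per stroke position with [grid_at_position()].
#'
#' @param tank A [tank_spec()].
#' @param nr,nz Number of cells in the radial and axial directions (>= 8).
#' @return An object of class `structured_grid`.
#' @export
generate_grid <- function(tank, nr = 24L, nz = 36L) {
  stopifnot(inherits(tank, "tank_spec"))
  nr <- as.integer(nr); nz <- as.integer(nz)
  if (nr < 8L || nz < 8L) stop("resolution must be >= 8 cells per direction")
  R <- tank$diameter / 2
  H <- tank$liquid_height
  dr <- R / nr
  dz <- H / nz
  for (im in tank$impellers) {
    if (im$disc_radius < 2 * dr)
      stop("resolution too coarse to resolve an impeller disc (< 2 cells)")
  }
  r_faces <- seq(0, R, length.out = nr + 1L)
  z_faces <- seq(0, H, length.out = nz + 1L)
  r <- (r_faces[-1L] + r_faces[-(nr + 1L)]) / 2
  z <- (z_faces[-1L] + z_faces[-(nz + 1L)]) / 2
  # annular volume between consecutive radial faces, exact
  ring <- pi * (r_faces[-1L]^2 - r_faces[-(nr + 1L)]^2)
  vol <- outer(ring, rep(dz, nz))
  structure(list(
    planar = FALSE, nr = nr, nz = nz, dr = dr, dz = dz,
    r = r, z = z, r_faces = r_faces, z_faces = z_faces,
    vol = vol,
    boundary_tags = c(west = "axis", east = "wall",
                      south = "wall", north = "liquid_surface"),
    tank = tank), class = "structured_grid")
}

#' Generate a planar Cartesian grid
#'
#' Plane (x, z) variant of the solver grid with unit depth, used for
#' verification cases (Couette/Poiseuille channels, manufactured solutions,
#' planar analytic fields). `x` plays the role of the first coordinate.
#'
#' @param Lx,Lz Domain extents (m).
#' @param nx,nz Cell counts.
#' @param tags Named character vector of boundary tags for sides
#'   `west`, `east`, `south`, `north`; any of `"wall"`, `"slip"`,
#'   `"symmetry"`, `"liquid_surface"`.
#' @return A `structured_grid` with `planar = TRUE`.
#' @export
planar_grid <- function(Lx, Lz, nx = 32L, nz = 32L,
                        tags = c(west = "wall", east = "wall",
                                 south = "wall", north = "wall")) {
  nx <- as.integer(nx); nz <- as.integer(nz)
  stopifnot(Lx > 0, Lz > 0, nx >= 4L, nz >= 4L)
  dr <- Lx / nx; dz <- Lz / nz
  r_faces <- seq(0, Lx, length.out = nx + 1L)
  z_faces <- seq(0, Lz, length.out = nz + 1L)
  r <- (r_faces[-1L] + r_faces[-(nx + 1L)]) / 2
  z <- (z_faces[-1L] + z_faces[-(nz + 1L)]) / 2
  vol <- matrix(dr * dz, nx, nz)
  periodic_z <- identical(unname(tags[["south"]]), "periodic") &&
    identical(unname(tags[["north"]]), "periodic")
  structure(list(
    planar = TRUE, nr = nx, nz = nz, dr = dr, dz = dz,
    r = r, z = z, r_faces = r_faces, z_faces = z_faces,
    vol = vol, boundary_tags = tags, periodic_z = periodic_z, tank = NULL),
    class = "structured_grid")
}

# face areas for the finite-volume discretisation.
# east/west faces are normal to r; north/south normal to z.
.face_areas <- function(g) {
  if (g$planar) {
    list(Ae = matrix(g$dz, g$nr, g$nz), Aw = matrix(g$dz, g$nr, g$nz),
         An = matrix(g$dr, g$nr, g$nz), As = matrix(g$dr, g$nr, g$nz))
  } else {
    Ae <- outer(2 * pi * g$r_faces[-1L] * g$dz, rep(1, g$nz))
    Aw <- outer(2 * pi * g$r_faces[-(g$nr + 1L)] * g$dz, rep(1, g$nz))
    ring <- pi * (g$r_faces[-1L]^2 - g$r_faces[-(g$nr + 1L)]^2)
    An <- outer(ring, rep(1, g$nz))
    list(Ae = Ae, Aw = Aw, An = An, As = An)
  }
}

#' Tag impeller discs at one stroke position
#'
#' Returns the grid augmented with the per-position impeller representation:
#' a logical `solid` cell mask covering each disc (at least one cell layer
#' thick; discs thinner than a cell are represented by the single adjacent
#' cell layer, the zero-thickness moving-wall limit), the instantaneous
#' axial wall velocity `imp_w` (m/s) of those cells, and `impeller_faces`,
#' the internal z-face indices spanned by each disc.
#'
#' @param grid A `structured_grid` from [generate_grid()].
#' @param motion A [motion_spec()]; defaults to the tank's.
#' @param position_index Snapshot index in `1..n_snapshots`.
#' @return The grid with fields `solid`, `imp_w`, `impeller_faces`,
#'   `position_index`, `impeller_position_mm`, `impeller_velocity`.
#' @export
grid_at_position <- function(grid, motion = NULL, position_index = 1L) {
  stopifnot(inherits(grid, "structured_grid"))
  tank <- grid$tank
  if (is.null(tank)) stop("grid has no tank: impellers undefined")
  if (is.null(motion)) motion <- tank$motion
  if (is.null(motion)) stop("no motion_spec available")
  position_index <- as.integer(position_index)
  if (position_index < 1L || position_index > motion$n_snapshots)
    stop("position_index out of range")
  pos <- impeller_positions(motion)[position_index, ]
  solid <- matrix(FALSE, grid$nr, grid$nz)
  swept <- matrix(FALSE, grid$nr, grid$nz)
  imp_w <- matrix(0, grid$nr, grid$nz)
  faces <- list()
  for (ii in seq_along(tank$impellers)) {
    im <- tank$impellers[[ii]]
    sgn <- if (motion$in_phase || ii %% 2L == 1L) 1 else -1
    zc <- im$center_height + sgn * pos$offset_mm / 1000
    wv <- sgn * pos$velocity_mm_s / 1000
    if (zc <= 0 || zc >= tank$liquid_height)
      stop(sprintf("impeller %d leaves the liquid column at position %d",
                   ii, position_index))
    half_t <- max(im$disc_thickness, grid$dz) / 2
    jz <- which(grid$z > zc - half_t & grid$z < zc + half_t)
    if (length(jz) == 0L) jz <- which.min(abs(grid$z - zc))
    ir <- which(grid$r < im$disc_radius)
    solid[ir, jz] <- TRUE
    imp_w[ir, jz] <- wv
    # stroke-sweep envelope: the disc passes through these cells each cycle
    half_sweep <- motion$stroke / 2 / 1000 + half_t
    js <- which(grid$z > im$center_height - half_sweep &
                grid$z < im$center_height + half_sweep)
    swept[ir, js] <- TRUE
    jface <- which.min(abs(grid$z_faces - zc))
    faces[[ii]] <- data.frame(impeller = ii, z_face = jface,
                              r_cells = max(ir), velocity = wv)
  }
  grid$solid <- solid
  grid$swept <- swept
  grid$imp_w <- imp_w
  grid$impeller_faces <- do.call(rbind, faces)
  grid$position_index <- position_index
  grid$impeller_position_mm <- pos$offset_mm
  grid$impeller_velocity <- pos$velocity_mm_s / 1000
  grid
}

#' @export
print.structured_grid <- function(x, ...) {
  kind <- if (x$planar) "planar" else "axisymmetric"
  cat(sprintf("%s structured grid: %d x %d cells, total volume %.6g m^3\n",
              kind, x$nr, x$nz, sum(x$vol)))
  invisible(x)
}

#' Export grid cell centres and volumes as a data frame
#'
#' @param grid A `structured_grid`.
#' @return Data frame with columns `i`, `j`, `r_m`, `z_m`, `volume_m3`.
#' @export
grid_table <- function(grid) {
  idx <- expand.grid(i = seq_len(grid$nr), j = seq_len(grid$nz))
  data.frame(i = idx$i, j = idx$j,
             r_m = grid$r[idx$i], z_m = grid$z[idx$j],
             volume_m3 = grid$vol[cbind(idx$i, idx$j)])
}
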