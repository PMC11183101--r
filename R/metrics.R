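#' Turbulent viscosity from k and epsilon
#'
#' `mu_t = C_mu rho k^2 / eps` per cell. In `"constant"` mode C_mu = 0.09;
#' in `"realizable"` mode the variable C_mu of the realizable closure is
#' used, which requires the velocity field (pass a `flow_state`).
#'
#' @param k Turbulent kinetic energy (m^2/s^2), matrix or vector.
#' @param eps Dissipation rate (m^2/s^3), same shape.
#' @param fluid A [fluid_properties()].
#' @param closure A [closure_config()]; `state`/`grid` are only needed for
#'   realizable mode.
#' @param state,grid Optional `flow_state` and grid for realizable C_mu.
#' @return mu_t (Pa s), same shape as `k`.
#' @export
turbulent_viscosity <- function(k, eps, fluid = fluid_properties(),
                                closure = closure_config(c_mu_mode = "constant"),
                                state = NULL, grid = NULL) {
  if (any(k < closure$k_min) || any(eps < closure$eps_min))
    stop("k/eps below configured floors; apply floors upstream")
  if (closure$c_mu_mode == "constant" || is.null(state)) {
    cmu <- closure$c_mu
    return(cmu * fluid$rho * k^2 / eps)
  }
  inv <- .strain_invariants(grid %||% state$grid, state$u, state$w)
  .mu_t_field(k, eps, inv, fluid, closure)
}

#' Strain-rate magnitude
#'
#' `gamma_dot = sqrt(2 S_ij S_ij)`, the modulus of the mean strain-rate
#' tensor, evaluated with second-order central differences (one-sided at
#' boundaries). On axisymmetric grids the hoop component u/r is included.
#'
#' @param state A `flow_state` (or any list with `u`, `w` matrices).
#' @param grid The `structured_grid` the fields live on (defaults to
#'   `state$grid`).
#' @return Matrix of strain rate (1/s), non-negative.
#' @export
strain_rate <- function(state, grid = state$grid) {
  inv <- .strain_invariants(grid, state$u, state$w)
  sqrt(2 * inv$S2)
}

#' Shear stress
#'
#' Mode `"molecular"` is the literal `tau = mu * gamma_dot`; mode
#' `"effective"` (default) uses the turbulence-augmented viscosity,
#' `tau = (mu + mu_t) * gamma_dot`, which is the scale on which the
#' summary tables of stirred-tank CFD report stress. The mode is recorded
#' in the result's `"tau_mode"` attribute.
#'
#' @param gamma_dot Strain-rate field (1/s).
#' @param fluid A [fluid_properties()].
#' @param mu_t Turbulent viscosity field (Pa s); required for effective mode.
#' @param mode `"effective"` or `"molecular"`.
#' @return Shear stress (Pa) with attribute `tau_mode`.
#' @export
shear_stress <- function(gamma_dot, fluid = fluid_properties(), mu_t = NULL,
                         mode = c("effective", "molecular")) {
  mode <- match.arg(mode)
  if (mode == "effective") {
    if (is.null(mu_t)) stop("effective mode requires mu_t")
    if (!identical(dim(gamma_dot), dim(mu_t)) &&
        length(gamma_dot) != length(mu_t))
      stop("gamma_dot and mu_t must be aligned on the same grid")
    tau <- (fluid$mu + mu_t) * gamma_dot
  } else {
    tau <- fluid$mu * gamma_dot
  }
  attr(tau, "tau_mode") <- mode
  tau
}

#' Vorticity magnitude
#'
#' `omega = ||curl v||`; on axisymmetric and planar section grids the only
#' non-trivial component is the out-of-plane one,
#' `omega_theta = du/dz - dw/dr`, so the magnitude is its absolute value.
#'
#' @inheritParams strain_rate
#' @return Matrix of vorticity magnitude (1/s).
#' @export
vorticity <- function(state, grid = state$grid) {
  dudz <- field_gradient(grid, state$u, "z")
  dwdr <- field_gradient(grid, state$w, "r")
  abs(dudz - dwdr)
}

#' Kolmogorov length scale
#'
#' `lambda = ((mu/rho)^3 / eps)^(1/4)` per cell: the smallest eddy size
#' sustained by the local dissipation rate.
#'
#' @param eps Dissipation rate (m^2/s^3), at or above the closure floor.
#' @param fluid A [fluid_properties()].
#' @return Kolmogorov scale (m), same shape as `eps`.
#' @export
kolmogorov_scale <- function(eps, fluid = fluid_properties()) {
  (fluid$nu^3 / eps)^0.25
}

#' Compute all derived turbulence fields for a flow state
#'
#' @param state A `flow_state`.
#' @param fluid,closure Property/closure objects (default: the state's own).
#' @param tau_mode Shear-stress mode, `"effective"` or `"molecular"`.
#' @return An object of class `derived_fields`: list of matrices `mu_t`,
#'   `gamma_dot`, `tau`, `omega`, `lambda_k`, `eps`, plus `tau_mode`.
#' @export
derive_fields <- function(state, fluid = state$fluid %||% fluid_properties(),
                          closure = state$closure %||% closure_config(),
                          tau_mode = c("effective", "molecular")) {
  tau_mode <- match.arg(tau_mode)
  g <- state$grid
  gd <- strain_rate(state, g)
  om <- vorticity(state, g)
  mu_t <- state$mu_t
  if (is.null(mu_t))
    mu_t <- turbulent_viscosity(pmax(state$k, closure$k_min),
                                pmax(state$eps, closure$eps_min),
                                fluid, closure, state, g)
  tau <- shear_stress(gd, fluid, mu_t, tau_mode)
  lam <- kolmogorov_scale(pmax(state$eps, closure$eps_min), fluid)
  structure(list(mu_t = mu_t, gamma_dot = gd, tau = tau, omega = om,
                 lambda_k = lam, eps = state$eps, tau_mode = tau_mode),
            class = "derived_fields")
}

#' Volume-averaged summary row (tank-scale comparison schema)
#'
#' Volume-weighted averages of the turbulence metrics in the fixed column
#' schema used for cross-scale comparison: scale (L), speed (mm/s),
#' turbulent energy (m^2/s^2), shear stress (Pa), Kolmogorov scale (um),
#' shear rate (1/s), vorticity (1/s), dissipation (m^2/s^3).
#'
#' `averaging_mode = "average-of-field"` (default) averages the per-cell
#' derived fields; `"field-of-average"` recomputes the nonlinear quantities
#' (Kolmogorov scale, shear stress) from the volume-averaged inputs.
#'
#' @param state A `flow_state`.
#' @param derived A `derived_fields` (default computed from `state`).
#' @param grid Grid (default the state's).
#' @param tank,motion Tank and motion metadata for the scale/speed columns.
#' @param averaging_mode `"average-of-field"` or `"field-of-average"`.
#' @param mask Optional logical matrix restricting the averaging region.
#' @return A one-row data frame of class `summary_row`.
#' @export
summarize_state <- function(state, derived = NULL, grid = state$grid,
                            tank = grid$tank, motion = NULL,
                            averaging_mode = c("average-of-field",
                                               "field-of-average"),
                            mask = NULL) {
  averaging_mode <- match.arg(averaging_mode)
  if (is.null(derived)) derived <- derive_fields(state)
  if (is.null(motion)) motion <- tank$motion %||% motion_spec(set_speed = NA)
  vol <- grid$vol
  if (is.null(mask)) mask <- matrix(TRUE, grid$nr, grid$nz)
  if (!any(mask)) stop("empty averaging mask")
  wsum <- sum(vol[mask])
  avg <- function(f) sum(f[mask] * vol[mask]) / wsum
  fluid <- state$fluid %||% fluid_properties()
  k_bar <- avg(state$k)
  eps_bar <- avg(derived$eps)
  gd_bar <- avg(derived$gamma_dot)
  om_bar <- avg(derived$omega)
  if (averaging_mode == "average-of-field") {
    tau_bar <- avg(derived$tau)
    lam_bar <- avg(derived$lambda_k)
  } else {
    mu_t_bar <- avg(derived$mu_t)
    tau_bar <- if (derived$tau_mode == "effective")
      (fluid$mu + mu_t_bar) * gd_bar else fluid$mu * gd_bar
    lam_bar <- kolmogorov_scale(eps_bar, fluid)
  }
  row <- data.frame(
    scale = if (!is.null(tank)) 1000 * tank$working_volume else NA_real_,
    speed = motion$set_speed,
    turbulent_energy = k_bar,
    shear_stress = tau_bar,
    kolmogorov = 1e6 * lam_bar,
    shear_rate = gd_bar,
    vorticity = om_bar,
    dissipation = eps_bar,
    averaging_mode = averaging_mode,
    tau_mode = derived$tau_mode,
    stringsAsFactors = FALSE)
  class(row) <- c("summary_row", class(row))
  row
}

#' Summarize a snapshot ensemble
#'
#' One [summarize_state()] row per snapshot plus their mean (simple mean of
#' the per-snapshot volume averages, representing the stroke cycle).
#'
#' @param ensemble A `snapshot_ensemble`.
#' @param tau_mode Shear-stress mode for the derived fields.
#' @param averaging_mode Passed to [summarize_state()].
#' @return A `summary_row` data frame; the last row (`position = "cycle"`)
#'   is the cycle mean.
#' @export
summarize_ensemble <- function(ensemble, tau_mode = "effective",
                               averaging_mode = "average-of-field") {
  rows <- lapply(ensemble$states, function(s)
    summarize_state(s, derived = derive_fields(s, tau_mode = tau_mode),
                    tank = ensemble$tank, motion = ensemble$motion,
                    averaging_mode = averaging_mode))
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1))
  cyc <- tab[1, , drop = FALSE]
  cyc[num] <- as.list(colMeans(tab[num]))
  tab$position <- paste0("snapshot", seq_len(nrow(tab)))
  cyc$position <- "cycle"
  out <- rbind(tab, cyc)
  class(out) <- c("summary_row", "data.frame")
  out
}

#' Write summary rows as CSV in the fixed column order
#'
#' Columns: Scale (L), Speed (mm s-1), Turbulent energy (m2 s-2),
#' Shear stress (Pa), Kolmogorov scale (um), Shear rate (s-1),
#' Vorticity (s-1), Dissipation of energy (m2 s-3).
#'
#' @param rows A `summary_row` data frame.
#' @param path Output path.
#' @export
write_summary_csv <- function(rows, path) {
  out <- data.frame(
    `Scale (L)` = rows$scale,
    `Speed (mm s-1)` = rows$speed,
    `Turbulent energy (m2 s-2)` = rows$turbulent_energy,
    `Shear stress (Pa)` = rows$shear_stress,
    `Kolmogorov scale (um)` = rows$kolmogorov,
    `Shear rate (s-1)` = rows$shear_rate,
    `Vorticity (s-1)` = rows$vorticity,
    `Dissipation of energy (m2 s-3)` = rows$dissipation,
    check.names = FALSE)
  out$`averaging mode` <- rows$averaging_mode
  out$`tau mode` <- rows$tau_mode
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
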