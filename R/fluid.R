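#' Fluid properties
#'
#' Constant-property incompressible working fluid. Defaults are the culture
#' medium used throughout: density 1005 kg/m^3, dynamic viscosity 3 mPa s.
#'
#' @param rho Density (kg/m^3), > 0.
#' @param mu Dynamic viscosity (Pa s), > 0.
#' @return Object of class `fluid_properties` with derived kinematic
#'   viscosity `nu = mu / rho` (m^2/s).
#' @export
fluid_properties <- function(rho = 1005, mu = 3e-3) {
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  structure(list(rho = rho, mu = mu, nu = mu / rho),
            class = "fluid_properties")
}

#' Realizable k-epsilon closure configuration
#'
#' Model constants and numerical floors for the realizable k-epsilon
#' closure. `c_mu_mode = "realizable"` uses the variable C_mu of the
#' realizable model (A0 = 4.04, As from the strain/rotation invariants);
#' `"constant"` uses the classical 0.09. The dissipation-equation sink is
#' `rho C2 eps^2 / (k + sqrt(nu eps))` by default; the variant with
#' `sqrt(mu eps)` in the denominator is selectable for comparison even
#' though it is not dimensionally homogeneous.
#'
#' @param c_mu_mode `"realizable"` or `"constant"`.
#' @param c_mu Value used in constant mode (default 0.09).
#' @param sigma_k,sigma_eps Turbulent Prandtl numbers for k and eps.
#' @param c2 Dissipation-equation constant (default 1.9).
#' @param c1_min Lower bound of C1 = max(c1_min, eta/(eta+5)) (default 0.43).
#' @param eps_denominator_mode `"sqrt_nu_eps"` (default) or `"sqrt_mu_eps"`.
#' @param k_min,eps_min Positivity floors (m^2/s^2, m^2/s^3).
#' @param turbulence Logical; `FALSE` gives a laminar solve (mu_t = 0,
#'   transport of k/eps skipped).
#' @param mu_t_ratio_max Cap on mu_t / mu for robustness.
#' @return Object of class `closure_config`.
#' @export
closure_config <- function(c_mu_mode = c("realizable", "constant"),
                           c_mu = 0.09, sigma_k = 1.0, sigma_eps = 1.2,
                           c2 = 1.9, c1_min = 0.43,
                           eps_denominator_mode = c("sqrt_nu_eps",
                                                    "sqrt_mu_eps"),
                           k_min = 1e-10, eps_min = 1e-12,
                           turbulence = TRUE, mu_t_ratio_max = 1e5) {
  c_mu_mode <- match.arg(c_mu_mode)
  eps_denominator_mode <- match.arg(eps_denominator_mode)
  vals <- c(c_mu, sigma_k, sigma_eps, c2, c1_min, k_min, eps_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all closure constants and floors must be positive")
  structure(list(c_mu_mode = c_mu_mode, c_mu = c_mu, sigma_k = sigma_k,
                 sigma_eps = sigma_eps, c2 = c2, c1_min = c1_min,
                 eps_denominator_mode = eps_denominator_mode,
                 k_min = k_min, eps_min = eps_min,
                 turbulence = turbulence, mu_t_ratio_max = mu_t_ratio_max),
            class = "closure_config")
}

#' Solver numerical controls
#'
#' @param max_iter Maximum SIMPLE outer iterations.
#' @param tol Normalized residual tolerance for convergence.
#' @param relax_u,relax_p,relax_ke Under-relaxation factors for momentum,
#'   pressure and the k/eps equations.
#' @param diverge_factor Abort when residuals exceed this multiple of their
#'   running minimum (after a grace period).
#' @param verbose Print residual history.
#' @return Object of class `solver_control`.
#' @export
solver_control <- function(max_iter = 500L, tol = 1e-5, relax_u = 0.7,
                           relax_p = 0.3, relax_ke = 0.5,
                           diverge_factor = 1e4, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1,
            relax_ke > 0, relax_ke <= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 relax_u = relax_u, relax_p = relax_p, relax_ke = relax_ke,
                 diverge_factor = diverge_factor, verbose = verbose),
            class = "solver_control")
}
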