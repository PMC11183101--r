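# independent scalar oracles for the pointwise formulas
oracle_mu_t <- function(k, eps, rho, c_mu) c_mu * rho * k * k / eps
oracle_tau <- function(mu, mu_t, gd) (mu + mu_t) * gd
oracle_lambda <- function(eps, nu) (nu^3 / eps)^(1 / 4)

test_that("turbulent viscosity matches hand evaluation on table inputs", {
  fl <- fluid_properties()
  cl <- closure_config(c_mu_mode = "constant")
  mt <- turbulent_viscosity(0.0113, 0.062, fl, cl)
  expect_equal(mt, 0.09 * 1005 * 0.0113^2 / 0.062, tolerance = 1e-12)
  expect_equal(mt, 0.1863, tolerance = 1e-3)
  # quadratic scaling in k
  expect_equal(turbulent_viscosity(0.0226, 0.062, fl, cl), 4 * mt,
               tolerance = 1e-12)
  expect_error(turbulent_viscosity(0, 0.062, fl, cl), "floors")
})

test_that("pointwise formulas agree with scalar oracles on random inputs", {
  set.seed(42)
  n <- 1e4
  k <- runif(n, 1e-6, 1)
  eps <- runif(n, 1e-8, 10)
  gd <- runif(n, 0, 100)
  fl <- fluid_properties()
  cl <- closure_config(c_mu_mode = "constant")
  mt <- turbulent_viscosity(k, eps, fl, cl)
  expect_equal(mt, oracle_mu_t(k, eps, fl$rho, 0.09), tolerance = 1e-12)
  tau <- shear_stress(gd, fl, mt, "effective")
  expect_equal(as.numeric(tau), oracle_tau(fl$mu, mt, gd), tolerance = 1e-12)
  lam <- kolmogorov_scale(eps, fl)
  expect_equal(lam, oracle_lambda(eps, fl$nu), tolerance = 1e-12)
})

test_that("Kolmogorov scale identities hold", {
  fl <- fluid_properties()
  expect_identical(kolmogorov_scale(fl$nu^3, fl), 1)
  # hand evaluation on the printed dissipation value
  expect_equal(kolmogorov_scale(0.062, fl), 1.439e-4, tolerance = 1e-3)
  # strict monotone decrease in eps
  eps <- sort(runif(50, 1e-6, 1))
  expect_true(all(diff(kolmogorov_scale(eps, fl)) < 0))
})

test_that("shear stress modes are both available and recorded", {
  fl <- fluid_properties()
  expect_equal(as.numeric(shear_stress(100, fl, mode = "molecular")), 0.3)
  expect_equal(as.numeric(shear_stress(0, fl, 0.5, "effective")), 0)
  tau <- shear_stress(10.5, fl, 0.1862832, "effective")
  expect_equal(as.numeric(tau), 1.9875, tolerance = 1e-3)
  expect_identical(attr(tau, "tau_mode"), "effective")
  expect_error(shear_stress(10, fl, mode = "effective"), "mu_t")
})

test_that("strain rate and vorticity recover closed forms", {
  g <- planar_grid(1, 1, 32, 32)
  f <- make_field(synthetic_field_spec("simple-shear", G = 5), g)
  gd <- strain_rate(f$state, g)
  om <- vorticity(f$state, g)
  expect_equal(max(abs(gd - 5)), 0, tolerance = 1e-10)
  expect_equal(max(abs(om - 5)), 0, tolerance = 1e-10)

  f <- make_field(synthetic_field_spec("solid-body-rotation", Omega = 2), g)
  expect_equal(max(abs(vorticity(f$state, g) - 4)), 0, tolerance = 1e-9)
  expect_equal(max(abs(strain_rate(f$state, g))), 0, tolerance = 1e-9)

  f <- make_field(synthetic_field_spec("uniform", u0 = 1, w0 = -2), g)
  expect_equal(max(abs(strain_rate(f$state, g))), 0, tolerance = 1e-12)
  expect_equal(max(abs(vorticity(f$state, g))), 0, tolerance = 1e-12)
})

test_that("difference operators converge at second order on a vortex", {
  errs_g <- errs_o <- c()
  for (n in c(16, 32, 64)) {
    g <- planar_grid(1, 1, n, n)
    f <- make_field(synthetic_field_spec("analytic-vortex", A = 0.05), g)
    errs_g <- c(errs_g, max(abs(strain_rate(f$state, g) -
                                  f$truth$gamma_dot)))
    errs_o <- c(errs_o, max(abs(vorticity(f$state, g) - f$truth$omega)))
  }
  expect_true(all(diff(errs_g) < 0))
  expect_true(all(diff(errs_o) < 0))
  ord_g <- log2(errs_g[-3] / errs_g[-1])
  ord_o <- log2(errs_o[-3] / errs_o[-1])
  expect_true(all(ord_g >= 1.9))
  expect_true(all(ord_o >= 1.9))
})

test_that("operators are linear in the velocity field", {
  g <- planar_grid(1, 1, 24, 24)
  f <- make_field(synthetic_field_spec("analytic-vortex", A = 0.03), g)
  s1 <- f$state
  s3 <- s1; s3$u <- 3 * s1$u; s3$w <- 3 * s1$w
  expect_equal(strain_rate(s3, g), 3 * strain_rate(s1, g), tolerance = 1e-12)
  expect_equal(vorticity(s3, g), 3 * vorticity(s1, g), tolerance = 1e-12)
})

test_that("summaries volume-average correctly in both modes", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 16)
  # uniform field: both modes reproduce the inputs exactly
  f <- make_field(synthetic_field_spec("uniform", k0 = 0.0113, eps0 = 0.062),
                  g)
  st <- f$state; st$grid <- g
  st$mu_t <- turbulent_viscosity(st$k, st$eps, st$fluid, st$closure)
  for (mode in c("average-of-field", "field-of-average")) {
    row <- summarize_state(st, grid = g, tank = tk, motion = tk$motion,
                           averaging_mode = mode)
    expect_equal(row$turbulent_energy, 0.0113, tolerance = 1e-12)
    expect_equal(row$dissipation, 0.062, tolerance = 1e-12)
    expect_equal(row$kolmogorov,
                 1e6 * kolmogorov_scale(0.062, st$fluid), tolerance = 1e-9)
    expect_equal(row$scale, 8)
  }
  # two-region weighted mean
  st2 <- st
  st2$k[] <- 0.01
  upper <- g$z > tk$liquid_height / 2
  st2$k[, upper] <- 0.03
  w <- sum(g$vol[, upper]) / sum(g$vol)
  row <- summarize_state(st2, grid = g, tank = tk, motion = tk$motion)
  expect_equal(row$turbulent_energy, 0.03 * w + 0.01 * (1 - w),
               tolerance = 1e-12)
  expect_error(summarize_state(st, grid = g, tank = tk,
                               mask = matrix(FALSE, g$nr, g$nz)),
               "empty")
})

test_that("average-of-field Kolmogorov dominates field-of-average (Jensen)", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 16)
  f <- make_field(synthetic_field_spec("uniform", k0 = 0.01, eps0 = 1), g)
  st <- f$state; st$grid <- g
  set.seed(7)
  st$eps <- matrix(rlnorm(g$nr * g$nz, meanlog = log(0.05), sdlog = 1),
                   g$nr, g$nz)
  st$mu_t <- turbulent_viscosity(st$k, st$eps, st$fluid, st$closure)
  raf <- summarize_state(st, grid = g, tank = tk, motion = tk$motion,
                         averaging_mode = "average-of-field")
  rfa <- summarize_state(st, grid = g, tank = tk, motion = tk$motion,
                         averaging_mode = "field-of-average")
  expect_gt(raf$kolmogorov, rfa$kolmogorov)
})

test_that("summary CSV carries the fixed column schema", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 16)
  f <- make_field(synthetic_field_spec("uniform", k0 = 0.01, eps0 = 0.05), g)
  st <- f$state; st$grid <- g
  st$mu_t <- turbulent_viscosity(st$k, st$eps, st$fluid, st$closure)
  row <- summarize_state(st, grid = g, tank = tk, motion = tk$motion)
  path <- tempfile(fileext = ".csv")
  write_summary_csv(row, path)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(got)[1:8],
                   c("Scale (L)", "Speed (mm s-1)",
                     "Turbulent energy (m2 s-2)", "Shear stress (Pa)",
                     "Kolmogorov scale (um)", "Shear rate (s-1)",
                     "Vorticity (s-1)", "Dissipation of energy (m2 s-3)"))
  expect_true(all(as.numeric(got[1, 3:8]) >= 0))
})
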