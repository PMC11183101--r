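test_that("laminar channel flows are recovered on a 64-cell grid", {
  ch <- solve_channel("couette", n = 64, U = 0.1)
  expect_true(ch$diagnostics$converged)
  expect_lt(ch$rel_err, 0.01)
  po <- solve_channel("poiseuille", n = 64, dpdz = -1)
  expect_true(po$diagnostics$converged)
  expect_lt(po$rel_err, 0.01)
  # profiles have the expected shapes
  expect_true(all(diff(ch$w) > 0))
  expect_equal(which.max(po$w), 32, tolerance = 1)
})

test_that("zero impeller speed returns the quiescent fixed point exactly", {
  tank <- build_tank("VerMES3", motion = motion_spec(set_speed = 0,
                                                     stroke = 60))
  g <- generate_grid(tank, 12, 16)
  cl <- closure_config()
  st <- solve_snapshot(g, closure = cl,
                       control = solver_control(max_iter = 30))
  expect_identical(max(abs(st$u)), 0)
  expect_identical(max(abs(st$w)), 0)
  expect_true(all(st$k == cl$k_min))
  expect_true(all(st$eps == cl$eps_min))
  expect_true(st$diagnostics$converged)
})

test_that("a turbulent tank snapshot converges with positive fields", {
  tank <- build_tank("VerMES3")
  g <- generate_grid(tank, 16, 24)
  st <- solve_snapshot(g, control = solver_control(max_iter = 600,
                                                   tol = 1e-5))
  expect_true(st$diagnostics$converged)
  expect_true(all(is.finite(st$u)))
  expect_true(all(is.finite(st$w)))
  expect_true(all(is.finite(st$k)))
  expect_true(all(is.finite(st$eps)))
  cl <- closure_config()
  expect_true(all(st$k >= cl$k_min))
  expect_true(all(st$eps >= cl$eps_min))
  # discrete mass conservation at convergence
  expect_lte(st$diagnostics$residuals[["continuity"]], 1e-5)
  # the impeller drives motion of the order of its own speed
  expect_gt(max(abs(st$w)), 0.1 * abs(st$impeller_velocity))
})

test_that("snapshot ensembles pair opposite stroke positions", {
  tank <- build_tank("VerMES3")
  g <- generate_grid(tank, 12, 16)
  ens <- run_snapshot_ensemble(g, control = solver_control(max_iter = 300,
                                                           tol = 1e-4))
  expect_length(ens$states, 2L)
  v <- vapply(ens$states, `[[`, numeric(1), "impeller_velocity")
  expect_equal(v[1], -v[2])
  p <- vapply(ens$states, `[[`, numeric(1), "impeller_position_mm")
  expect_equal(p[1], -p[2])
})

test_that("velocity scales linearly with impeller speed in the Stokes regime", {
  cl <- closure_config(turbulence = FALSE)
  mk <- function(v) {
    tank <- build_tank("VerMES3", motion = motion_spec(set_speed = v,
                                                       stroke = 60))
    g <- generate_grid(tank, 12, 16)
    solve_snapshot(g, closure = cl, motion = tank$motion,
                   control = solver_control(max_iter = 800, tol = 1e-9))
  }
  s1 <- mk(0.005); s2 <- mk(0.01)
  expect_lt(max(abs(2 * s1$w - s2$w)) / max(abs(s2$w)), 0.01)
  expect_lt(max(abs(2 * s1$u - s2$u)) / max(abs(s2$u)), 0.01)
})

test_that("opposite stroke snapshots mirror in a symmetric vessel", {
  # top surface replaced by a wall so the geometry is fore-aft symmetric
  tank <- build_tank("VerMES3")
  g <- generate_grid(tank, 12, 18)
  g$boundary_tags["north"] <- "wall"
  ens <- run_snapshot_ensemble(g, motion = tank$motion,
                               control = solver_control(max_iter = 1500,
                                                        tol = 1e-7))
  s1 <- ens$states[[1]]; s2 <- ens$states[[2]]
  mir <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_lt(max(abs(s2$w + mir(s1$w))) / max(abs(s1$w)), 1e-6)
  expect_lt(max(abs(s2$u - mir(s1$u))) / max(abs(s1$u)), 1e-6)
  expect_lt(max(abs(s2$k - mir(s1$k))) / max(abs(s1$k)), 1e-6)
})

test_that("solver input validation and divergence reporting work", {
  tank <- build_tank("VerMES3")
  g <- generate_grid(tank, 12, 16)
  expect_error(solve_snapshot(g, motion = tank$motion, position_index = 3),
               "out of range")
  expect_error(closure_config(k_min = -1), "positive")
  expect_error(solver_control(relax_u = 0), "relax_u")
})
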