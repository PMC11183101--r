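test_that("tank presets give the published working volumes", {
  t50 <- build_tank("VerMES50-2imp")
  expect_equal(t50$working_volume, 0.045)
  expect_length(t50$impellers, 2L)
  expect_equal(t50$motion$stroke, 60)

  t3 <- build_tank("VerMES3")
  expect_equal(t3$working_volume, 0.0024)
  t10 <- build_tank("VerMES10")
  expect_equal(t10$working_volume, 0.008)
  t3i <- build_tank("VerMES50-3imp")
  expect_length(t3i$impellers, 3L)

  expect_error(build_tank("VerMES9000"), "unknown preset")
})

test_that("explicit construction honours the cylinder identity", {
  tk <- build_tank(diameter = 0.1, aspect_ratio = 1.0)
  expect_equal(tk$liquid_height, 0.1)
  expect_equal(tk$working_volume, pi * 0.05^2 * 0.1, tolerance = 1e-12)
  # inconsistent triple rejected
  expect_error(tank_spec("bad", 0.01, 0.1, 0.1,
                         list(impeller_spec(0.05, 0.03))),
               "inconsistent")
})

test_that("scale_tank applies the cube-root length factor exactly", {
  tk <- build_tank("VerMES3")
  up <- scale_tank(tk, 0.008)
  f <- (0.008 / 0.0024)^(1 / 3)
  expect_equal(f, 1.49380, tolerance = 1e-5)
  expect_equal(up$diameter / tk$diameter, f, tolerance = 1e-12)
  expect_equal(up$liquid_height / tk$liquid_height, f, tolerance = 1e-12)
  expect_equal(up$working_volume, 0.008, tolerance = 1e-12)
  # geometric similarity of impeller placement
  for (i in seq_along(tk$impellers)) {
    expect_equal(up$impellers[[i]]$center_height /
                   tk$impellers[[i]]$center_height, f, tolerance = 1e-12)
    expect_equal(up$impellers[[i]]$disc_radius /
                   tk$impellers[[i]]$disc_radius, f, tolerance = 1e-12)
  }
  # stroke unchanged unless flagged
  expect_equal(up$motion$stroke, tk$motion$stroke)
  up2 <- scale_tank(tk, 0.045)
  expect_equal(up2$diameter / tk$diameter, (45 / 2.4)^(1 / 3),
               tolerance = 1e-12)
  # identity case
  same <- scale_tank(tk, tk$working_volume)
  expect_equal(same$diameter, tk$diameter, tolerance = 1e-14)
  expect_error(scale_tank(tk, -1), "target_volume")
})

test_that("grids conserve volume and refuse degenerate resolutions", {
  tk <- build_tank("VerMES3")
  g <- generate_grid(tk, 32, 48)
  expect_lt(abs(sum(g$vol) - 0.0024) / 0.0024, 1e-3)
  expect_true(all(g$vol > 0))
  g2 <- generate_grid(tk, 64, 96)
  expect_equal(sum(g2$vol), sum(g$vol), tolerance = 1e-12)
  expect_identical(g2$boundary_tags, g$boundary_tags)
  expect_error(generate_grid(tk, 4, 48), "resolution")
  tiny <- build_tank(diameter = 0.1, aspect_ratio = 1.2,
                     disc_radius_frac = 0.02)
  expect_error(generate_grid(tiny, 8, 8), "too coarse")
})

test_that("boundary tags partition the boundary", {
  g <- generate_grid(build_tank("VerMES10"), 12, 16)
  expect_setequal(names(g$boundary_tags),
                  c("west", "east", "south", "north"))
  expect_identical(unname(g$boundary_tags["west"]), "axis")
  expect_identical(unname(g$boundary_tags["north"]), "liquid_surface")
})

test_that("impeller positions follow the waveform at sampled phases", {
  mo <- motion_spec(set_speed = 300, stroke = 60, n_snapshots = 2L)
  pos <- impeller_positions(mo)
  expect_equal(pos$offset_mm, c(30, -30))
  expect_equal(pos$velocity_mm_s, c(-300, 300))

  mo4 <- motion_spec(set_speed = 200, stroke = 60, waveform = "sinusoidal",
                     n_snapshots = 4L)
  p4 <- impeller_positions(mo4)
  expect_equal(p4$offset_mm, 30 * sin(2 * pi * (1:4 - 0.5) / 4))
  expect_equal(p4$velocity_mm_s,
               200 * pi / 2 * cos(2 * pi * (1:4 - 0.5) / 4))

  expect_error(motion_spec(n_snapshots = 1), "n_snapshots")
  expect_error(motion_spec(stroke = -5), "stroke")
})

test_that("grid_at_position tags discs and sweep envelopes", {
  tk <- build_tank("VerMES3")
  g <- generate_grid(tk, 16, 24)
  g1 <- grid_at_position(g, tk$motion, 1)
  g2 <- grid_at_position(g, tk$motion, 2)
  expect_true(any(g1$solid))
  expect_false(identical(g1$solid, g2$solid))
  # solid always inside the sweep envelope
  expect_true(all(g1$swept[g1$solid]))
  expect_true(all(g2$swept[g2$solid]))
  expect_equal(nrow(g1$impeller_faces), length(tk$impellers))
  expect_error(grid_at_position(g, tk$motion, 5), "out of range")
})
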