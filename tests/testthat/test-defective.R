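make_patchy_state <- function(grid, patches, k_hi = 0.02, k_lo = 1e-4) {
  f <- make_field(synthetic_field_spec("patchy-turbulence", patches = patches,
                                       k_hi = k_hi, k_lo = k_lo), grid)
  f$state$grid <- grid
  f
}

test_that("uniform fields classify all-or-nothing", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 16)
  spec <- threshold_spec("k", "absolute", 0.005)
  hi <- make_field(synthetic_field_spec("uniform", k0 = 0.01), g)$state
  hi$grid <- g
  m <- classify_active(hi, g, spec)
  expect_true(all(m$active))
  lo <- make_field(synthetic_field_spec("uniform", k0 = 0.001), g)$state
  lo$grid <- g
  m <- classify_active(lo, g, spec)
  expect_false(any(m$active))
  d <- merge_defective(list(hi, hi), g, spec)
  expect_equal(d$defective_volume_L, 0)
})

test_that("constructed patch masks are recovered cell-exactly", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 16, 24)
  f <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0, 0.5))))
  m <- classify_active(f$state, g, threshold_spec("k", "absolute", 0.01))
  expect_identical(m$active, f$truth$active)
  # brute-force fraction against the generator's ground truth
  expect_equal(sum(g$vol[!m$active]) / sum(g$vol),
               f$truth$defective_fraction, tolerance = 1e-12)
  expect_error(classify_active(f$state, g,
                               threshold_spec("mu_t", "absolute", 1)),
               "not present")
})

test_that("merging intersects inactive sets (half and three-quarter case)", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 16, 24)
  a <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0, 0.5))))
  b <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0, 0.75))))
  spec <- threshold_spec("k", "absolute", 0.01)
  d <- merge_defective(list(a$state, b$state), g, spec)
  expect_equal(d$defective_fraction, 0.25, tolerance = 1e-12)
  # brute-force intersection oracle
  brute <- !(a$truth$active | b$truth$active)
  expect_identical(d$defective, brute)
  # idempotence: duplicating a snapshot changes nothing
  d2 <- merge_defective(list(a$state, b$state, b$state), g, spec)
  expect_equal(d2$defective_fraction, d$defective_fraction)
  # any fully-active snapshot clears the defective space
  full <- make_field(synthetic_field_spec("uniform", k0 = 1), g)$state
  full$grid <- g
  d3 <- merge_defective(list(a$state, full), g, spec)
  expect_equal(d3$defective_volume_L, 0)
  # conservation per snapshot: active + inactive = working volume
  act <- sum(g$vol[d$masks[[1]]$active])
  inact <- sum(g$vol[!d$masks[[1]]$active])
  expect_equal(act + inact, sum(g$vol), tolerance = 1e-12)
})

test_that("complementary patches leave no defective space", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 16, 24)
  lower <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0, 0.5))))
  upper <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0.5, 1))))
  made <- make_ensemble(list(
    synthetic_field_spec("patchy-turbulence",
                         patches = list(list(r = c(0, 1), z = c(0, 0.5)))),
    synthetic_field_spec("patchy-turbulence",
                         patches = list(list(r = c(0, 1), z = c(0.5, 1))))),
    g)
  expect_equal(made$expected$defective_fraction, 0)
  d <- merge_defective(list(lower$state, upper$state), g,
                       threshold_spec("k", "absolute", 0.01))
  expect_equal(d$defective_fraction, 0)
})

test_that("defective volume is monotone in threshold and snapshots", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 18)
  set.seed(11)
  for (rep in 1:5) {
    states <- lapply(1:3, function(i) {
      z0 <- runif(1, 0, 0.5)
      make_patchy_state(g, list(list(r = c(0, 1),
                                     z = c(z0, z0 + 0.4))))$state
    })
    # threshold monotonicity
    cuts <- c(0.001, 0.005, 0.019, 0.05)
    vols <- vapply(cuts, function(cv)
      merge_defective(states, g,
                      threshold_spec("k", "absolute", cv))$defective_volume_L,
      numeric(1))
    expect_true(all(diff(vols) >= 0))
    # snapshot monotonicity: adding snapshots never grows the space
    v1 <- merge_defective(states[1], g,
                          threshold_spec("k", "absolute", 0.01))
    v2 <- merge_defective(states[1:2], g,
                          threshold_spec("k", "absolute", 0.01))
    v3 <- merge_defective(states, g, threshold_spec("k", "absolute", 0.01))
    expect_lte(v2$defective_volume_L, v1$defective_volume_L)
    expect_lte(v3$defective_volume_L, v2$defective_volume_L)
  }
})

test_that("relative thresholds use the ensemble mean and are echoed", {
  tk <- build_tank("VerMES10")
  g <- generate_grid(tk, 12, 16)
  a <- make_patchy_state(g, list(list(r = c(0, 1), z = c(0, 0.5))),
                         k_hi = 0.02, k_lo = 1e-4)$state
  spec <- threshold_spec("k", "relative-to-mean", 0.1)
  d <- merge_defective(list(a, a), g, spec)
  mean_k <- sum(a$k * g$vol) / sum(g$vol)
  expect_equal(d$cutoff, 0.1 * mean_k, tolerance = 1e-12)
  expect_identical(d$spec$mode, "relative-to-mean")
  expect_error(threshold_spec(value = -1), "value")
})

test_that("compare_scales reports the trend verdict", {
  fake <- function(scale, frac) structure(
    list(defective_volume_L = frac * scale, defective_fraction = frac,
         working_volume_L = scale, scale_L = scale,
         tank_label = sprintf("%gL", scale)), class = "defective_space")
  inc <- compare_scales(list(fake(3, 0.05), fake(10, 0.08), fake(50, 0.20)))
  expect_identical(inc$verdict, "increasing")
  expect_equal(inc$table$scale_L, c(3, 10, 50))
  flat <- compare_scales(list(fake(3, 0.05), fake(10, 0.05)))
  expect_identical(flat$verdict, "non-increasing/flat")
  expect_error(compare_scales(list(fake(3, 0.1), fake(3, 0.2))),
               "duplicate")
})
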