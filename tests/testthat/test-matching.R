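test_that("the published two-impeller table selects 300 mm/s for 50 L", {
  tab <- reference_summary_table()
  ref <- tab[tab$scale == 10, ]
  cand <- tab[tab$scale == 50, ]
  m <- match_speed(ref, cand)
  expect_equal(m$selected_speed, 300)
  expect_true(m$selected_within_band)
  # the 200 and 400 rows are both outside the 10% band
  expect_false(m$within_band[cand$speed == 200])
  expect_false(m$within_band[cand$speed == 400])
})

test_that("the three-impeller summary matches the 10 L optimum at 200", {
  ref <- reference_summary_table()[2, ]
  cand <- reference_summary_three_impeller()
  m <- match_speed(ref, cand)
  expect_equal(m$selected_speed, 200)
  expect_true(m$selected_within_band)
  expect_lt(m$dev_k, 0.10)
  expect_lt(m$dev_tau, 0.10)
})

test_that("scores behave as a metric on the matched quantities", {
  ref <- data.frame(speed = 100, turbulent_energy = 0.01, shear_stress = 3)
  # identical candidate scores zero and is selected
  cand <- rbind(data.frame(speed = 150, turbulent_energy = 0.02,
                           shear_stress = 5), cbind(ref))
  m <- match_speed(ref, cand)
  expect_equal(m$scores[2], 0)
  expect_equal(m$selected_speed, 100)
  # permutation invariance
  m2 <- match_speed(ref, cand[c(2, 1), ])
  expect_equal(m2$selected_speed, m$selected_speed)
  expect_equal(sort(m2$scores), sort(m$scores))
  # scale invariance
  sc <- function(d, a) transform(d, turbulent_energy = a * turbulent_energy,
                                 shear_stress = a * shear_stress)
  m3 <- match_speed(sc(ref, 7), sc(cand, 7))
  expect_equal(m3$scores, m$scores, tolerance = 1e-12)
  # ties break toward the lower speed
  tie <- data.frame(speed = c(400, 200),
                    turbulent_energy = c(0.012, 0.008),
                    shear_stress = c(3.6, 2.4))
  mt <- match_speed(ref, tie)
  expect_equal(mt$selected_speed, 200)
  expect_error(match_speed(ref, cand[0, ]), "candidate")
  expect_error(match_speed(transform(ref, turbulent_energy = 0), cand),
               "reference")
})

test_that("speed calibration interpolates monotonically with clamping", {
  cal <- speed_calibration(c(150, 300), c(100.7, 130.4))
  expect_equal(real_speed(150, cal), 100.7)
  expect_equal(real_speed(300, cal), 130.4)
  expect_equal(real_speed(225, cal), 115.55)
  # clamped beyond the table (plateau)
  expect_equal(real_speed(400, cal), 130.4)
  expect_equal(real_speed(100, cal), 100.7)
  # identity with empty calibration
  expect_equal(real_speed(250), 250)
  # monotone non-decreasing over a query sweep
  q <- real_speed(seq(100, 400, by = 10), cal)
  expect_true(all(diff(q) >= 0))
  expect_error(speed_calibration(c(300, 150), c(1, 2)), "increasing")
  expect_error(speed_calibration(c(150, 300), c(5, 2)), "non-decreasing")
})
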