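tr <- fixture_traits

test_that("subsistence concentrations follow R* = K a / (y Vm - a)", {
  expect_equal(rstar(tr, 1, "OM"), 0.1 * 0.04 / (0.15 * 1.377 - 0.04),
               tolerance = 1e-12)
  expect_equal(rstar(tr, 4, "OM"), 0.0108, tolerance = 1e-2)
  expect_equal(rstar(tr, "B6", "NO2"), 0.16 / (0.016 * 50.8 - 0.04),
               tolerance = 1e-12)
  # no mortality, any concentration suffices
  tr0 <- omz_traits(dilution = 0)
  expect_equal(rstar(tr0, 1, "OM"), 0)
  # beyond the persistence condition R* is undefined
  trbad <- tr; trbad$a <- 0.25
  expect_error(rstar(trbad, 1, "OM"), "cannot persist")
  expect_error(rstar(tr, 5, "OM"), "does not use")
})

test_that("consumption vectors are the yield ratios of the trait table", {
  expect_equal(consumption_vector(tr, 1)$value, 0.15 / 0.011, tolerance = 1e-12)
  expect_equal(consumption_vector(tr, 2)$value, 0.148 / 0.023, tolerance = 1e-12)
  expect_equal(consumption_vector(tr, 3)$value, 0.197 / 0.024, tolerance = 1e-12)
  expect_equal(consumption_vector(tr, 4)$value, 0.298 / 0.013, tolerance = 1e-12)
  expect_error(consumption_vector(tr, 5), "anammox")
})

test_that("consortium vectors steepen OM demand relative to the feeder", {
  c1 <- consumption_vector(tr, 1)$value
  c3 <- consumption_vector(tr, 3)$value
  c13 <- consortium_vector(tr, 1, 3)$value
  expect_equal(c13, c1 / (1 + c1 / c3), tolerance = 1e-12)
  expect_equal(c13, 5.124, tolerance = 1e-3)
  expect_lt(c13, c1)

  c24 <- consortium_vector(tr, 2, 4)$value
  expect_equal(c24, 5.024, tolerance = 1e-3)
  expect_lt(c24, consumption_vector(tr, 2)$value)

  # an unconstrained recipient leaves the feeder vector unchanged:
  # c_f / (1 + c_f / c_r) -> c_f as c_r -> infinity
  cr <- 10^seq(2, 8, by = 2)
  expect_true(all(abs(c1 / (1 + c1 / cr) - c1) < c1^2 / cr + 1e-12))

  expect_error(consortium_vector(tr, 1, 4), "does not consume")
})

test_that("the feeder-threshold criterion scales as a y / mu", {
  expect_equal(feeder_threshold(tr, 1, 5, 0.04), 0.011, tolerance = 1e-12)
  expect_equal(feeder_threshold(tr, 1, 3, 0.04), 0.011, tolerance = 1e-12)
  expect_equal(feeder_threshold(tr, 2, 4, 0.04), 0.023, tolerance = 1e-12)
  # inverse proportionality in the recipient growth rate
  expect_equal(feeder_threshold(tr, 1, 5, 0.08),
               feeder_threshold(tr, 1, 5, 0.04) / 2, tolerance = 1e-12)
  expect_error(feeder_threshold(tr, 1, 5, 0), "positive")
  expect_error(feeder_threshold(tr, 1, 4), "does not consume")
})

test_that("direct ZNGIs are L-shaped corners at the subsistence pair", {
  z1 <- zngi(tr, 1, c("OM", "NO3"))
  expect_equal(unname(z1$corner), c(rstar(tr, 1, "OM"), rstar(tr, 1, "NO3")))
  # tabulated values (rounded yields): corner near (0.024, 0.295)
  expect_equal(unname(z1$corner), c(0.024, 0.295), tolerance = 0.05)
  expect_equal(nrow(z1$vertices), 3)  # arm, corner, arm

  z3 <- zngi(tr, 3, c("OM", "NO2"))
  expect_equal(unname(z3$corner), c(0.0172, 0.138), tolerance = 0.02)
  expect_error(zngi(tr, 3, c("OM", "NO3")), "does not use")
})

test_that("the derived anammox boundary lies above its feeder's", {
  z5 <- zngi(tr, 5, c("OM", "NO3"), s2 = c(10, 30))
  # bisection must recover the closed-form inversion of the threshold:
  # B1 is OM-limited on this boundary, so s1* = R*_1,OM + Bthr / y_1,OM
  s1_expected <- rstar(tr, 1, "OM") + feeder_threshold(tr, 1, 5) / 0.15
  expect_equal(z5$vertices$OM, rep(s1_expected, 2), tolerance = 1e-6)
  # strictly above B1's own persistence boundary at every NO3 level
  expect_true(all(z5$vertices$OM > rstar(tr, 1, "OM")))
})
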