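tr <- fixture_traits

test_that("potential growth saturates in the resource concentration", {
  # half-saturation: R = K gives y*Vm/2
  R <- c(0.1, 0, 0, 0, 0)
  expect_equal(potential_growth(tr, R, 1, "OM"), 0.15 * 1.377 / 2,
               tolerance = 1e-12)
  # zero resource, zero growth
  expect_equal(potential_growth(tr, numeric(5), 1, "OM"), 0)
  # saturation limit y*Vm
  R <- c(1e9, 0, 0, 0, 0)
  expect_equal(potential_growth(tr, R, 1, "OM"), 0.20655, tolerance = 1e-6)
  # undefined on unused pairs
  expect_error(potential_growth(tr, R, 1, "NO2"), "does not use")
})

test_that("potential growth is non-decreasing in the resource", {
  set.seed(11)
  for (rep in 1:20) {
    i <- sample(1:7, 1)
    j <- sample(which(tr$A[i, ] == 1L), 1)
    Rvals <- sort(runif(10, 0, 50))
    pot <- vapply(Rvals, function(r) {
      R <- numeric(5); R[j] <- r
      potential_growth(tr, R, i, j)
    }, numeric(1))
    expect_true(all(diff(pot) >= 0))
  }
})

test_that("realized growth follows Liebig's law of the minimum", {
  # B1 with saturating OM and NO3 exactly at subsistence: growth = dilution
  R <- c(1e6, rstar(tr, 1, "NO3"), 0, 0, 0)
  g <- realized_growth(tr, R, 1)
  expect_equal(g$rate, tr$a, tolerance = 1e-9)
  expect_equal(g$limiting, 2L)

  # essential resources are non-substitutable: no NO2, no anammox growth
  R <- c(0, 0, 0, 0, 100)
  expect_equal(realized_growth(tr, R, 5)$rate, 0)

  # both resources at R*: colimitation tie, lowest resource index reported
  R <- c(rstar(tr, 1, "OM"), rstar(tr, 1, "NO3"), 0, 0, 0)
  g <- realized_growth(tr, R, 1)
  expect_equal(g$rate, tr$a, tolerance = 1e-9)
  expect_true(g$colimited)
  expect_equal(g$limiting, 1L)
})

test_that("excretion routes reduced nitrogen per the stoichiometry", {
  e1 <- excretion_rates(tr, 0.04, 1)
  expect_equal(unname(e1["NO2"]), 0.04 / 0.011, tolerance = 1e-12)
  # NH4 regeneration is the non-assimilated share of OM-N uptake
  expect_equal(unname(e1["NH4"]), 0.04 * (1 / 0.15 - 1), tolerance = 1e-12)
  expect_equal(unname(e1["NH4"]) / (0.04 / 0.15), 1 - 0.15, tolerance = 1e-12)
  expect_equal(unname(e1[c("OM", "NO3", "N2O")]), c(0, 0, 0))

  e2 <- excretion_rates(tr, 0.04, 2)
  expect_equal(unname(e2["N2O"]), 0.04 / 0.023, tolerance = 1e-12)
  e6 <- excretion_rates(tr, 0.1, 6)
  expect_equal(unname(e6["N2O"]), 0.1 / 0.016, tolerance = 1e-12)

  # anammox excretes nothing
  expect_equal(unname(excretion_rates(tr, 0.3, 5)), rep(0, 5))
})

test_that("realized uptake is slaved to the limiting resource", {
  set.seed(21)
  for (rep in 1:10) {
    B <- runif(7, 0, 1); R <- runif(5, 0, 10)
    fl <- flux_record(tr, B, R)
    for (i in 1:7) {
      used <- which(tr$A[i, ] == 1L)
      # Vr * y identical across used resources and equal to mu
      expect_equal(unname(fl$Vr[i, used] * tr$Y[i, used]),
                   rep(unname(fl$mu[i]), length(used)), tolerance = 1e-12)
      expect_equal(unname(fl$Vr[i, -used]), rep(0, 5 - length(used)))
      # per-heterotroph nitrogen closure: OM uptake = growth + NH4 excretion
      if (i != 5) {
        expect_equal(fl$Vr[i, 1], unname(fl$mu[i]) + fl$E[i, 5],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the washout state is a fixed point", {
  s <- supply_spec(OM = 2, NO3 = 15)
  d <- community_rhs(tr, numeric(7), s, s)
  expect_equal(unname(d$dB), rep(0, 7))
  expect_equal(unname(d$dR), rep(0, 5))
})

test_that("the closed-form single-species equilibrium annihilates the rhs", {
  s <- c(1, 30, 0, 0, 0)
  cf <- closed_form_equilibrium(tr, 1, s)
  d <- community_rhs(tr, cf$B, cf$R, s)
  expect_lt(max(abs(c(d$dB, d$dR))), 1e-10)
})

test_that("the global nitrogen budget closes at arbitrary states", {
  set.seed(31)
  s <- c(5, 20, 0, 0, 0)
  for (rep in 1:25) {
    B <- runif(7, 0, 2); R <- runif(5, 0, 20)
    expect_lt(nitrogen_budget_residual(tr, B, R, s), 1e-10)
  }
})

test_that("gas fluxes follow the pathway stoichiometry", {
  # no biomass, no gas
  g0 <- gas_fluxes(tr, numeric(7), c(1, 1, 1, 1, 1))
  expect_equal(unname(g0), c(0, 0, 0))

  # anammox at equilibrium growth: N2 = (a/y_NO2 + a/y_NH4 - a) * B5
  B <- numeric(7); B[5] <- 0.2
  R <- c(0, 0, rstar(tr, 5, "NO2"), 0, 1e6)
  g <- gas_fluxes(tr, B, R)
  a <- tr$a
  expect_equal(unname(g["N2"]), (a / 0.011 + a / 0.013 - a) * 0.2,
               tolerance = 1e-9)

  # B1 + B2 community: N2O produced, nothing consumes it, no N2
  B <- c(0.1, 0.1, 0, 0, 0, 0, 0)
  R <- c(1, 1, 0, 0, 0)
  g <- gas_fluxes(tr, B, R)
  expect_equal(unname(g["N2"]), 0)
  expect_gt(g["N2O_prod"], 0)
  expect_equal(unname(g["N2O_cons"]), 0)
})

test_that("the rhs rejects corrupted states", {
  expect_error(community_rhs(tr, c(-1e-6, rep(0, 6)), rep(1, 5), rep(1, 5)),
               "integrity")
})
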