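tr <- fixture_traits

test_that("the washout state stays fixed under integration", {
  s <- supply_spec(OM = 1, NO3 = 30)
  traj <- simulate_chemostat(tr, list(B = numeric(7), R = s), s,
                             times = c(0, 500, 1000))
  final <- as.numeric(traj[nrow(traj), -1])
  expect_equal(final, c(numeric(7), unname(s)), tolerance = 1e-10)
})

test_that("a lone NO3->NO2 denitrifier reaches its chemostat balance", {
  eq <- find_equilibrium(tr, c(1, 30), subsystem = 1)
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-8)
  expect_equal(classify_community(eq), "B1")
  # OM drawn down to subsistence, biomass = y (s - R*), NO3 residual
  expect_equal(unname(eq$state$R["OM"]), rstar(tr, 1, "OM"), tolerance = 1e-4)
  expect_equal(unname(eq$state$B["B1"]), 0.15 * (1 - rstar(tr, 1, "OM")),
               tolerance = 1e-4)
  expect_equal(unname(eq$state$R["NO3"]), 30 - eq$state$B[["B1"]] / 0.011,
               tolerance = 1e-4)
  expect_equal(eq$limiting[1], 1L)
  # growth balances dilution for every persistent type
  expect_lt(max(abs(eq$fluxes$mu[eq$persistent] - tr$a)), 1e-6)
})

test_that("numerical equilibria match the closed-form oracle", {
  set.seed(42)
  for (i in 1:7) {
    for (rep in 1:3) {
      s <- random_feasible_supply(tr, i)
      cf <- closed_form_equilibrium(tr, i, s)
      eq <- find_equilibrium(tr, s, subsystem = i)
      expect_true(eq$converged)
      expect_equal(unname(eq$state$B), unname(cf$B), tolerance = 1e-4)
      expect_equal(unname(eq$state$R), unname(cf$R), tolerance = 1e-4)
      if (cf$persistent) expect_equal(eq$limiting[i], cf$limiting)
    }
  }
})

test_that("infeasible supply washes a species out", {
  # OM inflow below the subsistence concentration
  cf <- closed_form_equilibrium(tr, 1, c(0.01, 30, 0, 0, 0))
  expect_false(cf$persistent)
  expect_equal(unname(cf$R), c(0.01, 30, 0, 0, 0))
  eq <- find_equilibrium(tr, c(0.01, 30), subsystem = 1)
  expect_equal(classify_community(eq), "none")

  # a recipient without its feeder cannot persist (no N2O source)
  cf4 <- closed_form_equilibrium(tr, 4, c(10, 0, 0, 0, 0))
  expect_false(cf4$persistent)
  eq4 <- find_equilibrium(tr, c(10, 0), subsystem = 4)
  expect_equal(classify_community(eq4), "none")
})

test_that("every persistent type sits at its R* on its limiting resource", {
  for (s in list(c(1, 30), c(3, 30), c(6, 30))) {
    eq <- find_equilibrium(tr, s, subsystem = c(1, 2))
    expect_true(eq$converged)
    for (i in which(eq$persistent)) {
      j <- eq$limiting[i]
      expect_equal(unname(eq$state$R[j]), rstar(tr, i, j), tolerance = 1e-4)
    }
  }
})

test_that("the nitrogen budget holds along whole trajectories", {
  s <- c(5, 25, 0, 0, 0)
  B0 <- rep(1e-3, 7)
  traj <- simulate_chemostat(tr, list(B = B0, R = s), s,
                             times = seq(0, 2000, by = 100))
  for (k in seq_len(nrow(traj))) {
    B <- as.numeric(traj[k, 2:8]); R <- as.numeric(traj[k, 9:13])
    expect_lt(nitrogen_budget_residual(tr, B, R, s), 1e-8)
  }
})

test_that("pruning an extinct type does not change the surviving community", {
  # B2 goes extinct against B1 at low OM:NO3 supply
  eq_all <- find_equilibrium(tr, c(1, 30), subsystem = c(1, 2))
  expect_equal(classify_community(eq_all), "B1")
  eq_b1 <- find_equilibrium(tr, c(1, 30), subsystem = 1)
  expect_equal(unname(eq_all$state$B), unname(eq_b1$state$B), tolerance = 1e-4)
  expect_equal(unname(eq_all$state$R), unname(eq_b1$state$R), tolerance = 1e-4)
})

test_that("trajectories export to a long table that preserves the values", {
  s <- c(1, 30, 0, 0, 0)
  traj <- simulate_chemostat(tr, list(B = c(1e-3, rep(0, 6)), R = s), s,
                             times = c(0, 100, 1000))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, tmp)
  long <- read.csv(tmp)
  expect_setequal(unique(long$variable), c(omz_types, omz_resources))
  b1 <- long$value[long$variable == "B1" & long$time == 1000]
  expect_equal(b1, traj$B1[traj$time == 1000], tolerance = 1e-10)
})

test_that("nonstationary outcomes are flagged, not silently reported", {
  eq <- find_equilibrium(tr, c(6, 30), subsystem = c(1, 2), horizon = 10,
                         residual_tol = 1e-14)
  expect_false(eq$converged)
  expect_equal(classify_community(eq), "nonstationary")
})
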