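test_that("trajectories are seed-deterministic and jump along stoichiometry", {
  bd <- crn_fixture("birth_death")
  t1 <- ssa(bd, 0, 30, seed = 99)
  t2 <- ssa(bd, 0, 30, seed = 99)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  expect_false(identical(t1$states, ssa(bd, 0, 30, seed = 100)$states))

  for (net in list(bd, crn_fixture("dimerization_29"))) {
    tr <- ssa(net, rep(0, n_species(net)), 20, seed = 5)
    Z <- stoichiometry_matrix(net)
    jumps <- diff(tr$states)
    for (r in seq_len(nrow(jumps))) {
      match_col <- apply(Z, 2, function(z) all(z == jumps[r, ]))
      expect_true(any(match_col))
    }
  }

  # the R loop used for bounded propensities is seed-deterministic too
  tg <- crn_fixture("toggle_switch_35")
  s1 <- ssa(tg, rep(0, 4), 10, seed = 3)
  s2 <- ssa(tg, rep(0, 4), 10, seed = 3)
  expect_identical(s1$states, s2$states)
})

test_that("stopping reasons cover absorption, explosion and horizon", {
  dead <- reaction_network("X", list(
    reaction("d", reactants = c(X = 1), rate = 1)))
  tr <- ssa(dead, 5, 100, seed = 1)
  expect_equal(tr$stopped_reason, "absorbed")
  expect_equal(unname(tr$final_state), 0)

  none <- reaction_network("X", list())
  tr <- ssa(none, 3, 10, seed = 1)
  expect_equal(tr$stopped_reason, "absorbed")
  expect_equal(time_average(tr), 3)

  boom <- reaction_network("X", list(
    reaction("a", reactants = c(X = 1), products = c(X = 2), rate = 5)))
  tr <- ssa(boom, 1, 1000, seed = 2, propensity_cap = 1e4)
  expect_equal(tr$stopped_reason, "explosion_guard")

  tr <- ssa(crn_fixture("birth_death"), 0, 5, seed = 4)
  expect_equal(tr$stopped_reason, "horizon")
})

test_that("birth-death sampling matches the Poisson stationary law", {
  bd <- crn_fixture("birth_death")
  em <- ensemble_moments(bd, 0, n_paths = 2000, times = c(25, 50), n_max = 2,
                        seed = 21)
  m <- em$mean[2, 1]; se <- em$se[2, 1]
  expect_lt(abs(m - 2), 3 * se + 1e-9)
  m2 <- em$moments[[2]]$mean[2, 1]; se2 <- em$moments[[2]]$se[2, 1]
  expect_lt(abs(m2 - 6), 3 * se2 + 1e-9)

  # single long run: ergodic time-average converges to the mean
  tr <- ssa(bd, 0, 1e4, seed = 8, times = numeric(0), burn_in = 100)
  expect_lt(abs(tr$time_average - 2), 0.1)
})

test_that("the deterministic rate equations integrate and find equilibria", {
  bd <- crn_fixture("birth_death")
  sol <- rre(bd, 0, 10)
  x <- sol[, "X"]
  expect_true(all(diff(x) >= -1e-9))           # monotone approach
  expect_equal(unname(x[length(x)]), 2, tolerance = 1e-4)

  # globally stable pair: five initial conditions all reach (k3/k2, k1/k3)
  up <- crn_fixture("unstable_pair_26")
  for (x0 in list(c(1, 1), c(5, 1), c(1, 5), c(4, 4), c(0.5, 2))) {
    sol <- rre(up, x0, 200)
    fin <- attr(sol, "final")
    eq <- rre_equilibrium(up, fin)
    expect_equal(unname(eq$x), c(1, 1), tolerance = 1e-5)
    expect_true(eq$stable)
  }

  # bistable well: lower fixed point stable, upper unstable by the Jacobian
  wj <- crn_fixture("well_jumping_22")
  det_roots <- sort(Re(polyroot(c(600, -300, 30))))
  lo <- rre_equilibrium(wj, det_roots[1])
  hi <- rre_equilibrium(wj, det_roots[2])
  expect_true(lo$stable)
  expect_false(hi$stable)
  sol <- rre(wj, 2, 50)
  expect_equal(unname(attr(sol, "final")), det_roots[1], tolerance = 1e-4)
})

test_that("scalar drift roots separate the stable well from the escape region", {
  bd <- crn_fixture("birth_death")
  r <- drift_roots_1d(bd)
  expect_equal(r$roots, 2)
  expect_equal(r$sign_beyond_largest, -1)

  wj <- crn_fixture("well_jumping_22")
  r <- drift_roots_1d(wj)
  expect_equal(length(r$roots), 2)
  expect_true(all(r$roots > 0))
  expect_equal(r$sign_beyond_largest, 1)
  expect_equal(r$signs, c(1, -1, 1))
  # falling factorial: the stochastic escape threshold exceeds the
  # deterministic one
  det_hi <- max(Re(polyroot(c(600, -300, 30))))
  expect_gt(max(r$roots), det_hi)
  # companion-matrix oracle for the root values
  comp <- polyroot(r$coefs)
  expect_equal(sort(r$roots), sort(Re(comp[abs(Im(comp)) < 1e-8])),
               tolerance = 1e-9)
})

test_that("the large-population limit approaches the rate equations", {
  for (omega in c(100, 10000)) {
    net <- crn_fixture("birth_death", list(k_birth = 2 * omega, k_death = 1))
    em <- ensemble_moments(net, 0, n_paths = 30, times = 10, n_max = 1,
                           seed = 31, max_events = 1e7)
    scaled <- em$mean[1, 1] / omega
    rre_val <- 2 * (1 - exp(-10))
    expect_lt(abs(scaled - rre_val), 5 / sqrt(omega))
  }
})

test_that("divergence experiments show guard stops and censoring flags", {
  res <- divergence_experiment("well_jumping", n_runs = 100, seed = 6)
  expect_gte(res$fraction_stopped, 0.9)

  res <- divergence_experiment("unstable_pair", n_runs = 300, seed = 6)
  expect_equal(res$fraction_stopped, 0)
  expect_gt(res$mean_full - res$mean_half,
            3 * (res$se_full + res$se_half))
  expect_gt(res$moment_growth_ratio, 1)

  em <- ensemble_moments(crn_fixture("well_jumping_22"), 5, n_paths = 5,
                         times = c(50, 100), seed = 7)
  expect_gt(em$censored, 0)
})
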