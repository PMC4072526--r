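# combinatorial oracle: count ordered tuples of distinct molecules
fall_oracle <- function(x, m) {
  if (x < m) return(0)
  prod(x - seq_len(m) + 1) / factorial(m)
}

test_that("stochastic propensities follow the falling-factorial convention", {
  bd <- crn_fixture("birth_death")
  expect_equal(propensities(bd, 0), c(2, 0))

  dimer <- crn_fixture("dimerization_29")
  # 2X1 -> X2 at x1 = 4: unordered pairs = choose(4, 2) = 6, times 0.1
  expect_equal(propensities(dimer, c(4, 0))[3], 0.1 * choose(4, 2))
  expect_equal(propensities(dimer, c(4, 0))[3], 0.1 * fall_oracle(4, 2))

  sch <- crn_fixture("schlogl_40", list(k2 = 1))
  # 3X -> 2X at x = 3: unordered triples = choose(3, 3) = 1
  k <- match("autocat3", vapply(sch$reactions, `[[`, "", "label"))
  expect_equal(propensities(sch, 3)[k], 1 * choose(3, 3))
  expect_equal(propensities(sch, 5)[k], 1 * fall_oracle(5, 3))
})

test_that("the drift vector is the propensity-weighted stoichiometry sum", {
  bd <- crn_fixture("birth_death")
  expect_equal(drift_vector(bd, 5), -3)

  empty <- reaction_network("X", list())
  expect_equal(drift_vector(empty, 7), 0)

  dimer <- crn_fixture("dimerization_29")
  expect_equal(drift_vector(dimer, c(4, 0)), c(10 - 4 - 2 * 0.6, 0.6))
})

test_that("unimolecular networks have an exact Metzler affine drift", {
  bd <- crn_fixture("birth_death")
  af <- unimolecular_affine(bd)
  expect_equal(unname(af$A), matrix(-1))
  expect_equal(unname(af$b), 2)

  chain <- parse_rxn(paste("species: S1, S2",
                           "reaction b: -> S1 @ ma(6)",
                           "reaction c: S1 -> S2 @ ma(2)",
                           "reaction d: S2 -> @ ma(3)", sep = "\n"))
  af <- unimolecular_affine(chain)
  expect_equal(unname(af$A), rbind(c(-2, 0), c(2, -3)))
  expect_equal(unname(af$b), c(6, 0))

  # toggle switch: bounded productions in b, translation enters A[p, m]
  tg <- crn_fixture("toggle_switch_35")
  af <- unimolecular_affine(tg)
  expect_equal(unname(af$b), c(10, 0, 10, 0))
  expect_equal(af$A["P1", "M1"], 4)
  expect_equal(af$A["P2", "M2"], 4)
  # exactness on random states (mass-action part only)
  mass <- reaction_network(tg$species,
    Filter(function(r) r$kind == "mass_action", tg$reactions))
  for (s in 1:20) {
    x <- sample(0:20, 4, replace = TRUE)
    expect_equal(drift_vector(mass, x), as.numeric(af$A %*% x), tolerance = 1e-12)
  }
  expect_error(unimolecular_affine(crn_fixture("dimerization_29")), "bimolecular")

  # Metzler property across fixtures and random networks
  for (nm in c("birth_death", "toggle_switch_35", "repressilator_36")) {
    A <- unimolecular_affine(crn_fixture(nm))$A
    off <- A; diag(off) <- 0
    expect_true(all(off >= 0), info = nm)
  }
  for (i in 1:20) {
    A <- unimolecular_affine(random_unimolecular(sample(2:5, 1)))$A
    off <- A; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("the quadratic drift decomposition is exact (property)", {
  set.seed(101)
  for (i in 1:200) {
    net <- random_order2_network(sample(2:5, 1), sample(3:8, 1))
    v <- runif(n_species(net), 0.2, 3)
    qd <- quadratic_drift(net, v)
    expect_equal(qd$Q, t(qd$Q))
    for (s in 1:50) {
      x <- sample(0:40, n_species(net), replace = TRUE)
      lhs <- sum(v * drift_vector(net, x))
      rhs <- as.numeric(t(x) %*% qd$Q %*% x) + sum(qd$linear * x) + qd$const
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("specific quadratic decompositions match hand expansion", {
  dimer <- crn_fixture("dimerization_29")
  qd <- quadratic_drift(dimer, c(1, 2))
  expect_equal(qd$Q, matrix(0, 2, 2))            # conservation kills <v,zeta>
  expect_equal(qd$const, 10)
  expect_equal(qd$linear, c(-1, -2))

  qd2 <- quadratic_drift(dimer, c(1, 1))
  expect_equal(qd2$Q[1, 1], -0.1 / 2)            # homodimer, symmetrized
  expect_equal(qd2$Q[1, 2], 0)

  uni <- crn_fixture("toggle_switch_35")
  expect_equal(quadratic_drift(uni, c(1, 2, 3, 4))$Q, matrix(0, 4, 4))
})

test_that("the diffusivity is the squared-jump propensity sum", {
  bd <- crn_fixture("birth_death")
  expect_equal(diffusivity(bd, 1, 3), 2 + 3)
  dimer <- crn_fixture("dimerization_29")
  # dimerization reaction contributes zero for v in the conservation cone
  for (x1 in c(0, 3, 10))
    expect_equal(diffusivity(dimer, c(1, 2), c(x1, 1)),
                 10 * 1 + x1 * 1 + 1 * 4)
  expect_error(diffusivity(bd, 0, 3), "positive")
})

test_that("conservation weights for bimolecular reactions are found exactly", {
  v <- conservation_vector(crn_fixture("dimerization_29"))
  expect_equal(v / v[1], c(1, 2))
  v <- conservation_vector(crn_fixture("sir_37"))
  expect_equal(v[1], v[2])
  Sb <- bimolecular_stoichiometry(crn_fixture("sir_37"))
  expect_equal(as.numeric(t(Sb) %*% v), 0)

  # full-row-rank bimolecular stoichiometry: the cone must be empty
  fr <- reaction_network(c("X", "Y"), list(
    reaction("a", reactants = c(X = 1, Y = 1), products = c(Y = 1), rate = 1),
    reaction("b", reactants = c(X = 1, Y = 1), products = c(X = 1), rate = 1),
    reaction("bx", products = c(X = 1), rate = 1),
    reaction("by", products = c(Y = 1), rate = 1)))
  expect_null(conservation_vector(fr))

  # annihilation invariant for every returned vector
  for (nm in c("dimerization_29", "sir_37", "feedback_loop_34", "circadian_vilar")) {
    net <- crn_fixture(nm)
    v <- conservation_vector(net)
    expect_false(is.null(v))
    Sb <- bimolecular_stoichiometry(net)
    expect_true(all(abs(t(Sb) %*% v) < 1e-9), info = nm)
  }
})

test_that("verify_dd extracts tight constants", {
  bd <- crn_fixture("birth_death")
  cert <- verify_dd(bd, 1, audit_n = 500)
  expect_true(cert$dd1_verified && cert$dd2_verified)
  expect_equal(cert$c1, 1)
  expect_equal(cert$c2, 2)
  expect_equal(cert$gamma, 2)
  # minimal c3: scalar oracle max over a lattice of (2 + x) / (1 + x) = 2
  xs <- 0:10000
  expect_equal(cert$c3, max((2 + xs) / (1 + xs)))
  expect_equal(cert$zeta_bar, 1)

  dimer <- crn_fixture("dimerization_29")
  cert <- verify_dd(dimer, c(1, 2), audit_n = 500)
  expect_true(cert$dd1_verified && cert$dd2_verified)
  expect_equal(cert$c1, 1)
  expect_equal(cert$c2, 10)
  expect_equal(cert$gamma, 10)

  expect_error(verify_dd(bd, -1), "positive")
})

test_that("no drift certificate exists for the divergent pair on a weight grid", {
  net <- crn_fixture("unstable_pair_26")
  grid <- exp(seq(log(0.05), log(20), length.out = 20))
  for (v1 in grid) for (v2 in grid) {
    cert <- verify_dd(net, c(v1, v2), audit_n = 0)
    expect_false(cert$dd1_verified)
  }
})

test_that("issued certificates survive a randomized lattice audit", {
  cases <- list(
    list(net = crn_fixture("birth_death"), v = 1, pools = NULL),
    list(net = crn_fixture("dimerization_29"), v = c(1, 2), pools = NULL),
    list(net = crn_fixture("sir_37"), v = c(1, 1, 1), pools = NULL))
  for (cs in cases) {
    cert <- verify_dd(cs$net, cs$v, pools = cs$pools, audit_n = 3000,
                      audit_box = 1000)
    expect_true(cert$dd1_verified)
    expect_equal(cert$audit$dd1_violations, 0L)
    expect_equal(cert$audit$dd2_violations, 0L)
  }
  # pool-aware circadian certificate
  cc <- crn_fixture("circadian_vilar")
  pools <- pool_bounds(cc, circadian_x0())
  expect_equal(unname(pools[c("DA", "DAp", "DR", "DRp")]), rep(1, 4))
  expect_true(all(is.infinite(pools[c("MA", "A", "MR", "R", "C")])))
  rep <- analyze_bimolecular_conserved(cc, x0 = circadian_x0())
  cert <- verify_dd(cc, rep$certificate$v, pools = pools, audit_n = 3000)
  expect_true(cert$dd1_verified)
  expect_equal(cert$audit$dd1_violations, 0L)
  expect_equal(cert$audit$dd2_violations, 0L)
})
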