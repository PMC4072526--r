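test_that("Hurwitz test and positive certificates behave on canonical cases", {
  expect_true(as.logical(hurwitz_test(matrix(-1))))
  expect_false(as.logical(hurwitz_test(rbind(c(0, 1), c(-1, 0)))))
  expect_true(as.logical(hurwitz_test(rbind(c(-1, 0), c(1, -2)))))

  r <- positive_linear_certificate(matrix(-1))
  expect_true(r$feasible)
  expect_equal(r$v, 1)

  A <- rbind(c(-1, 0), c(1, -1))
  r <- positive_linear_certificate(A)
  expect_true(r$feasible)
  expect_true(all(t(A) %*% r$v < 0))
  expect_true(r$v[1] > r$v[2])

  expect_false(positive_linear_certificate(matrix(1))$feasible)
  expect_error(positive_linear_certificate(rbind(c(-1, -2), c(0, -1))),
               "Metzler")
})

test_that("certificate feasibility is equivalent to Hurwitz stability (property)", {
  set.seed(23)
  discord <- 0L
  for (i in 1:500) {
    d <- sample(1:8, 1)
    A <- random_metzler(d)
    if (positive_linear_certificate(A)$feasible != as.logical(hurwitz_test(A)))
      discord <- discord + 1L
  }
  expect_equal(discord, 0L)
})

test_that("unimolecular analysis certifies stable networks and not unstable ones", {
  rep <- analyze_unimolecular(crn_fixture("birth_death"))
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$moment_conclusion, "all_orders")
  expect_true(rep$light_tailed)

  auto <- reaction_network("X", list(
    reaction("b", products = c(X = 1), rate = 1),
    reaction("a", reactants = c(X = 1), products = c(X = 2), rate = 2),
    reaction("d", reactants = c(X = 1), rate = 1)))
  expect_equal(analyze_unimolecular(auto)$verdict, "no_certificate_found")

  # structural claim, small sample here (full sweep in the acceptance tests)
  set.seed(5)
  for (i in 1:10) {
    pars <- as.list(10^runif(8, -2, 2))
    names(pars) <- c("a1", "a2", "gamma_m1", "gamma_m2", "k1", "k2",
                     "gamma_p1", "gamma_p2")
    expect_equal(analyze_unimolecular(crn_fixture("toggle_switch_35", pars))$verdict,
                 "ergodic")
  }
})

test_that("robust certificates cover the whole interval family", {
  bd <- reaction_network("X", list(
    reaction("b", products = c(X = 1), rate = 2),
    reaction("d", reactants = c(X = 1), rate = 1)),
    rate_intervals = list(d = c(0.5, 2)))
  rep <- analyze_robust(bd)
  expect_equal(rep$verdict, "ergodic_robust")

  chain <- reaction_network(c("S1", "S2"), list(
    reaction("b", products = c(S1 = 1), rate = 6),
    reaction("c", reactants = c(S1 = 1), products = c(S2 = 1), rate = 1.5),
    reaction("d", reactants = c(S2 = 1), rate = 1.5)),
    rate_intervals = list(c = c(1, 2), d = c(1, 2)))
  rep <- analyze_robust(chain)
  # conversion rate appears with both signs: the attained bound matrix does
  # not exist, but the entrywise bound is still valid and certifies here
  expect_equal(rep$verdict, "ergodic_robust")

  # robust => pointwise: random members individually certify
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, 1, 2); b <- runif(1, 1, 2)
    member <- reaction_network(c("S1", "S2"), list(
      reaction("b", products = c(S1 = 1), rate = 6),
      reaction("c", reactants = c(S1 = 1), products = c(S2 = 1), rate = a),
      reaction("d", reactants = c(S2 = 1), rate = b)))
    expect_equal(analyze_unimolecular(member)$verdict, "ergodic")
  }

  # autocatalysis interval straddling the death rate: no robust certificate
  auto <- reaction_network("X", list(
    reaction("b", products = c(X = 1), rate = 1),
    reaction("a", reactants = c(X = 1), products = c(X = 2), rate = 1),
    reaction("d", reactants = c(X = 1), rate = 1.2)),
    rate_intervals = list(a = c(0.5, 2)))
  expect_equal(analyze_robust(auto)$verdict, "no_certificate_found")
})

test_that("conservation-weighted analysis certifies the classic bimolecular models", {
  rep <- analyze_bimolecular_conserved(crn_fixture("dimerization_29"))
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$moment_conclusion, "all_orders")
  v <- rep$certificate$v
  expect_equal(v[2] / v[1], 2)

  set.seed(31)
  for (i in 1:10) {
    pars <- as.list(10^runif(7, -2, 2))
    names(pars) <- c("b", "d_S", "d_I", "d_R", "beta", "gamma", "rho")
    expect_equal(analyze_bimolecular_conserved(crn_fixture("sir_37", pars))$verdict,
                 "ergodic", info = paste(unlist(pars), collapse = ","))
  }

  rep <- analyze_bimolecular_conserved(crn_fixture("circadian_vilar"),
                                       x0 = circadian_x0())
  expect_equal(rep$verdict, "ergodic")

  # empty cone is a prerequisite failure, not an error
  fr <- reaction_network(c("X", "Y"), list(
    reaction("a", reactants = c(X = 1, Y = 1), products = c(Y = 1), rate = 1),
    reaction("b", reactants = c(X = 1, Y = 1), products = c(X = 1), rate = 1),
    reaction("bx", products = c(X = 1), rate = 1),
    reaction("by", products = c(Y = 1), rate = 1)))
  rep <- analyze_bimolecular_conserved(fr)
  expect_equal(rep$attempts[[1]]$status, "prerequisite_failed")
})

test_that("the componentwise quadratic route works and unimolecular input reduces", {
  rep <- analyze_bimolecular_general(crn_fixture("dimerization_29"),
                                     "componentwise_lp")
  expect_equal(rep$verdict, "ergodic")

  # unimolecular network: Q = 0 and the LP is the linear certificate
  rep <- analyze_bimolecular_general(crn_fixture("birth_death"),
                                     "componentwise_lp")
  expect_equal(rep$verdict, "ergodic")

  # joint autocatalysis X + Y -> 2X + 2Y: Q(v) has a positive entry for all
  # v >= 1, so neither quadratic route can certify
  auto2 <- reaction_network(c("X", "Y"), list(
    reaction("grow", reactants = c(X = 1, Y = 1),
             products = c(X = 2, Y = 2), rate = 0.1),
    reaction("bx", products = c(X = 1), rate = 1),
    reaction("by", products = c(Y = 1), rate = 1),
    reaction("dx", reactants = c(X = 1), rate = 1),
    reaction("dy", reactants = c(Y = 1), rate = 1)))
  expect_equal(analyze_bimolecular_general(auto2, "componentwise_lp")$verdict,
               "no_certificate_found")
  expect_equal(analyze_bimolecular_general(auto2, "negdef_sdp")$verdict,
               "no_certificate_found")

  # p53: the componentwise route is what fires in the dispatcher
  rep <- analyze_network(crn_fixture("p53_38"))
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$method, "bimolecular_componentwise_lp")
})

test_that("copositivity is decided exactly on small matrices", {
  expect_true(copositivity_test(diag(3))$copositive)

  r <- copositivity_test(rbind(c(0, -1), c(-1, 0)))
  expect_false(r$copositive)
  expect_true(all(r$witness >= 0))
  expect_true(sum(r$witness %*% rbind(c(0, -1), c(-1, 0)) %*% r$witness) < 0)

  # PSD but with negative entries: copositive
  expect_true(copositivity_test(rbind(c(1, -1), c(-1, 1)))$copositive)

  # the 5x5 Horn matrix: copositive though not PSD-plus-nonnegative
  H <- rbind(c(1, -1, 1, 1, -1), c(-1, 1, -1, 1, 1), c(1, -1, 1, -1, 1),
             c(1, 1, -1, 1, -1), c(-1, 1, 1, -1, 1))
  rh <- copositivity_test(H)
  expect_true(rh$copositive)
  expect_false(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) >= 0)

  # witness soundness on random indefinite matrices
  set.seed(13)
  for (i in 1:30) {
    d <- sample(2:5, 1)
    M <- matrix(rnorm(d * d), d, d); M <- (M + t(M)) / 2
    r <- copositivity_test(M)
    if (!r$copositive) {
      expect_true(all(r$witness >= -1e-12))
      expect_true(as.numeric(r$witness %*% M %*% r$witness) < 0)
    }
  }
})

test_that("the Lotka-Volterra routes certify competition-stabilized systems", {
  # single-species logistic: scalar competition coefficient > 0
  lv1 <- reaction_network("X1", list(
    reaction("imm1", products = c(X1 = 1), rate = 1),
    reaction("rep1", reactants = c(X1 = 1), products = c(X1 = 2), rate = 2),
    reaction("comp11", reactants = c(X1 = 2), products = c(X1 = 1), rate = 0.05),
    reaction("death1", reactants = c(X1 = 1), rate = 1)))
  expect_equal(analyze_lotka_volterra(lv1)$verdict, "ergodic")

  # diagonally dominant competition: the scaling route fires
  rep <- analyze_lotka_volterra(crn_fixture("lotka_volterra_39"))
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$method, "lv_diagonal_scaling")

  # zero competition with reproduction above death: unimolecular, unstable
  nc <- reaction_network(c("X1", "X2"), list(
    reaction("imm1", products = c(X1 = 1), rate = 1),
    reaction("imm2", products = c(X2 = 1), rate = 1),
    reaction("rep1", reactants = c(X1 = 1), products = c(X1 = 2), rate = 2),
    reaction("rep2", reactants = c(X2 = 1), products = c(X2 = 2), rate = 2),
    reaction("death1", reactants = c(X1 = 1), rate = 1),
    reaction("death2", reactants = c(X2 = 1), rate = 1)))
  expect_equal(analyze_network(nc)$verdict, "no_certificate_found")
  expect_error(analyze_lotka_volterra(crn_fixture("birth_death")), "template")
})

test_that("the scalar polynomial route handles higher-order kinetics", {
  sch <- crn_fixture("schlogl_40")
  sp <- scalar_polynomial_drift(sch)
  expect_true(sp$feasible)
  expect_true(sp$leading < 0)
  expect_equal(sp$degree, 3)
  expect_false(sp$dd2_verified)

  rep <- analyze_network(sch)
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$method, "scalar_polynomial")
  expect_equal(rep$moment_conclusion, "first_order_only")
  expect_false(rep$light_tailed)

  pure_birth <- reaction_network("X", list(
    reaction("b", products = c(X = 1), rate = 1),
    reaction("a", reactants = c(X = 1), products = c(X = 2), rate = 0.5)))
  expect_false(scalar_polynomial_drift(pure_birth)$feasible)

  bd <- crn_fixture("birth_death")
  sp <- scalar_polynomial_drift(bd, c1 = 1)
  # degree-1 drift 2 - x: max over s >= 0 of (2 - s + s) = 2 exactly
  expect_equal(sp$c2, 2)
})

test_that("the dispatcher returns the first firing rung with a full trace", {
  rep <- analyze_network(crn_fixture("repressilator_36"))
  expect_equal(rep$verdict, "ergodic")
  expect_equal(rep$method, "unimolecular_linear_certificate")

  rep <- analyze_network(crn_fixture("feedback_loop_34"))
  expect_equal(rep$verdict, "ergodic")

  rep <- analyze_network(crn_fixture("unstable_pair_26"))
  expect_equal(rep$verdict, "no_certificate_found")
  expect_true(length(rep$attempts) >= 3)
  expect_true(all(vapply(rep$attempts, function(a)
    a$status != "certificate", TRUE)))

  # the dispatcher never claims ergodicity without the irreducibility input
  rep <- analyze_network(crn_fixture("birth_death"), assume_irreducible = FALSE)
  expect_false(rep$verdict == "ergodic")
})

test_that("adding a degradation never destroys a certificate (monotonicity)", {
  set.seed(17)
  for (i in 1:20) {
    net <- random_unimolecular(sample(2:4, 1))
    rep <- analyze_unimolecular(net)
    if (rep$verdict != "ergodic") next
    v <- rep$certificate$v
    i_sp <- sample(n_species(net), 1)
    net2 <- reaction_network(net$species, c(net$reactions, list(
      reaction("extra_deg",
               reactants = stats::setNames(1L, net$species[i_sp]),
               rate = runif(1, 0.1, 2)))))
    cert2 <- verify_dd(net2, v, audit_n = 0)
    expect_true(cert2$dd1_verified)
  }
})
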