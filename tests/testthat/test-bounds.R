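test_that("the birth-death attractor is exactly the Poisson stationary mean", {
  att <- optimal_attractor(crn_fixture("birth_death"))
  expect_equal(att$gamma_star, 2, tolerance = 1e-9)
  expect_equal(att$c1_star, 1, tolerance = 1e-9)

  att2 <- optimal_attractor(crn_fixture("birth_death", list(k_birth = 7, k_death = 0.5)))
  expect_equal(att2$gamma_star, 14, tolerance = 1e-9)
})

test_that("the two-species chain optimum matches its closed form", {
  # weighted drift 6 v1 - (2 v1 - 2 v2) x1 - 3 v2 x2: with v2 = 1 the optimum
  # of 6 v1 / c1 under v1 >= 2 v2 / (2 - c1) is 12 / (c1 (2 - c1)), minimized
  # at c1 = 1 with value 12 and v = (2, 1)
  ch <- reaction_network(c("S1", "S2"), list(
    reaction("b", products = c(S1 = 1), rate = 6),
    reaction("c", reactants = c(S1 = 1), products = c(S2 = 1), rate = 2),
    reaction("d", reactants = c(S2 = 1), rate = 3)))
  att <- optimal_attractor(ch)
  expect_equal(att$gamma_star, 12, tolerance = 1e-4)
  expect_equal(att$c1_star, 1, tolerance = 1e-2)
  expect_equal(att$v_star / att$v_star[2], c(2, 1), tolerance = 1e-3)
  # validity against the exact stationary mean of the linear network
  # (means 3 and 2): <v*, m> <= gamma*
  expect_true(sum(att$v_star * c(3, 2)) <= att$gamma_star + 1e-6)
})

test_that("the scalar search finds the grid optimum on random networks", {
  set.seed(47)
  n_done <- 0
  while (n_done < 20) {
    net <- random_unimolecular(sample(2:4, 1), sample(2:5, 1))
    af <- unimolecular_affine(net)
    hz <- hurwitz_test(af$A)
    if (!as.logical(hz)) next
    n_done <- n_done + 1
    att <- optimal_attractor(net)
    # independent oracle: dense c1 grid with the simplex inner solver
    alpha <- -attr(hz, "abscissa"); d <- n_species(net)
    gbest <- Inf
    for (c1 in exp(seq(log(alpha * 1e-6), log(alpha * (1 - 1e-9)),
                       length.out = 300))) {
      r <- lp_dense(af$b, A_ub = t(af$A) + diag(c1, d), b_ub = rep(0, d),
                    lower = 1)
      if (r$status == "optimal") gbest <- min(gbest, r$objective / c1)
    }
    # never worse than the independent grid (which cannot probe the spectral
    # boundary where the optimum may sit), and the returned certificate must
    # be feasible with a consistent objective
    expect_lt(att$gamma_star, gbest * 1.01)
    expect_true(max(t(af$A) %*% att$v_star + att$c1_star * att$v_star) <=
                  1e-7 * max(1, max(att$v_star)))
    expect_equal(att$gamma_star, sum(af$b * att$v_star) / att$c1_star,
                 tolerance = 1e-8)
  }
})

test_that("conserved and quadratic-negativity attractors agree on dimerization", {
  dimer <- crn_fixture("dimerization_29")
  a1 <- optimal_attractor(dimer, method = "conserved")
  expect_equal(a1$gamma_star, 10, tolerance = 1e-6)
  expect_equal(a1$v_star / a1$v_star[1], c(1, 2), tolerance = 1e-6)
  a2 <- optimal_attractor(dimer, method = "qneg")
  expect_true(a2$gamma_star >= a1$gamma_star - 1e-6)
  expect_equal(a2$gamma_star, 10, tolerance = 1e-4)

  sir <- crn_fixture("sir_37")
  a3 <- optimal_attractor(sir, method = "conserved")
  # closed form b / min(death rates) with unit weights
  expect_equal(a3$gamma_star, 10, tolerance = 1e-4)

  # not certifiable by the quadratic route: joint autocatalysis
  auto2 <- reaction_network(c("X", "Y"), list(
    reaction("grow", reactants = c(X = 1, Y = 1),
             products = c(X = 2, Y = 2), rate = 0.1),
    reaction("bx", products = c(X = 1), rate = 1),
    reaction("dx", reactants = c(X = 1), rate = 1),
    reaction("dy", reactants = c(Y = 1), rate = 1)))
  expect_error(optimal_attractor(auto2, method = "qneg"), "not certifiable")

  # unstable unimolecular network
  auto <- reaction_network("X", list(
    reaction("b", products = c(X = 1), rate = 1),
    reaction("a", reactants = c(X = 1), products = c(X = 2), rate = 2),
    reaction("d", reactants = c(X = 1), rate = 1)))
  expect_error(optimal_attractor(auto), "not certifiable")
})

test_that("moment-bound tables are valid, ordered and monotone in c1", {
  bd <- crn_fixture("birth_death")
  cert <- verify_dd(bd, 1, audit_n = 0)
  tab <- moment_bounds(cert, n_max = 3, x0 = 0)
  expect_equal(tab$asymptotic[1], 2)          # first order equals gamma
  expect_equal(tab$uniform[1], 2)             # x0 = 0 below the bound
  # Poisson(2): E[X^2] = 6, E[X^3] = 26 -- bounds must lie above
  expect_true(tab$asymptotic[2] >= 6)
  expect_true(tab$asymptotic[3] >= 26)
  expect_true(all(tab$uniform >= tab$asymptotic))

  tab_hi <- moment_bounds(
    structure(modifyList(unclass(cert), list(c1 = 2 * cert$c1)),
              class = "dd_certificate"), n_max = 3, x0 = 0)
  expect_true(all(tab_hi$asymptotic <= tab$asymptotic))

  # drift-only certificate: table stops at order 1
  cert1 <- structure(modifyList(unclass(cert), list(dd2_verified = FALSE,
                                                    c3 = Inf)),
                     class = "dd_certificate")
  tab1 <- moment_bounds(cert1, n_max = 3, x0 = 5)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$uniform[1], 5)            # max(<v,x0>, gamma)
})

test_that("light-tail flags follow the certificate hypotheses", {
  bd_cert <- verify_dd(crn_fixture("birth_death"), 1, audit_n = 0)
  f <- light_tail_flags(bd_cert)
  expect_true(f$uniform_light_tailed && f$stationary_light_tailed)

  dim_cert <- verify_dd(crn_fixture("dimerization_29"), c(1, 2), audit_n = 0)
  f <- light_tail_flags(dim_cert)
  expect_true(f$uniform_light_tailed && f$stationary_light_tailed)

  sch <- analyze_network(crn_fixture("schlogl_40"))
  f <- light_tail_flags(sch$certificate)
  expect_false(f$uniform_light_tailed)
  expect_false(f$stationary_light_tailed)
  expect_match(f$reason, "diffusivity")
})

test_that("the closure audit reproduces the dimerization equilibrium geometry", {
  dimer <- crn_fixture("dimerization_29")
  att <- optimal_attractor(dimer, method = "conserved")
  aud <- closure_audit(dimer, att)
  # oracle: cumulant-neglect equilibrium solves
  # 0.1 m1^2 + 0.9 m1 - 10 = 0, m2 = 0.05 (m1^2 - m1)
  m1 <- uniroot(function(m) 0.1 * m^2 + 0.9 * m - 10, c(0, 100),
                tol = 1e-12)$root
  m2 <- 0.05 * (m1^2 - m1)
  expect_equal(aud$closed_equilibrium, c(m1, m2), tolerance = 1e-6)
  expect_true(aud$jacobian_stable)
  # with k2 = k4 the closed equilibrium sits exactly on the boundary
  expect_lt(aud$error_lower_bound, 1e-6)
  expect_true(aud$inside_attractor)

  # inflating gamma keeps it strictly inside with zero error bound
  att_big <- att; att_big$gamma_star <- att$gamma_star * 10
  aud2 <- closure_audit(dimer, att_big)
  expect_true(aud2$inside_attractor)
  expect_equal(aud2$error_lower_bound, 0)

  # shrinking gamma pushes it outside; while the halfspace projection stays
  # in the orthant the bound is the point-to-halfspace distance
  att_small <- att; att_small$gamma_star <- 8
  aud3 <- closure_audit(dimer, att_small)
  v <- att$v_star
  expect_false(aud3$inside_attractor)
  expect_equal(aud3$error_lower_bound,
               max(0, sum(v * c(m1, m2)) - 8) / sqrt(sum(v^2)),
               tolerance = 1e-6)

  # divergent closed system is reported, not an error
  wj <- crn_fixture("well_jumping_22")
  att_wj <- list(v_star = 1, gamma_star = 10)
  aud4 <- closure_audit(wj, att_wj, x0 = 50)
  expect_equal(aud4$status, "closed system unbounded")
})

test_that("the attractor-distance formula matches a quadratic-program oracle", {
  skip_if_not_installed("quadprog")
  set.seed(19)
  for (i in 1:100) {
    d <- sample(2:4, 1)
    v <- runif(d, 0.5, 3)
    gam <- runif(1, 0.5, 5)
    p <- runif(d, -2, 6)
    got <- ergokit:::dist_to_halfspace_orthant(p, v, gam)
    # QP: minimize |x - p|^2 subject to x >= 0, <v, x> <= gam
    sol <- quadprog::solve.QP(diag(d), p,
                              cbind(diag(d), -v), c(rep(0, d), -gam))
    want <- sqrt(max(0, sum((sol$solution - p)^2)))
    expect_equal(got, want, tolerance = 1e-6)
  }
})
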