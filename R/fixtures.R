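# Registry of classic example networks. Species and reaction ordering is
# declaration order as written here; all matrices follow it. Rates for the
# three qualitative-regime fixtures (well_jumping_22, unstable_pair_26,
# carcinogenesis_41) are package defaults chosen to realize the regimes the
# models are known for (bistable well with reachable escape; globally stable
# rate equations with divergent stochastic moments; supercritical branching),
# with the escape-region tuning rule that the largest stochastic drift root
# stays below 50 so that escapes are observable in short simulations.

fixture_registry <- function() {
  list(
    birth_death = fixture_birth_death,
    well_jumping_22 = fixture_well_jumping,
    unstable_pair_26 = fixture_unstable_pair,
    dimerization_29 = fixture_dimerization,
    feedback_loop_34 = fixture_feedback_loop,
    toggle_switch_35 = fixture_toggle_switch,
    repressilator_36 = fixture_repressilator,
    sir_37 = fixture_sir,
    circadian_vilar = fixture_circadian,
    p53_38 = fixture_p53,
    lotka_volterra_39 = fixture_lotka_volterra,
    schlogl_40 = fixture_schlogl,
    carcinogenesis_41 = fixture_carcinogenesis
  )
}

#' Names of the bundled example networks
#' @return Character vector of fixture identifiers accepted by [crn_fixture()].
#' @export
fixture_names <- function() names(fixture_registry())

#' Build a bundled example network
#'
#' The registry covers the didactic birth-death process, the
#' dimerization, feedback-loop, toggle-switch, repressilator, SIR, circadian
#' clock (Vilar oscillator), p53, Lotka-Volterra, Schlogl and carcinogenesis
#' models, and the two cautionary networks whose stochastic behavior departs
#' from their rate equations (a bistable well the process can jump out of,
#' and a pair with globally stable rate equations but divergent moments).
#'
#' @param name Fixture identifier; see [fixture_names()].
#' @param params Named list overriding the fixture's default rate constants.
#'   Unknown parameter names are an error.
#' @return A [reaction_network()] whose \code{params} field records the rates
#'   used.
#' @export
crn_fixture <- function(name, params = list()) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; see fixture_names()")
  reg[[name]](params)
}

merge_params <- function(defaults, params) {
  params <- as.list(params)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown fixture parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  lapply(defaults, function(p) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0)
      stop("fixture parameters must be nonnegative numbers")
    p
  })
}

fixture_birth_death <- function(params = list()) {
  p <- merge_params(list(k_birth = 2, k_death = 1), params)
  reaction_network("X", list(
    reaction("birth", products = c(X = 1), rate = p$k_birth),
    reaction("death", reactants = c(X = 1), rate = p$k_death)
  ), params = unlist(p))
}

# Bistable autocatalysis 0 -> X, 2X -> 3X, X -> 0: the deterministic flow
# has a stable and an unstable fixed point; the jump process can cross the
# barrier and then explodes. Default stochastic drift roots are about 2.1
# and 18.9 (kept below 50 so the escape region is reachable in short runs);
# the overall rate scale is chosen so that escapes are near-certain within a
# 100-time-unit horizon.
fixture_well_jumping <- function(params = list()) {
  p <- merge_params(list(k1 = 600, k2 = 30, k3 = 300), params)
  reaction_network("X", list(
    reaction("birth", products = c(X = 1), rate = p$k1),
    reaction("autocat", reactants = c(X = 2), products = c(X = 3), rate = p$k2),
    reaction("death", reactants = c(X = 1), rate = p$k3)
  ), params = unlist(p))
}

# 0 -> X1, X1 + X2 -> 2X2, X2 -> 0: the rate equations have a unique globally
# stable equilibrium (k3/k2, k1/k3), but stochastically extinction of X2 traps
# the process on the X2 = 0 ray where X1 grows without bound, so no stationary
# distribution exists and first moments grow linearly.
fixture_unstable_pair <- function(params = list()) {
  p <- merge_params(list(k1 = 1, k2 = 1, k3 = 1), params)
  reaction_network(c("X1", "X2"), list(
    reaction("birth1", products = c(X1 = 1), rate = p$k1),
    reaction("convert", reactants = c(X1 = 1, X2 = 1), products = c(X2 = 2),
             rate = p$k2),
    reaction("death2", reactants = c(X2 = 1), rate = p$k3)
  ), params = unlist(p))
}

fixture_dimerization <- function(params = list()) {
  p <- merge_params(list(k1 = 10, k2 = 1, k3 = 0.1, k4 = 1), params)
  reaction_network(c("X1", "X2"), list(
    reaction("birth", products = c(X1 = 1), rate = p$k1),
    reaction("deg_monomer", reactants = c(X1 = 1), rate = p$k2),
    reaction("dimerize", reactants = c(X1 = 2), products = c(X2 = 1), rate = p$k3),
    reaction("deg_dimer", reactants = c(X2 = 1), rate = p$k4)
  ), params = unlist(p))
}

# Gene expression with dimerization of the protein and transcription driven by
# an arbitrary bounded nonnegative function of the dimer.
fixture_feedback_loop <- function(params = list()) {
  p <- merge_params(list(k0 = 10, gamma_m = 1, k_p = 5, gamma_p = 1,
                         k_dim = 0.01, gamma_d = 1), params)
  reaction_network(c("M", "P", "D"), list(
    reaction("transcribe", products = c(M = 1), sup_bound = p$k0,
             eval_hint = sprintf("%g/(1 + D^2)", p$k0)),
    reaction("deg_m", reactants = c(M = 1), rate = p$gamma_m),
    reaction("translate", reactants = c(M = 1), products = c(M = 1, P = 1),
             rate = p$k_p),
    reaction("deg_p", reactants = c(P = 1), rate = p$gamma_p),
    reaction("dimerize", reactants = c(P = 2), products = c(D = 1), rate = p$k_dim),
    reaction("deg_d", reactants = c(D = 1), rate = p$gamma_d)
  ), params = unlist(p))
}

# Two mutually repressing genes; repression enters through bounded propensities.
fixture_toggle_switch <- function(params = list()) {
  p <- merge_params(list(a1 = 10, a2 = 10, gamma_m1 = 1, gamma_m2 = 1,
                         k1 = 4, k2 = 4, gamma_p1 = 1, gamma_p2 = 1), params)
  reaction_network(c("M1", "P1", "M2", "P2"), list(
    reaction("tx1", products = c(M1 = 1), sup_bound = p$a1,
             eval_hint = sprintf("%g/(1 + P2^2)", p$a1)),
    reaction("deg_m1", reactants = c(M1 = 1), rate = p$gamma_m1),
    reaction("tl1", reactants = c(M1 = 1), products = c(M1 = 1, P1 = 1), rate = p$k1),
    reaction("deg_p1", reactants = c(P1 = 1), rate = p$gamma_p1),
    reaction("tx2", products = c(M2 = 1), sup_bound = p$a2,
             eval_hint = sprintf("%g/(1 + P1^2)", p$a2)),
    reaction("deg_m2", reactants = c(M2 = 1), rate = p$gamma_m2),
    reaction("tl2", reactants = c(M2 = 1), products = c(M2 = 1, P2 = 1), rate = p$k2),
    reaction("deg_p2", reactants = c(P2 = 1), rate = p$gamma_p2)
  ), params = unlist(p))
}

# n-gene ring oscillator; transcription of gene i is repressed by protein i-1
# through a bounded propensity. Species are M1..Mn then P1..Pn.
fixture_repressilator <- function(params = list()) {
  p <- merge_params(list(genes = 3, alpha = 10, gamma_m = 1, k_p = 4,
                         gamma_p = 1, hill = 2), params)
  n <- as.integer(p$genes)
  if (n < 2) stop("repressilator needs at least 2 genes")
  species <- c(paste0("M", 1:n), paste0("P", 1:n))
  rx <- list()
  for (i in 1:n) {
    rep_by <- paste0("P", if (i == 1) n else i - 1L)
    mi <- paste0("M", i); pi <- paste0("P", i)
    rx <- c(rx, list(
      reaction(paste0("tx", i), products = stats::setNames(1L, mi),
               sup_bound = p$alpha,
               eval_hint = sprintf("%g/(1 + %s^%g)", p$alpha, rep_by, p$hill)),
      reaction(paste0("deg_m", i), reactants = stats::setNames(1L, mi),
               rate = p$gamma_m),
      reaction(paste0("tl", i), reactants = stats::setNames(1L, mi),
               products = stats::setNames(c(1L, 1L), c(mi, pi)), rate = p$k_p),
      reaction(paste0("deg_p", i), reactants = stats::setNames(1L, pi),
               rate = p$gamma_p)
    ))
  }
  reaction_network(species, rx, params = unlist(p))
}

# Open SIR with demography: births and deaths of individuals, contamination
# S + I -> 2I, recovery I -> R and loss of immunity R -> S.
fixture_sir <- function(params = list()) {
  p <- merge_params(list(b = 10, d_S = 1, d_I = 1, d_R = 1, beta = 0.01,
                         gamma = 0.5, rho = 0.1), params)
  reaction_network(c("S", "I", "R"), list(
    reaction("birth", products = c(S = 1), rate = p$b),
    reaction("death_S", reactants = c(S = 1), rate = p$d_S),
    reaction("death_I", reactants = c(I = 1), rate = p$d_I),
    reaction("death_R", reactants = c(R = 1), rate = p$d_R),
    reaction("contaminate", reactants = c(S = 1, I = 1), products = c(I = 2),
             rate = p$beta),
    reaction("recover", reactants = c(I = 1), products = c(R = 1), rate = p$gamma),
    reaction("wane", reactants = c(R = 1), products = c(S = 1), rate = p$rho)
  ), params = unlist(p))
}

# Vilar-Kueh-Barkai-Leibler circadian oscillator: activator A and repressor R
# genes with promoter binding, transcription, translation, degradation and
# A:R complex formation. The activator is degraded at rate delta_A in every
# pool it occupies -- free, complexed (C -> R), and promoter-bound
# (D_A' -> D_A, D_R' -> D_R) -- giving 9 species and 18 reactions.
fixture_circadian <- function(params = list()) {
  p <- merge_params(list(
    alpha_A = 50, alpha_Ap = 500, alpha_R = 0.01, alpha_Rp = 50,
    beta_A = 50, beta_R = 5, delta_MA = 10, delta_MR = 0.5,
    delta_A = 1, delta_R = 0.2, gamma_A = 1, gamma_R = 1, gamma_C = 2,
    theta_A = 50, theta_R = 100), params)
  reaction_network(c("DA", "DAp", "DR", "DRp", "MA", "A", "MR", "R", "C"), list(
    reaction("bind_A", reactants = c(DA = 1, A = 1), products = c(DAp = 1),
             rate = p$gamma_A),
    reaction("unbind_A", reactants = c(DAp = 1), products = c(DA = 1, A = 1),
             rate = p$theta_A),
    reaction("bind_R", reactants = c(DR = 1, A = 1), products = c(DRp = 1),
             rate = p$gamma_R),
    reaction("unbind_R", reactants = c(DRp = 1), products = c(DR = 1, A = 1),
             rate = p$theta_R),
    reaction("tx_A_basal", reactants = c(DA = 1), products = c(DA = 1, MA = 1),
             rate = p$alpha_A),
    reaction("tx_A_active", reactants = c(DAp = 1), products = c(DAp = 1, MA = 1),
             rate = p$alpha_Ap),
    reaction("tx_R_basal", reactants = c(DR = 1), products = c(DR = 1, MR = 1),
             rate = p$alpha_R),
    reaction("tx_R_active", reactants = c(DRp = 1), products = c(DRp = 1, MR = 1),
             rate = p$alpha_Rp),
    reaction("tl_A", reactants = c(MA = 1), products = c(MA = 1, A = 1),
             rate = p$beta_A),
    reaction("tl_R", reactants = c(MR = 1), products = c(MR = 1, R = 1),
             rate = p$beta_R),
    reaction("deg_MA", reactants = c(MA = 1), rate = p$delta_MA),
    reaction("deg_MR", reactants = c(MR = 1), rate = p$delta_MR),
    reaction("deg_A", reactants = c(A = 1), rate = p$delta_A),
    reaction("deg_R", reactants = c(R = 1), rate = p$delta_R),
    reaction("complex", reactants = c(A = 1, R = 1), products = c(C = 1),
             rate = p$gamma_C),
    reaction("deg_A_in_C", reactants = c(C = 1), products = c(R = 1),
             rate = p$delta_A),
    reaction("deg_A_on_DA", reactants = c(DAp = 1), products = c(DA = 1),
             rate = p$delta_A),
    reaction("deg_A_on_DR", reactants = c(DRp = 1), products = c(DR = 1),
             rate = p$delta_A)
  ), params = unlist(p))
}

#' Conventional initial state for the circadian clock fixture
#' (one copy of each gene, everything else empty).
#' @return Integer state vector in the fixture's species order.
#' @export
circadian_x0 <- function() {
  c(DA = 1, DAp = 0, DR = 1, DRp = 0, MA = 0, A = 0, MR = 0, R = 0, C = 0)
}

# Oscillatory p53 core: p53 (X) is produced constitutively, degraded basally
# and through Mdm2 (Y); p53 drives production of the Mdm2 precursor (Y0)
# which matures into Mdm2.
fixture_p53 <- function(params = list()) {
  p <- merge_params(list(b_x = 90, a_x = 1.1, a_xy = 0.01, b_y = 1.1,
                         a_0 = 0.8, a_y = 0.8), params)
  reaction_network(c("X", "Y0", "Y"), list(
    reaction("make_p53", products = c(X = 1), rate = p$b_x),
    reaction("deg_p53", reactants = c(X = 1), rate = p$a_x),
    reaction("mdm2_deg_p53", reactants = c(X = 1, Y = 1), products = c(Y = 1),
             rate = p$a_xy),
    reaction("make_pre_mdm2", reactants = c(X = 1), products = c(X = 1, Y0 = 1),
             rate = p$b_y),
    reaction("mature_mdm2", reactants = c(Y0 = 1), products = c(Y = 1),
             rate = p$a_0),
    reaction("deg_mdm2", reactants = c(Y = 1), rate = p$a_y)
  ), params = unlist(p))
}

# Open two-species Lotka-Volterra analogue: immigration, reproduction,
# pairwise competition (the first-named individual dies) and death.
fixture_lotka_volterra <- function(params = list()) {
  p <- merge_params(list(b1 = 1, b2 = 1, beta1 = 2, beta2 = 2, d1 = 1, d2 = 1,
                         c11 = 0.01, c12 = 0.002, c21 = 0.002, c22 = 0.01),
                    params)
  reaction_network(c("X1", "X2"), list(
    reaction("imm1", products = c(X1 = 1), rate = p$b1),
    reaction("imm2", products = c(X2 = 1), rate = p$b2),
    reaction("rep1", reactants = c(X1 = 1), products = c(X1 = 2), rate = p$beta1),
    reaction("rep2", reactants = c(X2 = 1), products = c(X2 = 2), rate = p$beta2),
    reaction("comp11", reactants = c(X1 = 2), products = c(X1 = 1), rate = p$c11),
    reaction("comp12", reactants = c(X1 = 1, X2 = 1), products = c(X2 = 1),
             rate = p$c12),
    reaction("comp21", reactants = c(X1 = 1, X2 = 1), products = c(X1 = 1),
             rate = p$c21),
    reaction("comp22", reactants = c(X2 = 2), products = c(X2 = 1), rate = p$c22),
    reaction("death1", reactants = c(X1 = 1), rate = p$d1),
    reaction("death2", reactants = c(X2 = 1), rate = p$d2)
  ), params = unlist(p))
}

# Schlogl model reduced to a single species: birth/death exchange with the
# reservoirs plus the second- and third-order autocatalytic pair.
fixture_schlogl <- function(params = list()) {
  p <- merge_params(list(k1 = 0.03, k2 = 1e-4, k3 = 200, k4 = 3.5), params)
  reaction_network("X", list(
    reaction("autocat2", reactants = c(X = 2), products = c(X = 3), rate = p$k1),
    reaction("autocat3", reactants = c(X = 3), products = c(X = 2), rate = p$k2),
    reaction("birth", products = c(X = 1), rate = p$k3),
    reaction("death", reactants = c(X = 1), rate = p$k4)
  ), params = unlist(p))
}

# Two-type branching picture of carcinogenesis: normal cells N renew, die and
# mutate into M; mutant cells divide and die, supercritically by default.
fixture_carcinogenesis <- function(params = list()) {
  p <- merge_params(list(k_in = 10, d_n = 1, mu = 0.01, b_m = 1.2, d_m = 1),
                    params)
  reaction_network(c("N", "M"), list(
    reaction("influx", products = c(N = 1), rate = p$k_in),
    reaction("death_n", reactants = c(N = 1), rate = p$d_n),
    reaction("mutate", reactants = c(N = 1), products = c(N = 1, M = 1), rate = p$mu),
    reaction("divide_m", reactants = c(M = 1), products = c(M = 2), rate = p$b_m),
    reaction("death_m", reactants = c(M = 1), rate = p$d_m)
  ), params = unlist(p))
}
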