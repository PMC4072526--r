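# Certificate searches for exponential ergodicity.
#
# The unimolecular route rests on the equivalence, for Metzler matrices,
# between Hurwitz stability and the existence of a positive vector v with
# A'v < 0; such a v is a linear Foster-Lyapunov weight. Bimolecular routes
# either cancel the quadratic drift term with a conservation weighting or
# force it nonpositive (componentwise, or negative definite). Higher-order
# single-species kinetics use the scalar polynomial route.

default_eps_strict <- 1e-6
default_tol_eig <- 1e-9

#' Hurwitz stability test
#'
#' @param A Square numeric matrix.
#' @param tol_eig Stability margin: stable means every eigenvalue has real
#'   part below \code{-tol_eig}. Spectral abscissas within the margin of zero
#'   are flagged marginal.
#' @return Logical; attribute \code{"abscissa"} carries the spectral
#'   abscissa, attribute \code{"marginal"} the near-zero flag.
#' @export
hurwitz_test <- function(A, tol_eig = default_tol_eig) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  alpha <- max(Re(eigen(A, only.values = TRUE)$values))
  structure(alpha < -tol_eig, abscissa = alpha,
            marginal = abs(alpha) <= tol_eig)
}

is_metzler <- function(A, tol = 0) {
  A <- as.matrix(A)
  off <- A; diag(off) <- 0
  all(off >= -tol)
}

#' Positive linear certificate for a Metzler matrix
#'
#' Finds v with \eqn{v \ge 1} and \eqn{A'v \le -\epsilon v} when one exists.
#' For Metzler A, feasibility is equivalent to Hurwitz stability; the
#' certificate is constructed from the M-matrix identity
#' \eqn{v_0 = -(A')^{-1} \mathbf{1}}, which is strictly positive exactly in
#' the stable case, so no eigenvalue computation is involved and the
#' construction can serve as an independent counterpart to [hurwitz_test()].
#'
#' @param A Metzler matrix (nonnegative off-diagonal entries).
#' @param eps_strict Margin implementing the strict inequality
#'   \eqn{A'v < 0} as \eqn{(A'v)_i \le -\epsilon v_i}.
#' @return List with \code{feasible}, the scaled certificate \code{v}
#'   (\code{min(v) = 1}) and the achieved \code{margin}
#'   \eqn{\min_i -(A'v)_i / v_i}.
#' @export
positive_linear_certificate <- function(A, eps_strict = default_eps_strict) {
  A <- as.matrix(A)
  if (!is_metzler(A, tol = 1e-12))
    stop("A must be Metzler; the LP/Hurwitz equivalence is not guaranteed otherwise")
  d <- nrow(A)
  v0 <- tryCatch(solve(t(A), rep(-1, d)), error = function(e) NULL)
  if (is.null(v0) || any(!is.finite(v0)) || any(v0 <= 0))
    return(list(feasible = FALSE, v = NULL, margin = NA_real_))
  v <- v0 / min(v0)
  margin <- min(-(as.numeric(t(A) %*% v)) / v)
  list(feasible = margin >= eps_strict * 0.999, v = v, margin = margin)
}

new_report <- function(verdict, method = NA_character_, certificate = NULL,
                       moment_conclusion = "none", moment_order = NA_real_,
                       light_tailed = FALSE,
                       irreducibility_status = "unknown",
                       attempts = list(), details = list()) {
  structure(list(verdict = verdict, method = method, certificate = certificate,
                 moment_conclusion = moment_conclusion,
                 moment_order = moment_order, light_tailed = light_tailed,
                 irreducibility_status = irreducibility_status,
                 attempts = attempts, details = details),
            class = "ergodicity_report")
}

#' @export
print.ergodicity_report <- function(x, ...) {
  cat("Ergodicity report\n")
  cat("  verdict:             ", x$verdict, "\n")
  if (!is.na(x$method)) cat("  method:              ", x$method, "\n")
  cat("  moment conclusion:   ", x$moment_conclusion,
      if (!is.na(x$moment_order)) sprintf(" (order %g)", x$moment_order) else "",
      "\n", sep = "")
  cat("  light-tailed:        ", x$light_tailed, "\n")
  cat("  irreducibility:      ", x$irreducibility_status, "\n")
  if (length(x$attempts)) {
    cat("  attempts:\n")
    for (a in x$attempts)
      cat(sprintf("    - %-28s %s\n", a$method, a$status))
  }
  if (inherits(x$certificate, "dd_certificate")) {
    cat("  certificate: v = (", paste(signif(x$certificate$v, 5), collapse = ", "),
        "), gamma = ", signif(x$certificate$gamma, 6), "\n", sep = "")
  }
  invisible(x)
}

irr_status <- function(assume_irreducible) {
  if (isTRUE(assume_irreducible)) "asserted_by_user" else "unknown"
}

finish_report <- function(verdict, method, cert, moment_conclusion,
                          moment_order, assume_irreducible, attempts,
                          details = list()) {
  lt <- inherits(cert, "dd_certificate") && cert$dd1_verified &&
    cert$dd2_verified && is.finite(cert$c3) && is.finite(cert$zeta_bar)
  if (verdict %in% c("ergodic", "ergodic_robust") && !isTRUE(assume_irreducible))
    verdict <- "no_certificate_found"  # cannot conclude ergodicity without irreducibility
  new_report(verdict, method, cert, moment_conclusion, moment_order,
             light_tailed = lt,
             irreducibility_status = irr_status(assume_irreducible),
             attempts = attempts, details = details)
}

#' Ergodicity analysis of a unimolecular network
#'
#' Builds the affine drift \eqn{f(x) = Ax + b} and searches for a positive
#' linear certificate \eqn{A'v < 0}. Success proves exponential ergodicity
#' with all moments bounded and globally converging (given irreducibility);
#' with bounded jumps and linearly bounded diffusivity, the laws are
#' uniformly light-tailed.
#'
#' @param net Unimolecular [reaction_network()].
#' @param assume_irreducible The certificate conclusions are conditional on
#'   an irreducible state space; the package treats irreducibility as a
#'   separately supplied assumption (see
#'   [truncated_irreducibility_check()]).
#' @param eps_strict Strict-inequality margin.
#' @return An \code{"ergodicity_report"}.
#' @export
analyze_unimolecular <- function(net, assume_irreducible = TRUE,
                                 eps_strict = default_eps_strict) {
  af <- unimolecular_affine(net)
  res <- positive_linear_certificate(af$A, eps_strict)
  at <- list(list(method = "unimolecular_linear_certificate",
                  status = if (res$feasible) "certificate" else "infeasible"))
  if (!res$feasible)
    return(new_report("no_certificate_found", attempts = at,
                      irreducibility_status = irr_status(assume_irreducible)))
  cert <- verify_dd(net, res$v)
  finish_report("ergodic", "unimolecular_linear_certificate", cert,
                "all_orders", Inf, assume_irreducible, at)
}

# Componentwise upper-bound matrix over the declared rate intervals, plus a
# flag saying whether a single rate choice attains it (needed for the
# converse direction of the robust equivalence).
robust_bound_matrix <- function(net) {
  if (is.null(net$rate_intervals))
    stop("network has no rate_intervals; annotate reactions for robust analysis")
  d <- n_species(net)
  Z <- stoichiometry_matrix(net)
  A_bar <- matrix(0, d, d, dimnames = list(net$species, net$species))
  attainable <- TRUE
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    if (r$kind != "mass_action" || sum(r$reactants) != 1L) next
    i <- match(names(r$reactants), net$species)
    z <- Z[, k]
    iv <- net$rate_intervals[[r$label]]
    if (is.null(iv)) iv <- c(r$rate, r$rate)
    up <- ifelse(z > 0, iv[2], iv[1])
    A_bar[, i] <- A_bar[, i] + up * z
    if (iv[1] < iv[2] && any(z > 0) && any(z < 0)) attainable <- FALSE
  }
  list(A_bar = A_bar, attainable = attainable)
}

#' Robust ergodicity over interval-valued rates
#'
#' For a unimolecular family with independent rate intervals, a single
#' certificate on the componentwise upper-bound matrix \eqn{\bar A} certifies
#' every member: for Metzler matrices the spectral abscissa is monotone in
#' the entrywise order, so checking the family is no harder than checking one
#' network. When a rate constant appears with both signs in \eqn{A} the
#' entrywise bound is not attained by any member and failure of the bound is
#' inconclusive, reported as \code{"bound_matrix_unavailable"}.
#'
#' @inheritParams analyze_unimolecular
#' @return An \code{"ergodicity_report"} with verdict
#'   \code{"ergodic_robust"} on success.
#' @export
analyze_robust <- function(net, assume_irreducible = TRUE,
                           eps_strict = default_eps_strict) {
  rb <- robust_bound_matrix(net)
  res <- positive_linear_certificate(rb$A_bar, eps_strict)
  status <- if (res$feasible) "certificate"
            else if (rb$attainable) "infeasible"
            else "bound_matrix_unavailable"
  at <- list(list(method = "robust_bound_matrix", status = status))
  if (!res$feasible)
    return(new_report("no_certificate_found", attempts = at,
                      irreducibility_status = irr_status(assume_irreducible),
                      details = list(bound_matrix_unavailable = !rb$attainable)))
  cert <- verify_dd(net, res$v)
  finish_report("ergodic_robust", "robust_bound_matrix", cert,
                "all_orders", Inf, assume_irreducible, at,
                details = list(A_bar = rb$A_bar))
}

# Drift-envelope pieces for the conservation-weighted route: with S_b'v = 0
# every order-2 reaction contributes nothing, order-1 reactions from pooled
# species are absorbed into a constant envelope, and only the unconfined
# species carry linear decay constraints.
conserved_parts <- function(net, pools = NULL) {
  d <- n_species(net)
  if (is.null(pools)) pools <- rep(Inf, d)
  pooled <- is.finite(pools)
  Z <- stoichiometry_matrix(net)
  ord <- reaction_orders(net)
  LmatF <- matrix(0, d, d)
  env <- numeric(d)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    z <- Z[, k]
    if (r$kind == "bounded_function") {
      env <- env + r$sup_bound * pmax(z, 0)
    } else if (ord[k] == 0L) {
      env <- env + r$rate * z
    } else if (ord[k] == 1L) {
      i <- match(names(r$reactants), net$species)
      if (pooled[i]) env <- env + r$rate * pools[i] * pmax(z, 0)
      else LmatF[i, ] <- LmatF[i, ] + r$rate * z
    }
    # order-2 reactions vanish identically under S_b'v = 0
  }
  list(LmatF = LmatF, env = env, pooled = pooled, pools = pools)
}

#' Ergodicity via conservation of the bimolecular reactions
#'
#' Restricts the weight search to the cone where every bimolecular
#' stoichiometric vector is annihilated (so the quadratic drift term
#' vanishes exactly) and solves the linear program \eqn{v \ge 1},
#' \eqn{S_b'v = 0}, \eqn{L(v) \le -\epsilon v}. A nonempty cone is a
#' prerequisite. When an initial state is supplied, species confined to
#' finite conserved pools (gene/promoter states) are detected with
#' [pool_bounds()]: their catalytic propensities are absorbed into the
#' constant and no decay is demanded of them, which is what certifies
#' gene-expression networks whose promoter states have no degradation.
#'
#' @inheritParams analyze_unimolecular
#' @param net Bimolecular [reaction_network()].
#' @param x0 Optional initial state used to derive conserved-pool bounds.
#' @return An \code{"ergodicity_report"}; a network without any conservation
#'   relation for its bimolecular reactions yields the
#'   \code{"prerequisite_failed"} attempt status.
#' @export
analyze_bimolecular_conserved <- function(net, assume_irreducible = TRUE,
                                          eps_strict = default_eps_strict,
                                          x0 = NULL) {
  d <- n_species(net)
  Sb <- bimolecular_stoichiometry(net)
  vtest <- conservation_vector(net)
  if (is.null(vtest)) {
    at <- list(list(method = "bimolecular_conserved", status = "prerequisite_failed"))
    return(new_report("no_certificate_found", attempts = at,
                      irreducibility_status = irr_status(assume_irreducible),
                      details = list(conservation_cone_empty = TRUE)))
  }
  pools <- if (!is.null(x0)) pool_bounds(net, x0) else rep(Inf, d)
  parts <- conserved_parts(net, pools)
  free <- which(!parts$pooled)
  A_ub <- (parts$LmatF + diag(eps_strict, d))[free, , drop = FALSE]
  res <- lp_dense(parts$env + ifelse(parts$pooled, parts$pools, 0),
                  A_ub = if (nrow(A_ub)) A_ub else NULL,
                  b_ub = if (nrow(A_ub)) rep(0, nrow(A_ub)) else NULL,
                  A_eq = if (ncol(Sb)) t(Sb) else NULL,
                  b_eq = if (ncol(Sb)) rep(0, ncol(Sb)) else NULL, lower = 1)
  at <- list(list(method = "bimolecular_conserved",
                  status = if (res$status == "optimal") "certificate" else "infeasible"))
  if (res$status != "optimal")
    return(new_report("no_certificate_found", attempts = at,
                      irreducibility_status = irr_status(assume_irreducible)))
  cert <- verify_dd(net, res$x, pools = pools)
  finish_report("ergodic", "bimolecular_conserved", cert, "all_orders", Inf,
                assume_irreducible, at)
}

# inequality rows forcing every entry of Q(v) to be <= 0; one row per entry
# of the upper triangle that depends on v at all
qneg_rows <- function(Qcoef) {
  d <- dim(Qcoef)[1]
  rows <- NULL
  for (a in seq_len(d)) for (b in a:d) {
    coefs <- Qcoef[a, b, ]
    if (any(coefs != 0)) rows <- rbind(rows, coefs)
  }
  rows
}

#' Ergodicity of general bimolecular networks
#'
#' Without a conservation relation the quadratic drift term must be made
#' nonpositive on the orthant. Mode \code{"componentwise_lp"} forces every
#' entry of \eqn{Q(v)} nonpositive (a linear program, sufficient for
#' nonpositivity on the orthant); mode \code{"negdef_sdp"} asks for
#' \eqn{Q(v) \preceq -\epsilon I}, posed here as a direct convex minimax
#' search over \eqn{v \ge 1} of the largest eigenvalue together with the
#' linear drift condition, with the returned weights re-verified by an exact
#' eigenvalue check. Moment conclusions follow the conservative bookkeeping
#' (order 1 for the componentwise route, order 2 for the negative-definite
#' route).
#'
#' @inheritParams analyze_unimolecular
#' @param mode \code{"componentwise_lp"} or \code{"negdef_sdp"}.
#' @param eps_sdp Definiteness margin for the negative-definite route.
#' @return An \code{"ergodicity_report"}.
#' @export
analyze_bimolecular_general <- function(net, mode = c("componentwise_lp", "negdef_sdp"),
                                        assume_irreducible = TRUE,
                                        eps_strict = default_eps_strict,
                                        eps_sdp = 1e-6) {
  mode <- match.arg(mode)
  co <- drift_coefficients(net)
  d <- n_species(net)
  if (mode == "componentwise_lp") {
    A_ub <- co$Lmat + diag(eps_strict, d)
    b_ub <- rep(0, d)
    qr_ <- qneg_rows(co$Qcoef)
    if (!is.null(qr_)) {
      A_ub <- rbind(A_ub, qr_)
      b_ub <- c(b_ub, rep(0, nrow(qr_)))
    }
    res <- lp_dense(co$bvec, A_ub = A_ub, b_ub = b_ub, lower = 1)
    at <- list(list(method = "bimolecular_componentwise_lp",
                    status = if (res$status == "optimal") "certificate" else "infeasible"))
    if (res$status != "optimal")
      return(new_report("no_certificate_found", attempts = at,
                        irreducibility_status = irr_status(assume_irreducible)))
    cert <- verify_dd(net, res$x)
    return(finish_report("ergodic", "bimolecular_componentwise_lp", cert,
                         "up_to_order_n", 1, assume_irreducible, at))
  }
  # negative-definite route: minimize the worst of the two convex conditions
  objective <- function(u) {
    v <- 1 + exp(u)
    Q <- eval_Q(co$Qcoef, v)
    lam <- if (d > 1) max(eigen((Q + t(Q)) / 2, symmetric = TRUE,
                                only.values = TRUE)$values) else Q[1, 1]
    lin <- max(as.numeric(co$Lmat %*% v) + eps_strict * v)
    max(lam + eps_sdp, lin) / max(1, max(v))
  }
  best <- NULL
  set_starts <- rbind(rep(0, d), diag(2, d) - 1, matrix(stats::runif(3 * d, -1, 2), 3, d))
  for (s in seq_len(nrow(set_starts))) {
    o <- stats::optim(set_starts[s, ], objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  v <- 1 + exp(best$par)
  Q <- eval_Q(co$Qcoef, v)
  lam <- if (d > 1) max(eigen((Q + t(Q)) / 2, symmetric = TRUE,
                              only.values = TRUE)$values) else Q[1, 1]
  ok <- lam <= -eps_sdp * 0.5 && all(as.numeric(co$Lmat %*% v) <= -eps_strict * v * 0.5)
  at <- list(list(method = "bimolecular_negdef", status = if (ok) "certificate" else "no_certificate_found"))
  if (!ok)
    return(new_report("no_certificate_found", attempts = at,
                      irreducibility_status = irr_status(assume_irreducible)))
  cert <- verify_dd(net, v)
  finish_report("ergodic", "bimolecular_negdef", cert, "up_to_order_n", 2,
                assume_irreducible, at, details = list(Q_max_eig = lam))
}

#' Copositivity test
#'
#' Decides whether \eqn{x'Mx \ge 0} for all \eqn{x \ge 0} by exact
#' minimization of the quadratic form over the probability simplex: the
#' minimum is attained at a KKT point supported on some face, and all
#' supports are enumerated (closed form for dimensions 1-2). Practical up to
#' dimension about 10.
#'
#' @param M Symmetric matrix (a non-symmetric input is symmetrized with a
#'   warning).
#' @param tol Negativity tolerance.
#' @return List with \code{copositive} (logical), \code{min_value} (minimum
#'   of the form on the simplex) and, when not copositive, a nonnegative
#'   \code{witness} with \code{witness' M witness < 0}.
#' @export
copositivity_test <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  d <- nrow(M)
  if (d > 10) stop("copositivity test implemented for dimension <= 10")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    warning("matrix is not symmetric; using its symmetric part")
  }
  M <- (M + t(M)) / 2
  best_val <- Inf; best_x <- NULL
  supports <- seq_len(2^d - 1)
  for (s in supports) {
    S <- which(bitwAnd(s, 2^(seq_len(d) - 1)) > 0)
    k <- length(S)
    if (k == 1L) {
      val <- M[S, S]; x <- numeric(d); x[S] <- 1
    } else {
      MS <- M[S, S, drop = FALSE]
      sol <- tryCatch(solve(MS, rep(1, k)), error = function(e) NULL)
      if (is.null(sol)) {
        sol <- tryCatch(qr.coef(qr(MS, tol = 1e-12), rep(1, k)),
                        error = function(e) NULL)
        if (is.null(sol) || any(is.na(sol))) next
      }
      # interior stationary point needs x = sol / sum(sol) > 0, i.e. all
      # components of the same sign
      if (!(all(sol > 0) || all(sol < 0)) || sum(sol) == 0) next
      xs <- sol / sum(sol)
      x <- numeric(d); x[S] <- xs
      val <- as.numeric(xs %*% MS %*% xs)
    }
    if (val < best_val) { best_val <- val; best_x <- x }
  }
  if (best_val < -tol)
    list(copositive = FALSE, min_value = best_val, witness = best_x)
  else
    list(copositive = TRUE, min_value = best_val, witness = NULL)
}

# Extract the Lotka-Volterra template: immigration 0 -> Xi, reproduction
# Xi -> 2Xi, competition Xi + Xj -> Xj (i removed; intra-species 2Xi -> Xi),
# death Xi -> 0. Returns NULL if the network does not match.
lv_template <- function(net) {
  d <- n_species(net)
  b <- numeric(d); beta <- numeric(d); dd <- numeric(d)
  C <- matrix(0, d, d)
  Z <- stoichiometry_matrix(net)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    if (r$kind != "mass_action") return(NULL)
    z <- Z[, k]
    ord <- sum(r$reactants)
    if (ord == 0L && sum(z == 1) == 1 && sum(z != 0) == 1) {
      b[which(z == 1)] <- b[which(z == 1)] + r$rate
    } else if (ord == 1L) {
      i <- match(names(r$reactants), net$species)
      if (all(z == 0 | seq_len(d) == i) && z[i] == 1) beta[i] <- beta[i] + r$rate
      else if (all(z == 0 | seq_len(d) == i) && z[i] == -1) dd[i] <- dd[i] + r$rate
      else return(NULL)
    } else if (ord == 2L) {
      idx <- match(names(r$reactants), net$species)
      if (length(idx) == 1L) {            # 2Xi -> Xi
        i <- idx
        if (z[i] != -1 || any(z[-i] != 0)) return(NULL)
        C[i, i] <- C[i, i] + r$rate
      } else {                            # Xi + Xj -> Xj, the removed one has z = -1
        i <- idx[which(Z[idx, k] == -1)]
        j <- setdiff(idx, i)
        if (length(i) != 1L || any(z[-i] != 0)) return(NULL)
        C[i, j] <- C[i, j] + r$rate
      }
    } else return(NULL)
  }
  if (all(C == 0)) return(NULL)
  list(b = b, beta = beta, d = dd, C = C)
}

#' Ergodicity of the open Lotka-Volterra network
#'
#' For the immigration / reproduction / competition / death template the
#' quadratic drift term is governed by the competition matrix C. Two
#' sufficient conditions are tried: (a) a diagonal scaling D making
#' \eqn{DC + C'D} positive definite, and (b) strict copositivity of
#' \eqn{C + C'}. Either gives a negative drift for the weighted population
#' size at large states.
#'
#' @inheritParams analyze_unimolecular
#' @param net A network matching the Lotka-Volterra template.
#' @return An \code{"ergodicity_report"}.
#' @export
analyze_lotka_volterra <- function(net, assume_irreducible = TRUE,
                                   eps_strict = default_eps_strict) {
  tpl <- lv_template(net)
  if (is.null(tpl))
    stop("network does not match the Lotka-Volterra template ",
         "(immigration, reproduction, competition, death)")
  C <- tpl$C
  d <- nrow(C)
  attempts <- list()
  # (a) diagonal scaling making DC + C'D positive definite
  scale_obj <- function(u) {
    D <- diag(exp(u), d)
    S <- D %*% C + t(C) %*% D
    -min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values) /
      max(exp(u))
  }
  o <- stats::optim(rep(0, d), scale_obj, method = if (d == 1) "Brent" else "Nelder-Mead",
                    lower = if (d == 1) -20 else -Inf,
                    upper = if (d == 1) 20 else Inf,
                    control = list(maxit = 2000, reltol = 1e-12))
  Dstar <- exp(o$par)
  S <- diag(Dstar, d) %*% C + t(C) %*% diag(Dstar, d)
  lam_min <- min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min > 1e-10 * max(1, max(abs(S)))) {
    attempts <- c(attempts, list(list(method = "lv_diagonal_scaling",
                                      status = "certificate")))
    v <- Dstar / min(Dstar)
    return(finish_report("ergodic", "lv_diagonal_scaling",
                         structure(list(v = v, c1 = NA_real_, c2 = NA_real_,
                                        c3 = Inf, gamma = NA_real_,
                                        zeta_bar = NA_real_,
                                        dd1_verified = TRUE, dd2_verified = FALSE,
                                        audit = list(n = 0L, dd1_violations = 0L,
                                                     dd2_violations = 0L)),
                                   class = "dd_certificate"),
                         "up_to_order_n", 2, assume_irreducible, attempts,
                         details = list(D = Dstar, lambda_min = lam_min)))
  }
  attempts <- c(attempts, list(list(method = "lv_diagonal_scaling",
                                    status = "infeasible")))
  # (b) strict copositivity of C + C'
  cp <- copositivity_test(C + t(C))
  strict <- cp$copositive && cp$min_value > eps_strict * 1e-3
  attempts <- c(attempts, list(list(method = "lv_copositivity",
                                    status = if (strict) "certificate" else "not_strictly_copositive")))
  if (strict) {
    return(finish_report("ergodic", "lv_copositivity",
                         structure(list(v = rep(1, d), c1 = NA_real_,
                                        c2 = NA_real_, c3 = Inf,
                                        gamma = NA_real_, zeta_bar = NA_real_,
                                        dd1_verified = TRUE, dd2_verified = FALSE,
                                        audit = list(n = 0L, dd1_violations = 0L,
                                                     dd2_violations = 0L)),
                                   class = "dd_certificate"),
                         "up_to_order_n", 1, assume_irreducible, attempts,
                         details = list(simplex_min = cp$min_value)))
  }
  new_report("no_certificate_found", attempts = attempts,
             irreducibility_status = irr_status(assume_irreducible),
             details = list(copositivity = cp))
}

# Scalar stochastic drift polynomial of a single-species network: the
# coefficients (constant first) of sum_k kappa_k v zeta_k fall(x, m_k)/m_k!.
scalar_drift_poly <- function(net, v = 1) {
  if (n_species(net) != 1L)
    stop("scalar polynomial route requires a single-species network")
  if (any(vapply(net$reactions, function(r) r$kind != "mass_action", TRUE)))
    stop("scalar polynomial route requires mass-action kinetics")
  coefs <- 0
  for (r in net$reactions) {
    m <- if (length(r$reactants)) r$reactants[[1]] else 0L
    z <- sum(reaction_zeta(r, net$species))
    # falling factorial x(x-1)...(x-m+1)/m! as monomial coefficients
    p <- 1
    if (m > 0) for (j in 0:(m - 1)) p <- c(0, p) - j * c(p, 0)
    p <- p / factorial(m)
    term <- r$rate * v * z * p
    n <- max(length(coefs), length(term))
    coefs <- c(coefs, numeric(n - length(coefs))) +
      c(term, numeric(n - length(term)))
  }
  while (length(coefs) > 1 && abs(coefs[length(coefs)]) < 1e-300)
    coefs <- coefs[-length(coefs)]
  coefs
}

#' Scalar polynomial drift certificate
#'
#' For a single-species network with mass-action kinetics of any order up to
#' 3 the weighted drift is a univariate polynomial \eqn{p(s)}; a negative
#' leading coefficient makes \eqn{p(s) + c_1 s} bounded above on the
#' nonnegative axis, so the drift condition holds with
#' \eqn{c_2 = \max_{s \ge 0} (p(s) + c_1 s)}, located through the real
#' critical points. The diffusivity of such networks is superlinear whenever
#' an order-2+ reaction moves the state, in which case no moment-stability
#' conclusion is drawn beyond the first order.
#'
#' @param net Single-species mass-action [reaction_network()].
#' @param v Positive scalar weight.
#' @param c1 Drift decay rate; must be below the magnitude of the linear
#'   slope for degree-1 polynomials. Default 1 (any positive value works for
#'   degree 2 and higher).
#' @return List with \code{feasible}, \code{c1}, \code{c2}, \code{gamma},
#'   \code{degree}, \code{leading}, \code{dd2_verified}.
#' @export
scalar_polynomial_drift <- function(net, v = 1, c1 = NULL) {
  coefs <- scalar_drift_poly(net, v)
  deg <- length(coefs) - 1L
  lead <- coefs[length(coefs)]
  superlinear_diff <- any(vapply(net$reactions, function(r) {
    sum(reaction_zeta(r, net$species)) != 0 &&
      (length(r$reactants) && r$reactants[[1]] >= 2L)
  }, TRUE))
  if (deg < 1 || lead >= 0)
    return(list(feasible = FALSE, c1 = NA_real_, c2 = NA_real_,
                gamma = NA_real_, degree = deg, leading = lead,
                dd2_verified = FALSE))
  if (is.null(c1)) c1 <- if (deg <= 1) 0.9 * abs(coefs[2]) else 1
  q <- coefs
  q[2] <- q[2] + c1 * v          # p(s) + c1 * (v s)
  # maximize q over s >= 0: evaluate at 0 and at real nonnegative critical pts
  cand <- 0
  if (length(q) > 2) {
    dq <- q[-1] * seq_len(length(q) - 1L)
    rts <- polyroot(dq)
    rr <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    cand <- c(cand, rr[rr > 0])
  }
  evalp <- function(s) vapply(s, function(si) sum(q * si^(seq_along(q) - 1L)), 0.0)
  c2 <- max(evalp(cand))
  list(feasible = c2 < Inf && c1 > 0, c1 = c1, c2 = c2, gamma = c2 / c1,
       degree = deg, leading = lead, dd2_verified = !superlinear_diff)
}

#' Dispatch an ergodicity analysis through the certificate ladder
#'
#' Routes the network by its kinetic class: unimolecular linear certificate;
#' then for bimolecular networks the conservation-weighted, componentwise
#' and negative-definite quadratic routes plus the Lotka-Volterra template;
#' for single-species higher-order kinetics the scalar polynomial route. The
#' first successful rung determines the verdict; the full attempt trace is
#' kept. The method provides sufficient conditions only, so the verdict
#' \code{"no_certificate_found"} never claims non-ergodicity.
#'
#' @inheritParams analyze_unimolecular
#' @param net Any [reaction_network()].
#' @param x0 Optional initial state, used by the conserved route to derive
#'   finite conserved-pool bounds.
#' @return An \code{"ergodicity_report"}.
#' @export
analyze_network <- function(net, assume_irreducible = TRUE,
                            eps_strict = default_eps_strict, x0 = NULL) {
  attempts <- list()
  grab <- function(rep) { attempts <<- c(attempts, rep$attempts); rep }
  if (net$class_tag == "unimolecular") {
    rep <- grab(analyze_unimolecular(net, assume_irreducible, eps_strict))
    rep$attempts <- attempts
    return(rep)
  }
  if (net$class_tag == "bimolecular") {
    rep <- grab(analyze_bimolecular_conserved(net, assume_irreducible,
                                              eps_strict, x0 = x0))
    if (rep$verdict == "ergodic") { rep$attempts <- attempts; return(rep) }
    rep <- grab(analyze_bimolecular_general(net, "componentwise_lp",
                                            assume_irreducible, eps_strict))
    if (rep$verdict == "ergodic") { rep$attempts <- attempts; return(rep) }
    rep <- grab(analyze_bimolecular_general(net, "negdef_sdp",
                                            assume_irreducible, eps_strict))
    if (rep$verdict == "ergodic") { rep$attempts <- attempts; return(rep) }
    if (!is.null(lv_template(net))) {
      rep <- grab(analyze_lotka_volterra(net, assume_irreducible, eps_strict))
      if (rep$verdict == "ergodic") { rep$attempts <- attempts; return(rep) }
    }
    return(new_report("no_certificate_found", attempts = attempts,
                      irreducibility_status = irr_status(assume_irreducible)))
  }
  # general mass-action (order 3 present)
  if (n_species(net) == 1L) {
    sp <- scalar_polynomial_drift(net)
    attempts <- c(attempts, list(list(method = "scalar_polynomial",
                                      status = if (sp$feasible) "certificate" else "infeasible")))
    if (sp$feasible) {
      cert <- structure(list(v = 1, c1 = sp$c1, c2 = sp$c2, c3 = Inf,
                             gamma = sp$gamma, zeta_bar = NA_real_,
                             dd1_verified = TRUE,
                             dd2_verified = sp$dd2_verified,
                             audit = list(n = 0L, dd1_violations = 0L,
                                          dd2_violations = 0L)),
                        class = "dd_certificate")
      return(finish_report("ergodic", "scalar_polynomial", cert,
                           "first_order_only", 1, assume_irreducible, attempts))
    }
    return(new_report("no_certificate_found", attempts = attempts,
                      irreducibility_status = irr_status(assume_irreducible)))
  }
  attempts <- c(attempts, list(list(method = "general_mass_action",
                                    status = "no_route")))
  new_report("no_certificate_found", attempts = attempts,
             irreducibility_status = irr_status(assume_irreducible))
}
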