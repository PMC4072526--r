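# Exact decomposition of the v-weighted drift of the count process.
#
# For a network with stochastic mass-action kinetics the drift of <v, X(t)>
# is a polynomial in the state. For reactions of order <= 2 it decomposes
# exactly as
#     <v, f(x)> = x' Q(v) x + L(v)' x + c(v),
# where the falling-factorial part of a homodimerization propensity
# kappa x (x - 1) / 2 contributes kappa/2 to the quadratic term and -kappa/2
# to the linear term. All coefficient arrays below are linear in v so the
# certificate searches can pose linear constraints on them.

#' Evaluate stochastic propensities
#'
#' Mass-action propensities use the falling-factorial convention
#' \eqn{\kappa \prod_i {x_i \choose m_i} m_i!/m_i! = \kappa \prod_i x_i (x_i-1) \cdots / m_i!},
#' i.e. \eqn{\kappa x(x-1)/2} for a homodimerization. Bounded propensities
#' are evaluated through their \code{eval_hint} (an error if absent:
#' certificate computations should use the supremum instead).
#'
#' @param net A [reaction_network()].
#' @param x Nonnegative integer state vector.
#' @return Nonnegative numeric vector with one propensity per reaction.
#' @export
propensities <- function(net, x) {
  x <- check_state(net, x)
  vapply(net$reactions, function(r) propensity_one(net, r, x), 0.0)
}

propensity_one <- function(net, r, x) {
  if (r$kind == "bounded_function") {
    if (is.null(r$eval_hint))
      stop("bounded reaction '", r$label,
           "' has no eval_hint; analysis paths must use sup_bound")
    env <- as.list(stats::setNames(x, net$species))
    if (!is.null(net$params)) env <- c(env, as.list(net$params))
    val <- eval(parse(text = r$eval_hint), envir = env)
    return(max(0, min(val, r$sup_bound)))
  }
  p <- r$rate
  if (length(r$reactants)) {
    idx <- match(names(r$reactants), net$species)
    for (q in seq_along(idx)) {
      m <- r$reactants[[q]]
      xi <- x[idx[q]]
      if (xi < m) return(0)
      p <- p * prod(xi - seq_len(m) + 1) / factorial(m)
    }
  }
  p
}

#' Drift vector of the count process
#'
#' The exact finite sum \eqn{f(x) = \sum_k \lambda_k(x) \zeta_k}. Bounded
#' reactions require an \code{eval_hint}.
#'
#' @inheritParams propensities
#' @return Numeric vector of length d.
#' @export
drift_vector <- function(net, x) {
  lam <- propensities(net, x)
  as.numeric(stoichiometry_matrix(net) %*% lam)
}

#' Diffusivity of the weighted process
#'
#' \eqn{\sum_k \lambda_k(x) \langle v, \zeta_k \rangle^2}, the quadratic
#' variation rate of \eqn{\langle v, X(t)\rangle}.
#'
#' @inheritParams propensities
#' @param v Positive weight vector.
#' @return Nonnegative scalar.
#' @export
diffusivity <- function(net, v, x) {
  v <- check_weight(net, v)
  lam <- propensities(net, x)
  vz <- as.numeric(crossprod(stoichiometry_matrix(net), v))
  sum(lam * vz^2)
}

# Coefficient arrays of the weighted-drift decomposition. Returns:
#   Qcoef: d x d x d, Q(v)[a,b] = sum_i Qcoef[a,b,i] v[i]
#   Lmat:  d x d, L(v) = Lmat %*% v  (row a: coefficient of x_a)
#   Amat:  the affine drift matrix (first-order part, no corrections)
#   ccoef: c(v) = sum(ccoef * v) from zero-order reactions
#   bvec:  upper envelope of the constant drift, zero-order plus bounded
#          reactions at sup * pmax(zeta, 0)
# Superlinear (order-3) reactions are refused.
drift_coefficients <- function(net) {
  d <- n_species(net)
  Z <- stoichiometry_matrix(net)
  Qcoef <- array(0, c(d, d, d))
  Lmat <- matrix(0, d, d)
  Amat <- matrix(0, d, d, dimnames = list(net$species, net$species))
  ccoef <- numeric(d)
  bvec <- numeric(d)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    z <- Z[, k]
    if (r$kind == "bounded_function") {
      bvec <- bvec + r$sup_bound * pmax(z, 0)
      next
    }
    ord <- sum(r$reactants)
    if (ord == 0L) {
      ccoef <- ccoef + r$rate * z
      bvec <- bvec + r$rate * z
    } else if (ord == 1L) {
      i <- match(names(r$reactants), net$species)
      Lmat[i, ] <- Lmat[i, ] + r$rate * z
      Amat[, i] <- Amat[, i] + r$rate * z
    } else if (ord == 2L) {
      idx <- match(names(r$reactants), net$species)
      if (length(idx) == 1L) {       # 2 S_a: kappa x(x-1)/2
        a <- idx
        Qcoef[a, a, ] <- Qcoef[a, a, ] + r$rate * z / 2
        Lmat[a, ] <- Lmat[a, ] - r$rate * z / 2
      } else {                       # S_a + S_b: kappa x_a x_b
        a <- idx[1]; b <- idx[2]
        Qcoef[a, b, ] <- Qcoef[a, b, ] + r$rate * z / 2
        Qcoef[b, a, ] <- Qcoef[b, a, ] + r$rate * z / 2
      }
    } else {
      stop("reaction '", r$label, "' has order ", ord,
           "; the quadratic decomposition covers orders <= 2 ",
           "(see scalar_polynomial_drift for the scalar higher-order route)")
    }
  }
  list(Qcoef = Qcoef, Lmat = Lmat, Amat = Amat, ccoef = ccoef, bvec = bvec)
}

eval_Q <- function(Qcoef, v) {
  d <- length(v)
  Q <- matrix(0, d, d)
  for (i in seq_len(d)) Q <- Q + v[i] * Qcoef[, , i]
  Q
}

#' Affine drift of a unimolecular network
#'
#' For a network whose mass-action reactions all have order 0 or 1 the drift
#' is exactly \eqn{f(x) = A x + b} with A built from the first-order
#' reactions (column i collects \eqn{\kappa_k \zeta_k} over reactions with
#' reactant i) and b from the zero-order rates plus, for bounded reactions,
#' the conservative envelope \eqn{\sup_k \max(\zeta_k, 0)}. A is Metzler
#' (nonnegative off-diagonal) for every valid network.
#'
#' @param net A unimolecular [reaction_network()].
#' @return List with matrix \code{A} and vector \code{b}.
#' @export
unimolecular_affine <- function(net) {
  if (net$class_tag != "unimolecular")
    stop("network is ", net$class_tag,
         "; use quadratic_drift / the bimolecular analyses instead")
  co <- drift_coefficients(net)
  list(A = co$Amat, b = co$bvec)
}

#' Quadratic form of the weighted drift
#'
#' Returns the exact decomposition
#' \eqn{\langle v, f(x)\rangle = x' Q(v) x + L(v)' x + c(v)} for networks of
#' mass-action order at most 2. The falling-factorial part of
#' homodimerization propensities is folded into the linear term, so the
#' identity holds for the true stochastic drift on the integer lattice (and,
#' by polynomial identity, on all of \eqn{R^d}). Bounded reactions are not
#' part of the identity; their envelope is reported separately.
#'
#' @param net A [reaction_network()] of order at most 2.
#' @param v Positive weight vector.
#' @return List with symmetric matrix \code{Q}, vector \code{linear}, scalar
#'   \code{const} (zero-order mass-action part) and scalar
#'   \code{bounded_const} (the bounded-reaction envelope
#'   \eqn{\sum_k \sup_k \langle v, \max(\zeta_k, 0)\rangle}).
#' @export
quadratic_drift <- function(net, v) {
  v <- check_weight(net, v)
  co <- drift_coefficients(net)
  list(Q = eval_Q(co$Qcoef, v),
       linear = as.numeric(co$Lmat %*% v),
       const = sum(co$ccoef * v),
       bounded_const = sum(co$bvec * v) - sum(co$ccoef * v))
}

#' Conservation weights for the bimolecular reactions
#'
#' Searches for a positive vector annihilating every order-2 stoichiometric
#' vector, i.e. a weighting under which the quadratic drift term vanishes
#' identically. Feasibility is decided by the linear program
#' \eqn{\{v \ge 1,\ S_b' v = 0\}}; a necessary condition is that the
#' bimolecular stoichiometry is not of full row rank.
#'
#' @param net A [reaction_network()].
#' @return A weight vector with \code{min(v) = 1}, or \code{NULL} when no
#'   conservation relation exists (emptiness is a result, not an error).
#' @export
conservation_vector <- function(net) {
  Sb <- bimolecular_stoichiometry(net)
  d <- n_species(net)
  if (ncol(Sb) == 0L) return(rep(1, d))
  res <- lp_dense(rep(1, d), A_eq = t(Sb), b_eq = rep(0, ncol(Sb)), lower = 1)
  if (res$status != "optimal") return(NULL)
  v <- res$x
  v / min(v)
}

#' Per-species bounds from conserved pools
#'
#' A species whose count enters a nonnegative conservation relation is
#' confined to a finite pool: if \eqn{w \ge 0}, \eqn{w_i \ge 1} and
#' \eqn{w'\zeta_k = 0} for every reaction, then
#' \eqn{x_i(t) \le w'x_0 / w_i} forever. Gene copy numbers (free plus bound
#' promoter states) are the typical case. Certificate computations use these
#' bounds to absorb catalytic propensities from pooled species into
#' constants.
#'
#' @param net A [reaction_network()].
#' @param x0 Initial state determining the pool totals.
#' @return Numeric vector of per-species bounds (\code{Inf} for species not
#'   confined by any conservation relation).
#' @export
pool_bounds <- function(net, x0) {
  x0 <- check_state(net, x0)
  d <- n_species(net)
  Z <- stoichiometry_matrix(net)
  B <- rep(Inf, d)
  for (i in seq_len(d)) {
    lo <- numeric(d); lo[i] <- 1
    res <- lp_dense(x0 + 1e-6, A_eq = t(Z), b_eq = rep(0, ncol(Z)), lower = lo)
    if (res$status == "optimal") B[i] <- sum(res$x * x0) / res$x[i]
  }
  stats::setNames(B, net$species)
}

#' Verify the drift-diffusivity condition for a given weight vector
#'
#' Checks whether the positive weights v admit constants \eqn{c_1 > 0},
#' \eqn{c_2 \ge 0} with
#' \eqn{\langle v, f(x)\rangle \le c_2 - c_1 \langle v, x\rangle} (negative
#' drift at large weighted size) and \eqn{c_3} with
#' \eqn{\sum_k \lambda_k(x) \langle v,\zeta_k\rangle^2 \le c_3 (1 + \langle v, x\rangle)}
#' (linearly bounded diffusivity), extracting the tightest constants:
#' \eqn{c_1 = \min_i -L(v)_i / v_i} (requires the quadratic term to be
#' nonpositive on the orthant), \eqn{c_2 = \langle v, b\rangle}, and
#' \eqn{c_3} coefficientwise from the affine diffusivity. Reactions of order
#' 2 or more with \eqn{\langle v, \zeta_k\rangle \ne 0} make the diffusivity
#' superlinear: \eqn{c_3 = \infty} and the second condition fails. Bounded
#' reactions enter through their supremum only.
#'
#' @param net A [reaction_network()] of mass-action order at most 2 (order-3
#'   reactions make the certificate fail honestly through the quadratic /
#'   diffusivity tests).
#' @param v Positive weight vector.
#' @param pools Optional per-species bounds from [pool_bounds()]
#'   (\code{Inf} = unconfined). Propensities driven by pooled species are
#'   absorbed into the constants, and \eqn{c_1}-decay is only demanded of
#'   the unconfined species (their pooled contribution to
#'   \eqn{\langle v, x\rangle} is bounded and absorbed into \eqn{c_2}).
#' @param audit_n Number of random lattice states for the soundness audit
#'   (0 disables it).
#' @param audit_box Per-coordinate bound of the audit sample.
#' @return A \code{"dd_certificate"}: list with \code{v}, \code{c1},
#'   \code{c2}, \code{c3}, \code{gamma = c2/c1}, \code{zeta_bar},
#'   \code{dd1_verified}, \code{dd2_verified}, and audit counts.
#' @export
verify_dd <- function(net, v, pools = NULL, audit_n = 1000L,
                      audit_box = 1000L) {
  v <- check_weight(net, v)
  d <- n_species(net)
  if (is.null(pools)) pools <- rep(Inf, d)
  pooled <- is.finite(pools)
  Z <- stoichiometry_matrix(net)
  vz <- as.numeric(crossprod(Z, v))
  ord <- reaction_orders(net)
  c2_0 <- 0                 # constant part of the drift envelope
  lin <- numeric(d)         # coefficient of x_i in the drift envelope
  Q <- matrix(0, d, d)      # residual quadratic part (unpooled bimolecular)
  diff_const <- 0
  diff_lin <- numeric(d)
  superlinear <- FALSE
  order3 <- FALSE
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    if (r$kind == "bounded_function") {
      c2_0 <- c2_0 + r$sup_bound * sum(v * pmax(Z[, k], 0))
      diff_const <- diff_const + r$sup_bound * vz[k]^2
      next
    }
    if (abs(vz[k]) < 1e-13 * max(1, max(abs(v)))) next
    if (ord[k] == 0L) {
      c2_0 <- c2_0 + r$rate * vz[k]
      diff_const <- diff_const + r$rate * vz[k]^2
    } else if (ord[k] == 1L) {
      i <- match(names(r$reactants), net$species)
      if (pooled[i]) {
        c2_0 <- c2_0 + r$rate * pools[i] * max(vz[k], 0)
        diff_const <- diff_const + r$rate * pools[i] * vz[k]^2
      } else {
        lin[i] <- lin[i] + r$rate * vz[k]
        diff_lin[i] <- diff_lin[i] + r$rate * vz[k]^2
      }
    } else if (ord[k] == 2L) {
      idx <- match(names(r$reactants), net$species)
      if (length(idx) == 1L) {          # 2 S_a: kappa x(x-1)/2
        a <- idx
        if (pooled[a]) {
          env <- r$rate * pools[a] * max(pools[a] - 1, 0) / 2
          c2_0 <- c2_0 + env * max(vz[k], 0)
          diff_const <- diff_const + env * vz[k]^2
        } else {
          Q[a, a] <- Q[a, a] + r$rate * vz[k] / 2
          lin[a] <- lin[a] - r$rate * vz[k] / 2
          superlinear <- TRUE
        }
      } else {                          # S_a + S_b
        a <- idx[1]; b <- idx[2]
        if (pooled[a] && pooled[b]) {
          env <- r$rate * pools[a] * pools[b]
          c2_0 <- c2_0 + env * max(vz[k], 0)
          diff_const <- diff_const + env * vz[k]^2
        } else if (pooled[a] || pooled[b]) {
          pi_ <- if (pooled[a]) a else b
          fi <- if (pooled[a]) b else a
          lin[fi] <- lin[fi] + r$rate * pools[pi_] * max(vz[k], 0)
          diff_lin[fi] <- diff_lin[fi] + r$rate * pools[pi_] * vz[k]^2
        } else {
          Q[a, b] <- Q[a, b] + r$rate * vz[k] / 2
          Q[b, a] <- Q[b, a] + r$rate * vz[k] / 2
          superlinear <- TRUE
        }
      }
    } else {
      order3 <- TRUE
    }
  }
  tolq <- 1e-9 * max(1, max(abs(Q)))
  quad_ok <- !order3 && (all(Q <= tolq) ||
    (d > 1 && max(eigen((Q + t(Q)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values) <= tolq))
  free <- which(!pooled)
  c1 <- if (length(free)) min(-lin[free] / v[free]) else 1
  dd1 <- isTRUE(quad_ok && c1 > 0 && all(abs(lin[pooled]) == 0))
  c2 <- c2_0 + (if (dd1) c1 else 0) * sum(v[pooled] * pools[pooled])
  c3 <- if (superlinear || order3) Inf else
    max(diff_const, if (any(diff_lin > 0)) max(diff_lin / v) else 0)
  dd2 <- is.finite(c3)
  zeta_bar <- max(abs(vz))

  audit <- list(n = 0L, dd1_violations = 0L, dd2_violations = 0L)
  if (audit_n > 0L && (dd1 || dd2)) {
    caps <- as.integer(floor(pmin(pools, audit_box) + 1e-9))
    states <- vapply(caps, function(b)
      sample.int(b + 1L, audit_n, replace = TRUE) - 1L,
      integer(audit_n))
    states <- matrix(states, audit_n, d)
    vx <- as.numeric(states %*% v)
    is_bounded <- vapply(net$reactions, function(r)
      r$kind == "bounded_function", TRUE)
    sup_k <- vapply(net$reactions, function(r)
      if (r$kind == "bounded_function") r$sup_bound else 0, 0.0)
    # the bounded part of the drift envelope is state independent
    bounded_env <- sum(sup_k[is_bounded] *
                         colSums(pmax(Z[, is_bounded, drop = FALSE], 0) * v))
    bounded_diff <- sum(sup_k[is_bounded] * vz[is_bounded]^2)
    tolr <- 1e-7
    v1 <- 0L; v2 <- 0L
    for (s in seq_len(audit_n)) {
      x <- states[s, ]
      lam <- vapply(seq_along(net$reactions), function(k)
        if (is_bounded[k]) 0 else propensity_one(net, net$reactions[[k]], x), 0.0)
      wdrift <- sum(lam * vz) + bounded_env
      if (dd1 && wdrift > c2 - c1 * vx[s] + tolr * (1 + abs(c2) + c1 * vx[s]))
        v1 <- v1 + 1L
      if (dd2) {
        dval <- sum(lam * vz^2) + bounded_diff
        if (dval > c3 * (1 + vx[s]) * (1 + tolr)) v2 <- v2 + 1L
      }
    }
    audit <- list(n = audit_n, dd1_violations = v1, dd2_violations = v2)
  }

  structure(list(v = v, c1 = c1, c2 = c2, c3 = c3,
                 gamma = if (c1 > 0) c2 / c1 else NA_real_,
                 zeta_bar = zeta_bar,
                 dd1_verified = dd1, dd2_verified = dd2, audit = audit),
            class = "dd_certificate")
}

#' @export
print.dd_certificate <- function(x, ...) {
  cat("Drift-diffusivity certificate\n")
  cat("  v      =", paste(signif(x$v, 6), collapse = ", "), "\n")
  cat(sprintf("  DD1: %s  (c1 = %g, c2 = %g, gamma = c2/c1 = %g)\n",
              if (x$dd1_verified) "verified" else "NOT verified",
              x$c1, x$c2, x$gamma))
  cat(sprintf("  DD2: %s  (c3 = %g, max jump |<v,zeta>| = %g)\n",
              if (x$dd2_verified) "verified" else "NOT verified",
              x$c3, x$zeta_bar))
  if (x$audit$n > 0)
    cat(sprintf("  audit: %d random states, %d / %d violations (DD1 / DD2)\n",
                x$audit$n, x$audit$dd1_violations, x$audit$dd2_violations))
  invisible(x)
}
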