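# Optimal attractive compact sets for first-order moments and recursive
# moment-bound tables.
#
# The attractor search minimizes gamma = c2/c1 over drift certificates: for
# fixed c1 the inner problem (minimize <v, b> over v >= 1 with the drift
# coefficient condition) is a linear program, and the scalar outer search
# over c1 is a log-grid plus golden-section refinement. For unimolecular
# networks the inner LP has the least-element structure solved by
# lp_least_element, making the whole search linear-algebra cheap and linear
# in the number of species.

#' Optimal attractive compact set for the first-order moments
#'
#' Finds weights \eqn{v^* \ge 1} and constants \eqn{c_1^*, c_2^*} minimizing
#' \eqn{\gamma = c_2/c_1} subject to the drift condition, so that
#' \eqn{\{x \ge 0 : \langle v^*, x\rangle \le \gamma^*\}} attracts the
#' first-order moment from every initial condition. Methods:
#' \describe{
#'   \item{unimolecular}{inner problem \eqn{A'v \le -c_1 v} (least-element
#'     structure, scales to hundreds of species);}
#'   \item{conserved}{adds the conservation constraints \eqn{S_b'v = 0}
#'     cancelling the quadratic drift;}
#'   \item{qneg}{instead forces every entry of \eqn{Q(v)} nonpositive
#'     (O(d^2) constraints).}
#' }
#'
#' @param net A [reaction_network()].
#' @param method One of \code{"auto"}, \code{"unimolecular"},
#'   \code{"conserved"}, \code{"qneg"}. \code{"auto"} picks unimolecular for
#'   unimolecular networks, else conserved when the conservation cone is
#'   nonempty, else qneg.
#' @param rel_tol Relative tolerance of the outer scalar search.
#' @param n_grid Size of the log-spaced bracketing grid over \eqn{c_1}.
#' @param x0 Optional initial state; the conserved route uses it to derive
#'   finite conserved-pool bounds (see [pool_bounds()]), whose weighted size
#'   is then part of the attractor constant.
#' @return An object of class \code{"attractor"}: list with \code{v_star},
#'   \code{c1_star}, \code{c2_star}, \code{gamma_star}, \code{method},
#'   \code{set_description} and the outer-search \code{trace}.
#' @export
optimal_attractor <- function(net, method = c("auto", "unimolecular",
                                              "conserved", "qneg"),
                              rel_tol = 1e-6, n_grid = 150L, x0 = NULL) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (net$class_tag == "unimolecular") "unimolecular"
    else if (!is.null(conservation_vector(net))) "conserved"
    else "qneg"
  }
  d <- n_species(net)
  if (method == "unimolecular") {
    af <- unimolecular_affine(net)
    hz <- hurwitz_test(af$A)
    if (!hz) stop("not certifiable: the affine drift matrix is not Hurwitz-stable")
    c1_hi <- -attr(hz, "abscissa")
    inner <- function(c1) {
      res <- lp_least_element(t(af$A) + diag(c1, d), lower = 1)
      if (res$status != "optimal") return(NULL)
      list(v = res$x, obj = sum(af$b * res$x))
    }
  } else {
    co <- drift_coefficients(net)
    Sb <- bimolecular_stoichiometry(net)
    A_eq <- NULL; b_eq <- NULL; extra_ub <- NULL
    if (method == "conserved") {
      if (is.null(conservation_vector(net)))
        stop("the conservation cone is empty; use method = \"qneg\"")
      pools <- if (!is.null(x0)) pool_bounds(net, x0) else rep(Inf, d)
      parts <- conserved_parts(net, pools)
      free <- which(!parts$pooled)
      poolw <- ifelse(parts$pooled, parts$pools, 0)
      if (ncol(Sb)) { A_eq <- t(Sb); b_eq <- rep(0, ncol(Sb)) }
      inner <- function(c1) {
        A_ub <- (parts$LmatF + diag(c1, d))[free, , drop = FALSE]
        res <- lp_dense(parts$env + c1 * poolw,
                        A_ub = if (nrow(A_ub)) A_ub else NULL,
                        b_ub = if (nrow(A_ub)) rep(0, nrow(A_ub)) else NULL,
                        A_eq = A_eq, b_eq = b_eq, lower = 1)
        if (res$status != "optimal") return(NULL)
        list(v = res$x, obj = res$objective)
      }
      c1_seed <- max(-diag(parts$LmatF)[free], 1e-6)
    } else {
      extra_ub <- qneg_rows(co$Qcoef)
      inner <- function(c1) {
        A_ub <- co$Lmat + diag(c1, d)
        b_ub <- rep(0, d)
        if (!is.null(extra_ub)) { A_ub <- rbind(A_ub, extra_ub); b_ub <- c(b_ub, rep(0, nrow(extra_ub))) }
        res <- lp_dense(co$bvec, A_ub = A_ub, b_ub = b_ub,
                        A_eq = A_eq, b_eq = b_eq, lower = 1)
        if (res$status != "optimal") return(NULL)
        list(v = res$x, obj = res$objective)
      }
      c1_seed <- max(-diag(co$Lmat), 1e-6)
    }
    # feasible ceiling on c1: expand then bisect
    c1_hi <- c1_seed
    while (!is.null(inner(c1_hi)) && c1_hi < 1e8) c1_hi <- c1_hi * 2
    lo <- c1_hi / 2
    if (is.null(inner(lo))) {
      while (is.null(inner(lo)) && lo > 1e-12) lo <- lo / 2
      if (lo <= 1e-12)
        stop("not certifiable by method \"", method,
             "\": drift condition infeasible at every decay rate")
    }
    hi <- c1_hi
    for (it in 1:40) {
      mid <- sqrt(lo * hi)
      if (is.null(inner(mid))) hi <- mid else lo <- mid
    }
    c1_hi <- lo
  }

  gamma_of <- function(c1) {
    r <- inner(c1)
    if (is.null(r)) return(list(gamma = Inf))
    c(list(gamma = r$obj / c1, c1 = c1), r)
  }
  grid <- exp(seq(log(c1_hi * 1e-8), log(c1_hi), length.out = n_grid))
  evals <- lapply(grid, gamma_of)
  gvals <- vapply(evals, `[[`, 0.0, "gamma")
  trace <- data.frame(c1 = grid, gamma = gvals)
  best_i <- which.min(gvals)
  best <- evals[[best_i]]
  lo <- grid[max(1L, best_i - 1L)]
  hi <- grid[min(n_grid, best_i + 1L)]
  # golden-section refinement on log c1
  phi <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- gamma_of(exp(x1)); f2 <- gamma_of(exp(x2))
  for (it in 1:120) {
    if (abs(b - a) < rel_tol) break
    if (f1$gamma <= f2$gamma) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- gamma_of(exp(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- gamma_of(exp(x2))
    }
    fb <- if (f1$gamma < f2$gamma) f1 else f2
    if (fb$gamma < best$gamma) best <- fb
    trace <- rbind(trace, data.frame(c1 = fb$c1, gamma = fb$gamma))
  }
  if (!is.finite(best$gamma))
    stop("not certifiable: no feasible decay rate found")
  structure(list(v_star = best$v, c1_star = best$c1, c2_star = best$obj,
                 gamma_star = best$gamma, method = method,
                 set_description = sprintf(
                   "{x >= 0 : <v, x> <= %.8g} with v = (%s)",
                   best$gamma, paste(signif(best$v, 8), collapse = ", ")),
                 trace = trace),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("Attractive compact set for the first-order moments (", x$method,
      " route)\n", sep = "")
  cat("  v*     = (", paste(signif(x$v_star, 8), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  c1* = %.8g, c2* = %.8g, gamma* = c2*/c1* = %.10g\n",
              x$c1_star, x$c2_star, x$gamma_star))
  cat("  set: ", x$set_description, "\n", sep = "")
  invisible(x)
}

#' Uniform and asymptotic moment bounds
#'
#' For a certificate with verified drift and diffusivity conditions and
#' bounded jumps, the n-th moment of the weighted size
#' \eqn{W(t) = \langle v, X(t)\rangle} obeys the comparison recursion
#' \deqn{dm_n/dt \le -n c_1 m_n + K_n (1 + m_{n-1}), \quad
#'       K_n = n c_2 + 2 c_3 \sum_{j=2}^{n} \binom{n}{j} \bar\zeta^{\,j-2},}
#' obtained from Dynkin's formula, a binomial expansion of the jumps, and
#' \eqn{W^a \le 1 + W^{n-1}} for \eqn{a \le n - 1}. The bounds it yields are
#' valid but conservative; the first order is the pure drift bound
#' (asymptotically \eqn{\gamma = c_2/c_1}). Without the diffusivity
#' condition the table stops at order 1.
#'
#' @param cert A \code{"dd_certificate"} from [verify_dd()] with
#'   \code{dd1_verified}.
#' @param n_max Highest moment order.
#' @param x0 Initial state (for the uniform-in-time bounds).
#' @return A \code{"moment_bound_table"}: data.frame with columns
#'   \code{order}, \code{uniform}, \code{asymptotic}, plus the constants as
#'   attributes.
#' @export
moment_bounds <- function(cert, n_max = 3L, x0) {
  if (!inherits(cert, "dd_certificate") || !cert$dd1_verified)
    stop("moment_bounds needs a certificate with a verified drift condition")
  W0 <- sum(cert$v * x0)
  gamma <- cert$gamma
  if (!cert$dd2_verified || !is.finite(cert$c3) || !is.finite(cert$zeta_bar)) {
    n_max <- 1L
    validity <- "drift condition only: table restricted to order 1"
  } else {
    validity <- "drift and diffusivity conditions verified; bounds valid for every order"
  }
  uniform <- asympt <- numeric(n_max)
  uniform[1] <- max(W0, gamma)
  asympt[1] <- gamma
  if (n_max >= 2L) {
    for (n in 2:n_max) {
      Kn <- n * cert$c2 +
        2 * cert$c3 * sum(choose(n, 2:n) * cert$zeta_bar^(0:(n - 2)))
      asympt[n] <- Kn * (1 + asympt[n - 1]) / (n * cert$c1)
      uniform[n] <- max(W0^n, Kn * (1 + uniform[n - 1]) / (n * cert$c1))
    }
  }
  structure(data.frame(order = seq_len(n_max), uniform = uniform,
                       asymptotic = asympt),
            class = c("moment_bound_table", "data.frame"),
            c1 = cert$c1, c2 = cert$c2, c3 = cert$c3,
            zeta_bar = cert$zeta_bar, v = cert$v, W0 = W0,
            validity_condition = validity)
}

#' @export
print.moment_bound_table <- function(x, ...) {
  cat("Moment bounds for <v, X(t)> (conservative comparison recursion)\n")
  print.data.frame(x, row.names = FALSE)
  cat("  ", attr(x, "validity_condition"), "\n", sep = "")
  invisible(x)
}

#' Light-tailedness flags
#'
#' Both the time-marginal laws (uniformly in t) and the stationary law are
#' light-tailed -- tails dominated by an exponential, so the moment
#' generating function and all cumulants exist -- whenever the drift and
#' diffusivity conditions hold with finite constants and bounded jumps.
#' These are the visible hypotheses of the light-tailedness results; the
#' flags are reported under that conservative reading.
#'
#' @param cert A \code{"dd_certificate"}.
#' @return List with \code{uniform_light_tailed},
#'   \code{stationary_light_tailed} and a \code{reason} string.
#' @export
light_tail_flags <- function(cert) {
  ok <- isTRUE(cert$dd1_verified) && isTRUE(cert$dd2_verified) &&
    is.finite(cert$c3) && is.finite(cert$zeta_bar)
  reason <- if (ok) "drift and diffusivity conditions hold with finite constants and bounded jumps"
  else if (!isTRUE(cert$dd1_verified)) "drift condition not verified"
  else "diffusivity condition fails (superlinear diffusivity or unbounded jumps)"
  list(uniform_light_tailed = ok, stationary_light_tailed = ok, reason = reason)
}

# Closed first-moment drift under cumulant neglect: the mass-action
# propensities are evaluated at the real-valued means with their falling
# factorials kept (E[x(x-1)]/2 -> (m^2 - m)/2), which is exactly what
# neglecting the second- and higher-order cumulants does.
closed_drift <- function(net, m) {
  Z <- stoichiometry_matrix(net)
  lam <- vapply(seq_along(net$reactions), function(k) {
    r <- net$reactions[[k]]
    if (r$kind == "bounded_function") {
      env <- as.list(stats::setNames(m, net$species))
      if (!is.null(net$params)) env <- c(env, as.list(net$params))
      if (is.null(r$eval_hint))
        stop("closure audit needs eval_hint for bounded reaction '", r$label, "'")
      max(0, min(eval(parse(text = r$eval_hint), envir = env), r$sup_bound))
    } else {
      p <- r$rate
      if (length(r$reactants)) {
        idx <- match(names(r$reactants), net$species)
        for (q in seq_along(idx)) {
          mult <- r$reactants[[q]]
          p <- p * prod(m[idx[q]] - seq_len(mult) + 1) / factorial(mult)
        }
      }
      p
    }
  }, 0.0)
  as.numeric(Z %*% lam)
}

#' Audit a moment-closure approximation against a certified attractor
#'
#' Integrates the cumulant-neglect closure of the first-moment equations to
#' its equilibrium and checks whether the closed prediction lands inside the
#' certified attractive set \eqn{\{x \ge 0 : \langle v, x\rangle \le \gamma\}}.
#' A closed equilibrium outside the set gives a rigorous lower bound on the
#' closure error, the Euclidean distance from the equilibrium to the set.
#'
#' @param net A [reaction_network()] (mass-action; the classic use is the
#'   dimerization network).
#' @param attractor An \code{"attractor"} from [optimal_attractor()], or a
#'   list with \code{v_star} and \code{gamma_star}.
#' @param x0 Initial means for the integration (defaults to zero).
#' @param t_max Integration horizon before the equilibrium polish.
#' @return A \code{"closure_audit"}: list with \code{closed_equilibrium},
#'   \code{jacobian_stable}, \code{inside_attractor},
#'   \code{error_lower_bound}.
#' @export
closure_audit <- function(net, attractor, x0 = NULL, t_max = 500) {
  d <- n_species(net)
  if (is.null(x0)) x0 <- numeric(d)
  f <- function(t, y, parms) list(closed_drift(net, y))
  # chunked integration with an early divergence bail-out keeps the stiff
  # solver from grinding against a finite-time blow-up
  yT <- as.numeric(x0)
  diverged <- FALSE
  for (chunk in seq_len(20)) {
    utils::capture.output(
      sol <- suppressWarnings(deSolve::ode(y = yT, times = c(0, t_max / 20),
                                           func = f, parms = NULL,
                                           maxsteps = 10000)))
    yT <- sol[nrow(sol), -1]
    if (any(!is.finite(yT)) || max(abs(yT)) > 1e6 ||
        nrow(sol) < 2) { diverged <- TRUE; break }
  }
  if (diverged)
    return(structure(list(closed_equilibrium = NULL, jacobian_stable = NA,
                          inside_attractor = NA,
                          error_lower_bound = NA_real_,
                          status = "closed system unbounded"),
                     class = "closure_audit"))
  # Newton polish of the equilibrium
  m <- as.numeric(yT)
  for (it in 1:50) {
    fm <- closed_drift(net, m)
    if (max(abs(fm)) < 1e-12 * max(1, max(abs(m)))) break
    J <- numeric_jacobian(function(z) closed_drift(net, z), m)
    step <- tryCatch(solve(J, -fm), error = function(e) NULL)
    if (is.null(step)) break
    m <- m + step
  }
  J <- numeric_jacobian(function(z) closed_drift(net, z), m)
  stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
  v <- attractor$v_star
  gam <- attractor$gamma_star
  dist <- dist_to_halfspace_orthant(m, v, gam)
  structure(list(closed_equilibrium = m, jacobian_stable = stable,
                 inside_attractor = dist <= 1e-7 * max(1, gam),
                 error_lower_bound = dist, status = "ok"),
            class = "closure_audit")
}

#' @export
print.closure_audit <- function(x, ...) {
  cat("Moment-closure audit (cumulant neglect)\n")
  if (!is.null(x$status) && x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat("  closed equilibrium: (",
      paste(signif(x$closed_equilibrium, 8), collapse = ", "), ")\n", sep = "")
  cat("  Jacobian stable:   ", x$jacobian_stable, "\n")
  cat("  inside attractor:  ", x$inside_attractor, "\n")
  cat(sprintf("  closure-error lower bound: %.8g\n", x$error_lower_bound))
  invisible(x)
}

numeric_jacobian <- function(f, x, h = 1e-6) {
  d <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), d)
  for (i in seq_len(d)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

# Exact Euclidean distance from a point to {x >= 0 : <v, x> <= gamma} by
# enumerating the active set of zeroed coordinates (exact for modest d).
dist_to_halfspace_orthant <- function(p, v, gamma, tol = 1e-10) {
  d <- length(p)
  if (d > 16) stop("distance computation supports up to 16 species")
  if (all(p >= -tol) && sum(v * p) <= gamma + tol) return(0)
  best <- Inf
  for (s in 0:(2^d - 1)) {
    zero <- which(bitwAnd(s, 2^(seq_len(d) - 1)) > 0)
    free <- setdiff(seq_len(d), zero)
    if (!length(free)) {
      x <- numeric(d)
      if (sum(v * x) <= gamma + tol) best <- min(best, sqrt(sum(p^2)))
      next
    }
    xf <- p[free]
    t <- max(0, (sum(v[free] * xf) - gamma) / sum(v[free]^2))
    xf <- xf - t * v[free]
    if (any(xf < -tol)) next
    x <- numeric(d); x[free] <- pmax(xf, 0)
    if (sum(v * x) <= gamma + 1e-7 * max(1, gamma))
      best <- min(best, sqrt(sum((x - p)^2)))
  }
  best
}
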