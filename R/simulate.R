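# Exact stochastic simulation (Gillespie direct method), ensemble moments,
# ergodic time-averages, and the deterministic reaction-rate equations.
#
# Mass-action networks run in the compiled engine; networks with bounded
# propensities (which need their eval_hint) run in a plain R loop, which is
# adequate for the gene-expression fixtures where those appear.

#' Simulate one trajectory with the stochastic simulation algorithm
#'
#' Exact direct-method sampling of the reaction-network Markov process.
#' Simulation stops at the horizon, when an event-count guard trips, when the
#' total propensity exceeds \code{propensity_cap} (explosion guard), or when
#' every propensity vanishes (absorption).
#'
#' @param net A [reaction_network()]. Bounded reactions need an
#'   \code{eval_hint}.
#' @param x0 Initial state (nonnegative integers).
#' @param t_end Simulation horizon.
#' @param seed Integer seed; the same seed reproduces the trajectory exactly.
#' @param times Optional grid of record times; when \code{NULL} every jump is
#'   recorded (up to \code{max_record}).
#' @param max_events Event-count guard.
#' @param propensity_cap Total-propensity explosion guard.
#' @param burn_in Time before which states are excluded from the running
#'   time-average.
#' @param max_record Cap on stored jump records.
#' @return An \code{"ssa_trajectory"}: list with \code{times},
#'   \code{states} (matrix, species in columns), \code{stopped_reason} in
#'   \code{{"horizon", "explosion_guard", "max_events", "absorbed"}},
#'   \code{t_final}, \code{final_state}, \code{n_events},
#'   \code{time_average} (time-weighted species means after \code{burn_in})
#'   and \code{seed}.
#' @export
ssa <- function(net, x0, t_end, seed = NULL, times = NULL,
                max_events = 1e7, propensity_cap = 1e6, burn_in = 0,
                max_record = 1e6) {
  x0 <- check_state(net, x0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  has_bounded <- any(vapply(net$reactions, function(r)
    r$kind == "bounded_function", TRUE))
  record_events <- is.null(times)
  grid <- if (is.null(times)) numeric() else sort(as.numeric(times))
  if (has_bounded) {
    res <- ssa_r_loop(net, x0, t_end, grid, max_events, propensity_cap,
                      burn_in, record_events, max_record)
  } else {
    res <- .ssa_engine(vapply(net$reactions, `[[`, 0.0, "rate"),
                       reactant_matrix(net), stoichiometry_matrix(net),
                       x0, t_end, max_events, propensity_cap, grid, burn_in,
                       record_events, as.integer(max_record))
  }
  if (record_events) {
    st <- res$event_states
    tt <- res$event_times
  } else {
    st <- res$grid_states
    if (res$grid_filled < length(grid) && res$grid_filled < nrow(st))
      st[(res$grid_filled + 1):nrow(st), ] <- NA_real_
    tt <- grid
  }
  colnames(st) <- net$species
  structure(list(times = tt, states = st,
                 stopped_reason = if (res$stopped == "horizon" && res$t_final >= t_end)
                   "horizon" else res$stopped,
                 t_final = res$t_final,
                 final_state = stats::setNames(res$x_final, net$species),
                 n_events = res$n_events,
                 time_average = stats::setNames(res$time_average, net$species),
                 burn_in = burn_in, seed = seed),
            class = "ssa_trajectory")
}

# plain R direct method for networks with bounded propensities
ssa_r_loop <- function(net, x0, t_end, grid, max_events, propensity_cap,
                       burn_in, record_events, max_record) {
  d <- n_species(net)
  K <- n_reactions(net)
  Z <- stoichiometry_matrix(net)
  R <- reactant_matrix(net)
  rates <- vapply(net$reactions, `[[`, 0.0, "rate")
  is_bounded <- vapply(net$reactions, function(r) r$kind == "bounded_function", TRUE)
  sup <- vapply(net$reactions, `[[`, 0.0, "sup_bound")
  hint_fun <- vector("list", K)
  par_env <- if (is.null(net$params)) list() else as.list(net$params)
  for (k in which(is_bounded)) {
    r <- net$reactions[[k]]
    if (is.null(r$eval_hint))
      stop("bounded reaction '", r$label, "' has no eval_hint; cannot simulate")
    expr <- parse(text = r$eval_hint)
    hint_fun[[k]] <- local({
      e <- expr; s <- sup[k]
      function(env) max(0, min(eval(e, envir = env), s))
    })
  }
  x <- x0
  t <- 0
  nev <- 0
  gi <- 0L
  G <- length(grid)
  grid_states <- matrix(NA_real_, G, d)
  acc <- numeric(d); acc_time <- 0
  ev_t <- if (record_events) 0 else NULL
  ev_x <- if (record_events) list(x) else NULL
  stopped <- "horizon"
  lam <- numeric(K)
  repeat {
    for (k in seq_len(K)) {
      if (is_bounded[k]) {
        env <- c(as.list(stats::setNames(x, net$species)), par_env)
        lam[k] <- hint_fun[[k]](env)
      } else {
        p <- rates[k]
        nz <- which(R[, k] > 0)
        for (i in nz) {
          m <- R[i, k]
          if (x[i] < m) { p <- 0; break }
          p <- p * prod(x[i] - seq_len(m) + 1) / factorial(m)
        }
        lam[k] <- p
      }
    }
    tot <- sum(lam)
    if (tot > propensity_cap) { stopped <- "explosion_guard"; break }
    if (tot <= 0) {
      stopped <- "absorbed"
      if (gi < G) { grid_states[(gi + 1):G, ] <- rep(x, each = G - gi); gi <- G }
      hold <- t_end - max(t, burn_in)
      if (hold > 0) { acc <- acc + x * hold; acc_time <- acc_time + hold }
      t <- t_end
      break
    }
    dt <- stats::rexp(1, tot)
    tcap <- min(t + dt, t_end)
    while (gi < G && grid[gi + 1] <= tcap) {
      gi <- gi + 1L
      grid_states[gi, ] <- x
    }
    lo <- max(t, burn_in); hi <- tcap
    if (hi > lo) { acc <- acc + x * (hi - lo); acc_time <- acc_time + (hi - lo) }
    t <- t + dt
    if (t >= t_end) { t <- t_end; break }
    k <- sample.int(K, 1L, prob = lam)
    x <- x + Z[, k]
    nev <- nev + 1
    if (record_events && length(ev_t) < max_record) {
      ev_t <- c(ev_t, t)
      ev_x[[length(ev_x) + 1L]] <- x
    }
    if (nev >= max_events) { stopped <- "max_events"; break }
  }
  out <- list(t_final = t, x_final = x, n_events = nev, stopped = stopped,
              grid_states = grid_states, grid_filled = gi,
              time_average = if (acc_time > 0) acc / acc_time else rep(NA_real_, d),
              tavg_time = acc_time)
  if (record_events) {
    out$event_times <- ev_t
    out$event_states <- do.call(rbind, ev_x)
  }
  out
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory: ", x$n_events, " events to t = ", signif(x$t_final, 6),
      " (", x$stopped_reason, ")\n", sep = "")
  cat("  final state: (", paste(x$final_state, collapse = ", "), ")\n", sep = "")
  if (!all(is.na(x$time_average)))
    cat("  time-average after burn-in ", x$burn_in, ": (",
        paste(signif(x$time_average, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.ssa_trajectory <- function(x, species = NULL, ...) {
  st <- x$states
  if (!is.null(species)) st <- st[, species, drop = FALSE]
  graphics::matplot(x$times, st, type = "s", lty = 1, xlab = "time",
                    ylab = "copy number", ...)
  graphics::legend("topright", legend = colnames(st), lty = 1,
                   col = seq_len(ncol(st)), bty = "n")
  invisible(x)
}

#' Time-average of a state functional along a trajectory
#'
#' Computes \eqn{\frac{1}{T}\int_0^T f(X(s))\,ds} from a jump-recorded
#' trajectory; by the ergodic theorem this converges, for an ergodic network,
#' to the stationary expectation of f.
#'
#' @param traj An \code{"ssa_trajectory"} recorded at jumps
#'   (\code{times = NULL} in [ssa()]).
#' @param f State functional, default the identity (per-species averages).
#' @return Numeric scalar or vector.
#' @export
time_average <- function(traj, f = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  tt <- c(traj$times, traj$t_final)
  if (traj$t_final <= 0) stop("trajectory has no elapsed time")
  w <- diff(tt)
  vals <- if (is.null(f)) traj$states else
    t(apply(traj$states, 1, f))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  as.numeric(crossprod(vals, w) / sum(w))
}

#' Ensemble moment estimation
#'
#' Runs independent seeded SSA paths and returns unbiased sample moments of
#' every species (and optionally of a weighted size \eqn{\langle v, X\rangle})
#' on a time grid, with standard errors.
#'
#' @inheritParams ssa
#' @param n_paths Number of independent paths (>= 2).
#' @param times Record-time grid.
#' @param n_max Highest raw-moment order.
#' @param v Optional positive weights; adds moments of the weighted size.
#' @param seed Master seed; path i uses a stream derived from (seed, i).
#' @return An \code{"ensemble_moments"} object: \code{times}, \code{mean}
#'   and \code{se} matrices (time x species), \code{moments} (list over
#'   orders of time x species matrices), \code{weighted} (matrix time x
#'   order plus SEs) and the number of explosion-censored paths.
#' @export
ensemble_moments <- function(net, x0, n_paths, times, n_max = 2L, v = NULL,
                             seed = 1L, max_events = 1e7,
                             propensity_cap = 1e6) {
  stopifnot(n_paths >= 2)
  times <- sort(as.numeric(times))
  Tn <- length(times)
  d <- n_species(net)
  sums <- array(0, c(Tn, d, n_max))
  sums2 <- array(0, c(Tn, d, n_max))
  cnt <- matrix(0, Tn, d)
  wsum <- if (!is.null(v)) matrix(0, Tn, n_max)
  wsum2 <- if (!is.null(v)) matrix(0, Tn, n_max)
  wcnt <- if (!is.null(v)) numeric(Tn)
  censored <- 0L
  for (p in seq_len(n_paths)) {
    tr <- ssa(net, x0, t_end = max(times), seed = path_seed(seed, p),
              times = times, max_events = max_events,
              propensity_cap = propensity_cap)
    if (tr$stopped_reason %in% c("explosion_guard", "max_events"))
      censored <- censored + 1L
    st <- tr$states
    ok <- !is.na(st[, 1])
    for (m in seq_len(n_max)) {
      sm <- st^m
      sums[ok, , m] <- sums[ok, , m] + sm[ok, , drop = FALSE]
      sums2[ok, , m] <- sums2[ok, , m] + sm[ok, , drop = FALSE]^2
    }
    cnt[ok, ] <- cnt[ok, ] + 1
    if (!is.null(v)) {
      w <- as.numeric(st %*% v)
      for (m in seq_len(n_max)) {
        wsum[ok, m] <- wsum[ok, m] + w[ok]^m
        wsum2[ok, m] <- wsum2[ok, m] + w[ok]^(2 * m)
      }
      wcnt[ok] <- wcnt[ok] + 1
    }
  }
  moment <- function(S, S2, N) {
    mu <- S / N
    va <- pmax(0, S2 / N - mu^2) * N / pmax(N - 1, 1)
    list(mean = mu, se = sqrt(va / N))
  }
  moments <- lapply(seq_len(n_max), function(m)
    moment(sums[, , m, drop = FALSE][, , 1], sums2[, , m, drop = FALSE][, , 1], cnt))
  weighted <- NULL
  if (!is.null(v)) {
    weighted <- lapply(seq_len(n_max), function(m)
      moment(wsum[, m], wsum2[, m], wcnt))
  }
  structure(list(times = times, n_paths = n_paths,
                 mean = moments[[1]]$mean, se = moments[[1]]$se,
                 moments = moments, weighted = weighted, v = v,
                 censored = censored, species = net$species, seed = seed),
            class = "ensemble_moments")
}

path_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' @export
print.ensemble_moments <- function(x, ...) {
  cat("Ensemble moments over ", x$n_paths, " paths (",
      length(x$times), " time points)", sep = "")
  if (x$censored > 0) cat(" [", x$censored, " paths censored by guards]", sep = "")
  cat("\n  mean at final time: (",
      paste(signif(x$mean[nrow(x$mean), ], 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

det_propensities <- function(net, x) {
  vapply(seq_along(net$reactions), function(k) {
    r <- net$reactions[[k]]
    if (r$kind == "bounded_function") {
      env <- c(as.list(stats::setNames(x, net$species)),
               if (is.null(net$params)) list() else as.list(net$params))
      if (is.null(r$eval_hint))
        stop("bounded reaction '", r$label, "' has no eval_hint")
      max(0, min(eval(parse(text = r$eval_hint), envir = env), r$sup_bound))
    } else {
      p <- r$rate
      if (length(r$reactants)) {
        idx <- match(names(r$reactants), net$species)
        p <- p * prod(x[idx]^r$reactants)
      }
      p
    }
  }, 0.0)
}

det_drift <- function(net, x) {
  as.numeric(stoichiometry_matrix(net) %*% det_propensities(net, x))
}

#' Deterministic reaction-rate equations
#'
#' Integrates \eqn{dx/dt = \sum_k \kappa_k x^{m_k} \zeta_k} with the
#' deterministic monomial convention (\eqn{\kappa x^m}, no falling
#' factorial), which is the standard large-population limit of the jump
#' process.
#'
#' @param net A [reaction_network()].
#' @param x0 Initial concentrations.
#' @param t_end Horizon.
#' @param times Output grid (default 200 points).
#' @return An \code{"rre_trajectory"}: deSolve output matrix with attributes
#'   \code{final}, \code{escape_time} (finite-time blow-up, or NA).
#' @export
rre <- function(net, x0, t_end, times = NULL) {
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  f <- function(t, y, parms) list(det_drift(net, pmax(y, 0)))
  sol <- suppressWarnings(deSolve::ode(y = as.numeric(x0), times = times,
                                       func = f, parms = NULL))
  bad <- !is.finite(rowSums(sol[, -1, drop = FALSE])) |
    apply(abs(sol[, -1, drop = FALSE]), 1, max) > 1e10
  escape <- if (any(bad)) sol[which(bad)[1], 1] else NA_real_
  keep <- if (any(bad)) seq_len(max(1, which(bad)[1] - 1)) else seq_len(nrow(sol))
  out <- sol[keep, , drop = FALSE]
  colnames(out) <- c("time", net$species)
  structure(out, final = out[nrow(out), -1], escape_time = escape,
            class = c("rre_trajectory", class(out)))
}

#' Equilibrium of the reaction-rate equations
#'
#' Newton refinement of an equilibrium from a starting guess, with the
#' Jacobian spectrum for local stability.
#'
#' @param net A [reaction_network()].
#' @param guess Starting point (e.g. the end state of [rre()]).
#' @return List with \code{x}, \code{residual}, \code{jacobian},
#'   \code{eigenvalues} and logical \code{stable}.
#' @export
rre_equilibrium <- function(net, guess) {
  x <- pmax(as.numeric(guess), 0)
  for (it in 1:100) {
    fx <- det_drift(net, x)
    if (max(abs(fx)) < 1e-12 * max(1, max(abs(x)))) break
    J <- numeric_jacobian(function(z) det_drift(net, z), x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    x <- x + step
  }
  J <- numeric_jacobian(function(z) det_drift(net, z), x)
  ev <- eigen(J, only.values = TRUE)$values
  list(x = x, residual = max(abs(det_drift(net, x))), jacobian = J,
       eigenvalues = ev, stable = max(Re(ev)) < 0)
}

#' Roots of the scalar stochastic drift polynomial
#'
#' For a single-species network, returns the sorted real roots of the
#' stochastic drift polynomial (falling-factorial convention) together with
#' the drift sign in each interval. A positive sign beyond the largest root
#' marks the region where trajectories, once there, tend to grow.
#'
#' @param net Single-species mass-action [reaction_network()].
#' @param v Positive scalar weight.
#' @return List with \code{roots} (sorted real roots), \code{coefs}
#'   (ascending), \code{sign_beyond_largest} and \code{signs} (drift sign in
#'   the open intervals between consecutive roots, left to right).
#' @export
drift_roots_1d <- function(net, v = 1) {
  coefs <- scalar_drift_poly(net, v)
  if (length(coefs) < 2) return(list(roots = numeric(), coefs = coefs,
                                     sign_beyond_largest = sign(coefs[1]),
                                     signs = sign(coefs[1])))
  rts <- polyroot(coefs)
  re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
  re <- sort(re)
  evalp <- function(s) sum(coefs * s^(seq_along(coefs) - 1L))
  pts <- if (length(re)) c(re[1] - 1, (re[-1] + re[-length(re)]) / 2,
                           re[length(re)] + 1) else 0
  list(roots = re, coefs = coefs,
       sign_beyond_largest = sign(evalp(max(re, 0) + 1)),
       signs = vapply(pts, function(s) sign(evalp(s)), 0.0))
}

#' Divergence experiments
#'
#' Reproduces the two cautionary phenomena: \code{"well_jumping"} counts how
#' many guarded SSA runs of the bistable autocatalytic network are stopped
#' by the explosion guard before the horizon; \code{"unstable_pair"}
#' measures the growth of the first moments of the network whose rate
#' equations are globally stable while the stochastic moments diverge.
#'
#' @param name \code{"well_jumping"} or \code{"unstable_pair"}.
#' @param params Fixture parameter overrides.
#' @param n_runs Number of SSA runs.
#' @param t_end Horizon (defaults: 100 and 50).
#' @param seed Master seed.
#' @param x0 Initial state (defaults: 5, and c(1, 1)).
#' @param propensity_cap Explosion guard.
#' @return List with \code{n_stopped}, \code{fraction_stopped},
#'   \code{moment_growth_ratio} (total population mean at \code{t_end} over
#'   the mean at \code{t_end/2}, among uncensored runs), the underlying
#'   means and standard errors, and \code{n_complete}.
#' @export
divergence_experiment <- function(name = c("well_jumping", "unstable_pair"),
                                  params = list(), n_runs = 1000L,
                                  t_end = NULL, seed = 1L, x0 = NULL,
                                  propensity_cap = 1e6) {
  name <- match.arg(name)
  if (name == "well_jumping") {
    net <- crn_fixture("well_jumping_22", params)
    if (is.null(t_end)) t_end <- 100
    if (is.null(x0)) x0 <- 5
  } else {
    net <- crn_fixture("unstable_pair_26", params)
    if (is.null(t_end)) t_end <- 50
    if (is.null(x0)) x0 <- c(1, 1)
  }
  half <- numeric(0); full <- numeric(0)
  n_stopped <- 0L
  for (i in seq_len(n_runs)) {
    tr <- ssa(net, x0, t_end, seed = path_seed(seed, i),
              times = c(t_end / 2, t_end), propensity_cap = propensity_cap)
    if (tr$stopped_reason %in% c("explosion_guard", "max_events")) {
      n_stopped <- n_stopped + 1L
    } else {
      half <- c(half, sum(tr$states[1, ]))
      full <- c(full, sum(tr$states[2, ]))
    }
  }
  n_complete <- length(full)
  m_half <- mean(half); m_full <- mean(full)
  se_half <- stats::sd(half) / sqrt(max(n_complete, 1))
  se_full <- stats::sd(full) / sqrt(max(n_complete, 1))
  list(n_stopped = n_stopped, fraction_stopped = n_stopped / n_runs,
       moment_growth_ratio = if (n_complete > 1) m_full / m_half else NA_real_,
       mean_half = m_half, mean_full = m_full,
       se_half = se_half, se_full = se_full, n_complete = n_complete,
       t_end = t_end)
}
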