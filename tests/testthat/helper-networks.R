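# Generators and independent oracles shared across the test files.

# random unimolecular network: conversions, catalytic productions, births,
# deaths; every species gets a degradation so stable instances are common
random_unimolecular <- function(d = 3, extra = 4) {
  sp <- paste0("S", seq_len(d))
  rx <- list()
  for (i in seq_len(d))
    rx[[length(rx) + 1]] <- reaction(paste0("deg", i),
                                     reactants = stats::setNames(1L, sp[i]),
                                     rate = stats::runif(1, 0.5, 2))
  rx[[length(rx) + 1]] <- reaction("birth", products = stats::setNames(1L, sp[1]),
                                   rate = stats::runif(1, 0.5, 5))
  for (e in seq_len(extra)) {
    i <- sample(d, 1); j <- sample(d, 1)
    kind <- sample(c("convert", "catalyze"), 1)
    lab <- paste0("e", e)
    if (kind == "convert" && i != j) {
      rx[[length(rx) + 1]] <- reaction(lab, reactants = stats::setNames(1L, sp[i]),
                                       products = stats::setNames(1L, sp[j]),
                                       rate = stats::runif(1, 0.1, 1))
    } else {
      prod <- stats::setNames(c(1L, 1L), c(sp[i], sp[j]))
      if (i == j) prod <- stats::setNames(2L, sp[i])
      rx[[length(rx) + 1]] <- reaction(lab, reactants = stats::setNames(1L, sp[i]),
                                       products = prod,
                                       rate = stats::runif(1, 0.05, 0.4))
    }
  }
  reaction_network(sp, rx)
}

# random network with orders <= 2 for the decomposition-exactness property
random_order2_network <- function(d = 3, n_rx = 6) {
  sp <- paste0("S", seq_len(d))
  rx <- list()
  for (k in seq_len(n_rx)) {
    ord <- sample(0:2, 1)
    reac <- integer()
    if (ord >= 1) {
      i <- sample(d, 1)
      reac <- stats::setNames(1L, sp[i])
      if (ord == 2) {
        j <- sample(d, 1)
        if (j == i) reac <- stats::setNames(2L, sp[i])
        else reac <- stats::setNames(c(1L, 1L), c(sp[i], sp[j]))
      }
    }
    nprod <- sample(0:2, 1)
    prod <- if (nprod > 0) {
      js <- sample(d, nprod, replace = TRUE)
      tapply(rep(1L, nprod), sp[js], sum)[unique(sp[js])]
    } else integer()
    zeta <- numeric(d); names(zeta) <- sp
    if (length(reac)) zeta[names(reac)] <- zeta[names(reac)] - reac
    if (length(prod)) zeta[names(prod)] <- zeta[names(prod)] + prod
    if (all(zeta == 0)) prod <- c(prod, stats::setNames(1L, sp[sample(d, 1)]))
    rx[[k]] <- reaction(paste0("r", k), reac, prod,
                        rate = stats::runif(1, 0.1, 2))
  }
  reaction_network(sp, rx)
}

sort_side <- function(s) {
  if (length(s) == 0) return(integer())
  s[order(names(s))]
}

# random Metzler matrix, mixed stable / unstable
random_metzler <- function(d) {
  A <- matrix(stats::runif(d * d, 0, 1), d, d)
  diag(A) <- -stats::runif(d, 0.5, d + 1) * sample(c(1, 0.2), d, replace = TRUE)
  A
}

# brute-force LP oracle: minimize c'v over {A_ub v <= b_ub, A_eq v = b_eq,
# v >= lower} by enumerating all basic points (intersections of n active
# constraints drawn from rows of A_ub, A_eq and the bounds)
lp_oracle <- function(cvec, A_ub = NULL, b_ub = NULL, A_eq = NULL,
                      b_eq = NULL, lower = 0, tol = 1e-8) {
  n <- length(cvec)
  lower <- rep_len(lower, n)
  rows <- rbind(if (!is.null(A_ub)) cbind(A_ub, b_ub),
                if (!is.null(A_eq)) cbind(A_eq, b_eq),
                cbind(diag(n), lower))
  m_eq <- if (is.null(A_eq)) 0 else nrow(A_eq)
  m_ub <- if (is.null(A_ub)) 0 else nrow(A_ub)
  eq_rows <- if (m_eq) (m_ub + 1):(m_ub + m_eq) else integer()
  feasible <- function(v) {
    ok <- all(v >= lower - tol)
    if (ok && m_ub) ok <- all(A_ub %*% v <= b_ub + tol)
    if (ok && m_eq) ok <- all(abs(A_eq %*% v - b_eq) <= tol)
    ok
  }
  best <- Inf
  combs <- utils::combn(nrow(rows), n)
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    if (!all(eq_rows %in% sel) && m_eq) next
    M <- rows[sel, seq_len(n), drop = FALSE]
    rhs <- rows[sel, n + 1]
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (feasible(v)) best <- min(best, sum(cvec * v))
  }
  best
}

# exact stationary distribution of a 1-species birth-death chain on 0..N
bd_chain_stationary <- function(birth, death, N) {
  logpi <- numeric(N + 1)
  for (x in 1:N) logpi[x + 1] <- logpi[x] + log(birth(x - 1)) - log(death(x))
  p <- exp(logpi - max(logpi))
  p / sum(p)
}

expect_no_error <- function(expr) expect_error(expr, NA)
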