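# Dense linear programming used by the certificate searches.
#
# The LPs arising here are small (variables = number of species, constraints
# at most quadratic in it), so a textbook two-phase primal simplex with
# Bland's anticycling rule is adequate and keeps the package self-contained.
# The special inner problem of the unimolecular attractor search -- a
# feasibility cone with nonnegative off-diagonal row structure -- is solved
# by a monotone least-element iteration instead, which scales to hundreds of
# species.

#' Solve a small dense linear program
#'
#' Minimizes \code{sum(cvec * v)} subject to \code{A_ub \%*\% v <= b_ub},
#' \code{A_eq \%*\% v == b_eq} and \code{v >= lower}.
#'
#' @param cvec Objective coefficients.
#' @param A_ub,b_ub Inequality constraints (may be NULL).
#' @param A_eq,b_eq Equality constraints (may be NULL).
#' @param lower Componentwise lower bound on the variables (scalar or vector).
#' @param tol Pivoting tolerance.
#' @return List with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x} (the minimizer on success) and \code{objective}.
#' @export
lp_dense <- function(cvec, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                     lower = 0, tol = 1e-9) {
  n <- length(cvec)
  lower <- rep_len(lower, n)
  A <- NULL; b <- NULL; is_eq <- logical()
  if (!is.null(A_ub)) {
    A_ub <- matrix(A_ub, ncol = n)
    A <- rbind(A, A_ub); b <- c(b, b_ub - A_ub %*% lower)
    is_eq <- c(is_eq, rep(FALSE, nrow(A_ub)))
  }
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = n)
    A <- rbind(A, A_eq); b <- c(b, b_eq - A_eq %*% lower)
    is_eq <- c(is_eq, rep(TRUE, nrow(A_eq)))
  }
  if (is.null(A)) {
    # bounds only: minimized at the lower bound for nonnegative costs
    if (any(cvec < 0)) return(list(status = "unbounded", x = NULL, objective = -Inf))
    return(list(status = "optimal", x = lower, objective = sum(cvec * lower)))
  }
  b <- as.numeric(b)
  m <- nrow(A)

  # standard form: slack on every inequality row, then flip rows with b < 0,
  # artificials wherever the slack cannot serve as the initial basis
  n_slack <- sum(!is_eq)
  Tab <- matrix(0, m, n + n_slack)
  Tab[, seq_len(n)] <- A
  slack_col <- integer(m)
  j <- n
  for (i in seq_len(m)) if (!is_eq[i]) {
    j <- j + 1L
    Tab[i, j] <- 1
    slack_col[i] <- j
  }
  flip <- b < 0
  Tab[flip, ] <- -Tab[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  basis <- integer(m)
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (!is_eq[i] && !flip[i]) {
      basis[i] <- slack_col[i]
    } else {
      Tab <- cbind(Tab, 0)
      Tab[i, ncol(Tab)] <- 1
      basis[i] <- ncol(Tab)
      art_cols <- c(art_cols, ncol(Tab))
    }
  }
  ntot <- ncol(Tab)

  run_simplex <- function(Tab, b, basis, cost, allowed, tol) {
    m <- nrow(Tab)
    repeat {
      # reduced costs via the basis rows (Tab kept in canonical form)
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(Tab, cb))
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tab = Tab, b = b, basis = basis,
                                      status = "optimal"))
      enter <- min(enter)             # Bland
      col <- Tab[, enter]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, b = b, basis = basis,
                                    status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      leave <- cand[which.min(basis[cand])]   # Bland on the leaving index
      piv <- Tab[leave, enter]
      Tab[leave, ] <- Tab[leave, ] / piv
      b[leave] <- b[leave] / piv
      for (i in seq_len(m)) if (i != leave && abs(Tab[i, enter]) > 0) {
        f <- Tab[i, enter]
        Tab[i, ] <- Tab[i, ] - f * Tab[leave, ]
        b[i] <- b[i] - f * b[leave]
      }
      b[abs(b) < 1e-13] <- 0
      basis[leave] <- enter
    }
  }

  # canonicalize the initial tableau (basis columns are already unit vectors)
  if (length(art_cols)) {
    cost1 <- c(rep(0, ntot)); cost1[art_cols] <- 1
    res1 <- run_simplex(Tab, b, basis, cost1, rep(TRUE, ntot), tol)
    val1 <- sum(res1$b[res1$basis %in% art_cols])
    if (res1$status != "optimal" || val1 > 1e-7)
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    # drive any residual artificial out of the basis where possible
    Tab <- res1$Tab; b <- res1$b; basis <- res1$basis
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        piv_cols <- setdiff(which(abs(Tab[i, seq_len(n + n_slack)]) > tol),
                            basis)
        if (length(piv_cols)) {
          enter <- piv_cols[1]
          piv <- Tab[i, enter]
          Tab[i, ] <- Tab[i, ] / piv; b[i] <- b[i] / piv
          for (r in seq_len(m)) if (r != i && abs(Tab[r, enter]) > 0) {
            f <- Tab[r, enter]
            Tab[r, ] <- Tab[r, ] - f * Tab[i, ]
            b[r] <- b[r] - f * b[i]
          }
          basis[i] <- enter
        }
      }
    }
  }
  allowed <- rep(TRUE, ntot)
  allowed[art_cols] <- FALSE
  cost2 <- c(cvec, rep(0, ntot - n))
  res2 <- run_simplex(Tab, b, basis, cost2, allowed, tol)
  if (res2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = -Inf))
  x <- numeric(ntot)
  x[res2$basis] <- res2$b
  v <- x[seq_len(n)] + lower
  list(status = "optimal", x = v, objective = sum(cvec * v))
}

# Least element of {v >= lower : M v <= 0} for a matrix with nonnegative
# off-diagonal entries, by monotone fixed-point iteration
#   v_i <- max(lower_i, sum_{j != i} M_ij v_j / (-M_ii)).
# The feasible set is a lattice (closed under componentwise min), so its
# least element exists whenever the set is nonempty and minimizes every
# objective with nonnegative weights simultaneously.
lp_least_element <- function(M, lower = 1, max_iter = 100000L, big = 1e12,
                             tol = 1e-12) {
  d <- nrow(M)
  lower <- rep_len(lower, d)
  diag_M <- diag(M)
  zero_rows <- apply(abs(M), 1, max) == 0
  if (any(diag_M >= 0 & !zero_rows))
    return(list(status = "infeasible", x = NULL))
  N <- M; diag(N) <- 0
  denom <- ifelse(zero_rows, 1, -diag_M)
  v <- lower
  for (it in seq_len(max_iter)) {
    vn <- pmax(lower, as.numeric(N %*% v) / denom)
    vn[zero_rows] <- lower[zero_rows]
    if (max(vn) > big) return(list(status = "infeasible", x = NULL))
    if (max(abs(vn - v)) <= tol * max(1, max(abs(v)))) {
      v <- vn
      break
    }
    v <- vn
  }
  # polish: solve the tight rows exactly given the at-bound components
  for (pass in 1:3) {
    tight <- which(v > lower + 1e-8 & !zero_rows)
    if (length(tight)) {
      free <- setdiff(seq_len(d), tight)
      Mtt <- M[tight, tight, drop = FALSE]
      rhs <- if (length(free)) -M[tight, free, drop = FALSE] %*% v[free]
             else rep(0, length(tight))
      sol <- tryCatch(solve(Mtt, rhs), error = function(e) NULL)
      if (!is.null(sol) && all(sol >= lower[tight] - 1e-9)) {
        v[tight] <- pmax(sol, lower[tight])
      }
    }
    resid <- as.numeric(M %*% v)
    resid[zero_rows] <- 0
    if (max(resid) <= 1e-9 * max(1, max(abs(v)))) break
    v <- pmax(lower, as.numeric(N %*% v) / denom)
  }
  resid <- as.numeric(M %*% v)
  resid[zero_rows] <- 0
  if (max(resid) > 1e-7 * max(1, max(abs(v))))
    return(list(status = "infeasible", x = NULL))
  list(status = "optimal", x = v)
}
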