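# Heuristic irreducibility verification on a finite truncation of the state
# space. Ergodicity conclusions require an irreducible state space; deciding
# that in general is a separate problem, so the package verifies the property
# on a finite box (conservation-aware) and otherwise leaves it to an explicit
# user assertion.

#' Irreducibility check on a truncated state space
#'
#' Builds the directed transition graph on the box \eqn{\{0..box_1\} \times
#' \ldots \times \{0..box_d\}} (edges where a propensity is positive, target
#' inside the box), restricted to the conservation slice through \code{x0}
#' when a positive vector annihilates every stoichiometric vector. The
#' states reachable from \code{x0} must form a single strongly connected
#' component; a reachable terminal component that is closed under all
#' reactions in the full lattice (not merely cut off by the box faces) is a
#' genuine trap and is returned as a counterexample witness. Reachable sets
#' that leak through the box faces without being mutually reachable are
#' inconclusive.
#'
#' @param net A [reaction_network()]. Bounded reactions are treated as
#'   having positive propensity everywhere (their supremum is positive).
#' @param box Per-species upper bounds (scalar recycled; default 30).
#' @param x0 Starting state, inside the box.
#' @return A \code{"truncation_check"}: list with \code{status} in
#'   \code{{"verified_on_truncation", "counterexample", "inconclusive"}},
#'   \code{witness} (closed trapping set, as a matrix of states, when status
#'   is counterexample), and \code{n_states_explored}.
#' @export
truncated_irreducibility_check <- function(net, box = 30L, x0) {
  d <- n_species(net)
  x0 <- check_state(net, x0)
  box <- rep_len(as.integer(box), d)
  if (any(x0 > box)) stop("x0 must lie inside the box")
  if (prod(box + 1) > 1e7)
    stop("box volume exceeds 10^7 states; shrink the truncation")
  Z <- stoichiometry_matrix(net)
  # conservation slice: restrict to <w, x> = <w, x0> when w > 0 kills all zeta
  w <- tryCatch(conservation_all(net), error = function(e) NULL)
  grid <- as.matrix(expand.grid(lapply(box, function(b) 0:b)))
  colnames(grid) <- net$species
  if (!is.null(w)) {
    keep <- abs(grid %*% w - sum(w * x0)) < 1e-9
    grid <- grid[keep, , drop = FALSE]
  }
  n <- nrow(grid)
  key <- function(states) apply(states, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(n), key(grid))
  x0i <- idx[[paste(x0, collapse = ",")]]
  edges <- NULL
  exits_box <- logical(n)   # state has a firing reaction leaving the box
  for (k in seq_len(ncol(Z))) {
    lam_pos <- propensity_positive(net, grid, k)
    tgt <- sweep(grid[lam_pos, , drop = FALSE], 2, Z[, k], `+`)
    inside <- apply(tgt >= 0, 1, all) & apply(sweep(tgt, 2, box, `<=`), 1, all)
    from <- which(lam_pos)
    toi <- rep(NA_integer_, length(from))
    if (any(inside)) toi[inside] <- idx[key(tgt[inside, , drop = FALSE])]
    ok <- !is.na(toi)
    if (any(ok)) edges <- rbind(edges, cbind(from[ok], toi[ok]))
    exits_box[from[!ok | !inside]] <- TRUE
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), 0, 2) else edges, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  reach <- sort(as.integer(igraph::subcomponent(g, x0i, mode = "out")))
  comp <- igraph::components(igraph::induced_subgraph(g, reach), mode = "strong")
  if (comp$no == 1L) {
    status <- "verified_on_truncation"
    witness <- NULL
  } else {
    # terminal components of the reachable set: no edge out, closed in the
    # full lattice only if none of their states can fire out of the box
    sub <- igraph::induced_subgraph(g, reach)
    memb <- comp$membership
    status <- "inconclusive"; witness <- NULL
    for (cc in seq_len(comp$no)) {
      vs <- which(memb == cc)
      orig <- reach[vs]
      out_edges <- igraph::adjacent_vertices(sub, vs, mode = "out")
      leaves <- any(vapply(seq_along(vs), function(q)
        any(!(as.integer(out_edges[[q]]) %in% vs)), TRUE))
      if (!leaves && !any(exits_box[orig]) && !(x0i %in% orig)) {
        status <- "counterexample"
        witness <- grid[orig, , drop = FALSE]
        break
      }
    }
    if (status == "inconclusive" && !any(exits_box[reach])) {
      # everything is inside the box yet not mutually reachable
      status <- "counterexample"
      term <- which(vapply(seq_len(comp$no), function(cc) {
        vs <- which(memb == cc)
        oe <- igraph::adjacent_vertices(sub, vs, mode = "out")
        !any(vapply(seq_along(vs), function(q)
          any(!(as.integer(oe[[q]]) %in% vs)), TRUE))
      }, TRUE))[1]
      witness <- grid[reach[comp$membership == term], , drop = FALSE]
    }
  }
  structure(list(status = status, witness = witness,
                 n_states_explored = n, box = box),
            class = "truncation_check")
}

# positive conservation vector for the whole network (all reactions), or NULL
conservation_all <- function(net) {
  Z <- stoichiometry_matrix(net)
  res <- lp_dense(rep(1, nrow(Z)), A_eq = t(Z), b_eq = rep(0, ncol(Z)), lower = 1)
  if (res$status != "optimal") return(NULL)
  res$x
}

# logical vector over grid rows: propensity of reaction k positive there
propensity_positive <- function(net, grid, k) {
  r <- net$reactions[[k]]
  if (r$kind == "bounded_function") return(rep(TRUE, nrow(grid)))
  ok <- rep(TRUE, nrow(grid))
  if (length(r$reactants)) {
    idx <- match(names(r$reactants), net$species)
    for (q in seq_along(idx))
      ok <- ok & grid[, idx[q]] >= r$reactants[[q]]
  }
  ok & r$rate > 0
}

#' @export
print.truncation_check <- function(x, ...) {
  cat("Irreducibility check on box [0, ",
      paste(x$box, collapse = "] x [0, "), "]\n", sep = "")
  cat("  status:", x$status, " (", x$n_states_explored, "states explored )\n")
  if (!is.null(x$witness))
    cat("  trapping set of", nrow(x$witness), "state(s), first:",
        paste(x$witness[1, ], collapse = ","), "\n")
  invisible(x)
}
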