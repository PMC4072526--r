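#' Define a reaction channel
#'
#' A reaction channel is a net stoichiometric change together with a
#' propensity specification: either stochastic mass-action kinetics with a
#' rate constant, or an arbitrary bounded nonnegative propensity declared
#' through a finite supremum (and, optionally, a concrete functional form
#' used only for simulation).
#'
#' @param label Reaction identifier, unique within a network.
#' @param reactants Named integer vector of reactant multiplicities
#'   (e.g. \code{c(X = 2)} for a homodimerization). May be empty for a
#'   zero-order (birth) reaction.
#' @param products Named integer vector of product multiplicities. May be
#'   empty for pure consumption.
#' @param rate Nonnegative mass-action rate constant (per time unit).
#'   Exactly one of \code{rate} and \code{sup_bound} must be given.
#' @param sup_bound Finite supremum of a bounded propensity function.
#' @param eval_hint For bounded propensities only: a character string with an
#'   R expression in the species names (e.g. \code{"10/(1 + P^2)"}) used by
#'   the simulation layer. Certificate computations never read it.
#' @return An object of class \code{"crn_reaction"}.
#' @export
reaction <- function(label, reactants = integer(), products = integer(),
                     rate = NULL, sup_bound = NULL, eval_hint = NULL) {
  reactants <- validate_side(reactants, label, "reactants")
  products <- validate_side(products, label, "products")
  if (is.null(rate) == is.null(sup_bound))
    stop("reaction '", label,
         "': give exactly one of `rate` (mass action) or `sup_bound` (bounded)")
  if (!is.null(rate)) {
    if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
      stop("reaction '", label, "': negative or invalid rate constant")
    kind <- "mass_action"
    if (sum(reactants) > 3L)
      stop("reaction '", label, "': mass-action order ", sum(reactants),
           " exceeds the supported maximum of 3")
  } else {
    if (!is.numeric(sup_bound) || length(sup_bound) != 1L ||
        !is.finite(sup_bound) || sup_bound < 0)
      stop("reaction '", label, "': bounded propensity needs a finite sup_bound")
    kind <- "bounded_function"
  }
  structure(list(label = as.character(label), reactants = reactants,
                 products = products, kind = kind,
                 rate = if (is.null(rate)) NA_real_ else as.numeric(rate),
                 sup_bound = if (is.null(sup_bound)) NA_real_ else as.numeric(sup_bound),
                 eval_hint = eval_hint),
            class = "crn_reaction")
}

validate_side <- function(side, label, what) {
  if (length(side) == 0L) return(integer())
  if (is.null(names(side)) || any(names(side) == ""))
    stop("reaction '", label, "': ", what, " must be a named vector")
  if (any(side != round(side)) || any(side < 1))
    stop("reaction '", label, "': ", what, " multiplicities must be positive integers")
  s <- as.integer(side)
  names(s) <- names(side)
  tapply(s, names(s), sum)[unique(names(s))]
}

#' Assemble a reaction network
#'
#' Species order and reaction order are declaration order; all matrices
#' produced from the network follow it.
#'
#' @param species Character vector of unique species names.
#' @param reactions List of [reaction()] objects.
#' @param rate_intervals Optional named list mapping reaction labels to
#'   \code{c(lo, hi)} rate intervals for robust analysis.
#' @param params Optional named numeric vector of the symbolic rate values
#'   used to build the network (kept for reporting only).
#' @return An object of class \code{"reaction_network"} with fields
#'   \code{species}, \code{reactions}, \code{rate_intervals}, \code{params}
#'   and a computed \code{class_tag} in \code{{"unimolecular", "bimolecular",
#'   "general_mass_action"}} (highest mass-action order 0/1, exactly 2, or 3).
#' @export
reaction_network <- function(species, reactions, rate_intervals = NULL,
                             params = NULL) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  if (length(species) == 0L) stop("a network needs at least one species")
  if (!all(vapply(reactions, inherits, TRUE, "crn_reaction")))
    stop("`reactions` must be a list of reaction() objects")
  labels <- vapply(reactions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("reaction labels must be unique")
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(unknown))
      stop("reaction '", r$label, "' uses undeclared species: ",
           paste(unknown, collapse = ", "))
    z <- reaction_zeta(r, species)
    if (all(z == 0))
      stop("reaction '", r$label, "' has zero net stoichiometry")
  }
  if (!is.null(rate_intervals)) {
    bad <- setdiff(names(rate_intervals), labels)
    if (length(bad)) stop("rate_intervals for unknown reactions: ",
                          paste(bad, collapse = ", "))
    for (nm in names(rate_intervals)) {
      iv <- rate_intervals[[nm]]
      if (length(iv) != 2L || any(iv < 0) || iv[1] > iv[2])
        stop("invalid rate interval for reaction '", nm, "'")
    }
  }
  net <- structure(list(species = species, reactions = reactions,
                        rate_intervals = rate_intervals, params = params),
                   class = "reaction_network")
  net$class_tag <- classify_network(net)
  net
}

reaction_zeta <- function(r, species) {
  z <- integer(length(species))
  names(z) <- species
  if (length(r$reactants)) z[names(r$reactants)] <- z[names(r$reactants)] - r$reactants
  if (length(r$products)) z[names(r$products)] <- z[names(r$products)] + r$products
  unname(z)
}

classify_network <- function(net) {
  ord <- vapply(net$reactions, function(r)
    if (r$kind == "mass_action") sum(r$reactants) else 0L, 0L)
  if (any(ord >= 3L)) "general_mass_action"
  else if (any(ord == 2L)) "bimolecular"
  else "unimolecular"
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network: ", length(x$species), " species, ",
      length(x$reactions), " reactions (", x$class_tag, ")\n", sep = "")
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) {
    lhs <- side_string(r$reactants)
    rhs <- side_string(r$products)
    prop <- if (r$kind == "mass_action") sprintf("ma(%g)", r$rate)
            else sprintf("bounded(sup=%g)", r$sup_bound)
    cat(sprintf("  %s: %s -> %s @ %s\n", r$label, lhs, rhs, prop))
  }
  if (!is.null(x$rate_intervals))
    cat("Rate intervals on:", paste(names(x$rate_intervals), collapse = ", "), "\n")
  invisible(x)
}

side_string <- function(side) {
  if (length(side) == 0L) return("0")
  paste(ifelse(side > 1L, paste(side, names(side)), names(side)), collapse = " + ")
}

#' Number of species / reactions
#' @param net A [reaction_network()].
#' @return Integer count.
#' @export
n_species <- function(net) length(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) length(net$reactions)

#' Stoichiometry matrix
#'
#' Returns the d x K integer matrix whose k-th column is the net
#' stoichiometric change of reaction k, in declaration order.
#'
#' @param net A [reaction_network()].
#' @return Integer matrix with species as rows, reactions as columns.
#' @export
stoichiometry_matrix <- function(net) {
  Z <- vapply(net$reactions, reaction_zeta, integer(n_species(net)),
              species = net$species)
  Z <- matrix(Z, nrow = n_species(net),
              dimnames = list(net$species,
                              vapply(net$reactions, `[[`, "", "label")))
  Z
}

#' Reactant multiplicity matrix (d x K), used for propensity evaluation.
#' @inheritParams stoichiometry_matrix
#' @return Integer matrix of reactant multiplicities.
#' @export
reactant_matrix <- function(net) {
  d <- n_species(net)
  R <- matrix(0L, d, length(net$reactions),
              dimnames = list(net$species,
                              vapply(net$reactions, `[[`, "", "label")))
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    if (length(r$reactants)) R[names(r$reactants), k] <- r$reactants
  }
  R
}

reaction_orders <- function(net) {
  vapply(net$reactions, function(r)
    if (r$kind == "mass_action") sum(r$reactants) else NA_integer_, 0L)
}

#' Stoichiometry restricted to bimolecular reactions
#'
#' Columns are the stoichiometric vectors of the order-2 mass-action
#' reactions only, in reaction order. Unimolecular networks yield a
#' zero-column matrix.
#'
#' @inheritParams stoichiometry_matrix
#' @return Integer matrix with d rows.
#' @export
bimolecular_stoichiometry <- function(net) {
  ord <- reaction_orders(net)
  keep <- which(!is.na(ord) & ord == 2L)
  stoichiometry_matrix(net)[, keep, drop = FALSE]
}

is_valid_state <- function(net, x) {
  is.numeric(x) && length(x) == n_species(net) && all(is.finite(x)) &&
    all(x >= 0) && all(x == round(x))
}

check_state <- function(net, x) {
  if (!is_valid_state(net, x))
    stop("state must be a nonnegative integer vector of length ", n_species(net))
  as.numeric(x)
}

check_weight <- function(net, v) {
  if (!is.numeric(v) || length(v) != n_species(net) || any(!is.finite(v)) ||
      any(v <= 0))
    stop("weight vector v must be positive with one entry per species")
  as.numeric(v)
}
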