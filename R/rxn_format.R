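# Plain-text reaction format (.rxn)
#
#   # comment
#   species: A, B, C
#   param k1 = 10.0
#   reaction R1: 2 A + B -> C @ ma(k1)
#   reaction R2: -> M @ bounded(sup=5.0, hint="k0/(1+D^2)")
#   interval k1 = [0.5, 2.0]
#
# Empty reactant side = birth; empty product side = pure consumption.
# Rates may be numeric literals or declared param symbols; `interval`
# annotates a param with a range, attached to every reaction using it.

#' Parse the plain-text reaction format
#'
#' @param text Either a single string (possibly with newlines), a character
#'   vector of lines, or the path of a file when \code{file = TRUE}.
#' @param file Read \code{text} as a file path.
#' @return A [reaction_network()]. Species and reactions keep declaration
#'   order; the result round-trips through [write_rxn()].
#' @export
parse_rxn <- function(text, file = FALSE) {
  lines <- if (file) readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- character()
  params <- numeric()
  intervals <- list()
  rx <- list()
  rx_param <- character()   # param symbol used for each reaction's rate ("" if literal)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "") next
    perr <- function(msg) stop("parse error at line ", ln, ": ", msg,
                               "\n  ", lines[[ln]], call. = FALSE)
    if (grepl("^species\\s*:", line)) {
      sp <- trimws(strsplit(sub("^species\\s*:", "", line), ",")[[1]])
      sp <- sp[sp != ""]
      if (!all(grepl("^[A-Za-z][A-Za-z0-9_.]*$", sp))) perr("bad species name")
      species <- c(species, sp)
    } else if (grepl("^param\\s+", line)) {
      m <- regmatches(line, regexec(
        "^param\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*([-0-9.eE+]+)\\s*$", line))[[1]]
      if (length(m) != 3L) perr("expected `param name = value`")
      val <- suppressWarnings(as.numeric(m[3]))
      if (is.na(val)) perr("bad numeric value")
      params[m[2]] <- val
    } else if (grepl("^interval\\s+", line)) {
      m <- regmatches(line, regexec(
        "^interval\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*\\[\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*\\]\\s*$",
        line))[[1]]
      if (length(m) != 4L) perr("expected `interval name = [lo, hi]`")
      lo <- as.numeric(m[3]); hi <- as.numeric(m[4])
      if (is.na(lo) || is.na(hi) || lo < 0 || lo > hi) perr("bad interval")
      intervals[[m[2]]] <- c(lo, hi)
    } else if (grepl("^reaction\\s+", line)) {
      m <- regmatches(line, regexec(
        "^reaction\\s+([A-Za-z0-9_.]+)\\s*:\\s*(.*?)->(.*?)@\\s*(.*)$", line))[[1]]
      if (length(m) != 5L) perr("expected `reaction label: lhs -> rhs @ propensity`")
      label <- m[2]
      lhs <- parse_side(m[3], perr)
      rhs <- parse_side(m[4], perr)
      prop <- trimws(m[5])
      if (grepl("^ma\\s*\\(", prop)) {
        arg <- trimws(sub("^ma\\s*\\((.*)\\)\\s*$", "\\1", prop))
        if (grepl("^[A-Za-z]", arg)) {
          if (!arg %in% names(params)) perr(paste0("undeclared param '", arg, "'"))
          rate <- params[[arg]]
          psym <- arg
        } else {
          rate <- suppressWarnings(as.numeric(arg))
          if (is.na(rate)) perr("bad rate")
          psym <- ""
        }
        if (rate < 0) perr("negative rate")
        rx[[length(rx) + 1L]] <- reaction(label, lhs, rhs, rate = rate)
      } else if (grepl("^bounded\\s*\\(", prop)) {
        body <- sub("^bounded\\s*\\((.*)\\)\\s*$", "\\1", prop)
        msup <- regmatches(body, regexec("sup\\s*=\\s*([-0-9.eE+]+)", body))[[1]]
        if (length(msup) != 2L) perr("bounded propensity needs sup=<value>")
        sup <- as.numeric(msup[2])
        mh <- regmatches(body, regexec("hint\\s*=\\s*\"([^\"]*)\"", body))[[1]]
        hint <- if (length(mh) == 2L) mh[2] else NULL
        psym <- ""
        rx[[length(rx) + 1L]] <- reaction(label, lhs, rhs, sup_bound = sup,
                                          eval_hint = hint)
      } else perr("propensity must be ma(...) or bounded(...)")
      rx_param[length(rx)] <- psym
    } else perr("unrecognized directive")
  }
  if (length(species) == 0L) stop("no `species:` declaration found")
  for (k in seq_along(rx)) {
    unknown <- setdiff(c(names(rx[[k]]$reactants), names(rx[[k]]$products)), species)
    if (length(unknown))
      stop("parse error: reaction '", rx[[k]]$label,
           "' uses undeclared species: ", paste(unknown, collapse = ", "))
  }
  ri <- NULL
  if (length(intervals)) {
    ri <- list()
    for (k in seq_along(rx)) {
      ps <- rx_param[k]
      if (nzchar(ps) && ps %in% names(intervals))
        ri[[rx[[k]]$label]] <- intervals[[ps]]
    }
    if (length(ri) == 0L) ri <- NULL
  }
  reaction_network(species, rx, rate_intervals = ri,
                   params = if (length(params)) params else NULL)
}

parse_side <- function(s, perr) {
  s <- trimws(s)
  if (s == "" || s == "0") return(integer())
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- integer()
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_.]*)$", tm))[[1]]
    if (length(m) != 3L) perr(paste0("bad species term '", tm, "'"))
    mult <- if (m[2] == "") 1L else as.integer(m[2])
    out[m[3]] <- (if (m[3] %in% names(out)) out[[m[3]]] else 0L) + mult
  }
  out
}

#' Serialize a network to the plain-text reaction format
#'
#' @param net A [reaction_network()].
#' @param path Optional file path; when given the document is written there.
#' @return The document as a character scalar (invisibly when writing a file).
#' @export
write_rxn <- function(net, path = NULL) {
  out <- c(paste0("species: ", paste(net$species, collapse = ", ")))
  labels <- vapply(net$reactions, `[[`, "", "label")
  for (r in net$reactions) {
    prop <- if (r$kind == "mass_action") {
      sprintf("ma(%s)", format(r$rate, digits = 17))
    } else if (!is.null(r$eval_hint)) {
      sprintf("bounded(sup=%s, hint=\"%s\")", format(r$sup_bound, digits = 17),
              r$eval_hint)
    } else sprintf("bounded(sup=%s)", format(r$sup_bound, digits = 17))
    out <- c(out, sprintf("reaction %s: %s -> %s @ %s", r$label,
                          rxn_side(r$reactants), rxn_side(r$products), prop))
  }
  if (!is.null(net$rate_intervals)) {
    # round-trip via one synthetic param per annotated reaction
    pre <- character(); post <- character()
    for (nm in names(net$rate_intervals)) {
      r <- net$reactions[[match(nm, labels)]]
      psym <- paste0("k_", nm)
      pre <- c(pre, sprintf("param %s = %s", psym, format(r$rate, digits = 17)))
      post <- c(post, sprintf("interval %s = [%s, %s]", psym,
                              format(net$rate_intervals[[nm]][1], digits = 17),
                              format(net$rate_intervals[[nm]][2], digits = 17)))
      out[1 + match(nm, labels)] <- sprintf(
        "reaction %s: %s -> %s @ ma(%s)", r$label,
        rxn_side(r$reactants), rxn_side(r$products), psym)
    }
    out <- c(out[1], pre, out[-1], post)
  }
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

rxn_side <- function(side) {
  if (length(side) == 0L) return("")
  paste(ifelse(side > 1L, paste(side, names(side)), names(side)), collapse = " + ")
}
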