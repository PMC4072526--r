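Package: ergokit
Title: Ergodicity Certificates and Moment Bounds for Stochastic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Foster-Lyapunov certification of long-term behavior for stochastic
    chemical reaction networks modeled as continuous-time Markov chains.
    Provides a plain-text reaction format and a registry of classic example
    networks; exact decomposition of the weighted drift and diffusivity;
    linear-programming searches for drift certificates of exponential
    ergodicity (unimolecular, conservation-weighted bimolecular, componentwise
    and negative-definite quadratic routes, copositivity for Lotka-Volterra
    competition, and a scalar polynomial route for higher-order kinetics such
    as the Schlogl model); robust certificates over interval-valued rates;
    optimal attractive compact sets for first-order moments via bisection over
    linear programs; recursive uniform and asymptotic moment bounds with
    light-tailedness flags; a moment-closure audit against certified
    attractors; an exact Gillespie simulator with explosion guards, ensemble
    moments, and ergodic time-averages; deterministic reaction-rate equations;
    and a truncated-reachability irreducibility check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    quadprog,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
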