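---
title: "Certifying long-term behavior of stochastic reaction networks"
author: "ergokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certifying long-term behavior of stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergokit)
```

## The model and the questions

A reaction network with $d$ species and $K$ reaction channels, modeled
stochastically, is a continuous-time Markov chain $X(t)$ on the nonnegative
integer lattice: channel $k$ fires at the state-dependent rate
$\lambda_k(x)$ (its *propensity*) and displaces the state by its
stoichiometric vector $\zeta_k$. The probability law of $X(t)$ solves the
chemical master equation, which is rarely tractable, so the questions this
package answers are asked — and answered — without solving it:

* **Ergodicity.** Is there a unique stationary distribution that attracts
  every initial condition? This is the stochastic counterpart of a globally
  attracting fixed point, and it licenses the ergodic theorem: time averages
  along one trajectory converge to ensemble averages, so a single cell
  observed for a long time carries the same information as a population
  snapshot.
* **Moment boundedness and convergence.** Do $E[X(t)^n]$ stay bounded
  uniformly in time, and converge to stationary values?
* **Light tails.** Are the laws dominated by an exponential tail, so that
  the moment generating function and all cumulants exist? This is the
  soundness condition implicitly assumed by cumulant-based moment-closure
  schemes.

All certificates rest on one inequality pair for a weighted population size
$W(x) = \langle v, x\rangle$ with positive weights $v$, the
**drift–diffusivity condition**:

$$\textstyle\sum_k \lambda_k(x)\,\langle v,\zeta_k\rangle \;\le\; c_2 - c_1
\langle v, x\rangle \qquad\text{(DD1, negative drift at large size)}$$

$$\textstyle\sum_k \lambda_k(x)\,\langle v,\zeta_k\rangle^2 \;\le\; c_3\,(1
+ \langle v, x\rangle) \qquad\text{(DD2, linearly bounded diffusivity)}$$

for all states $x$, with $c_1 > 0$, $c_2 \ge 0$, $c_3 \ge 0$. Given an
irreducible state space, DD1 yields exponential ergodicity and an
attractive set for the first moment; DD1 + DD2 with bounded jumps
yields bounds on all moments and uniform light-tailedness. The package's
job is to *find* $v$ — by linear programming — and to extract the tightest
constants.

`verify_dd()` extracts constants exactly rather than feasibly: for drift
that is affine in $x$ (after the reductions below),
$c_1 = \min_i -L(v)_i / v_i$ and $c_2 = \langle v, b\rangle$ are the
smallest constants valid on the whole orthant (attained along coordinate
rays), and $c_3$ is read coefficientwise off the affine diffusivity. Every
issued certificate is re-audited on random lattice states; the test suite
keeps that audit at zero violations.

## The certificate ladder

`analyze_network()` walks the routes in order and returns the first success
together with the full attempt trace. "No certificate found" is always an
honest outcome — the conditions are sufficient, never necessary, so the
package never claims non-ergodicity. (Divergence diagnostics come from the
simulation layer instead.)

**Unimolecular networks** (mass-action orders 0–1, plus bounded
propensities). The drift is exactly $Ax + b$ with $A$ Metzler (nonnegative
off-diagonal). For Metzler matrices, Hurwitz stability of $A$ is
*equivalent* to the existence of $v > 0$ with $A'v < 0$, and such a $v$ is
constructed directly from the M-matrix identity $v = -(A')^{-1}\mathbf 1$,
which is strictly positive exactly in the stable case. This makes the
certificate search eigenvalue-free, and the equivalence itself is a
property the test suite checks on hundreds of random Metzler matrices.
Bounded propensities (transcriptional regulation of unknown form, declared
only through a supremum) enter $b$ through the conservative envelope
$\sup_k \max(\zeta_k, 0)$; this is what makes the toggle-switch and
repressilator conclusions *structural* — valid for any bounded regulation
and any positive rates.

**Robust certificates.** When rates are known only up to intervals, the
entrywise upper-bound matrix $\bar A$ (interval maxima where the
stoichiometric entry is positive, minima where negative) dominates every
member, and the spectral abscissa of a Metzler matrix is monotone in the
entrywise order, so one certificate on $\bar A$ certifies the family. If a
single rate constant appears in $A$ with both signs (a conversion), no
member attains $\bar A$; a certificate on $\bar A$ is then still valid for
the family, but its failure is inconclusive and is reported as
`bound_matrix_unavailable` rather than as infeasibility.

**Bimolecular networks, conservation route.** The weighted drift of an
order-2 network is $x'Q(v)x + L(v)'x + c(v)$, computed *exactly for the
stochastic kinetics*: a homodimerization propensity $\kappa x(x-1)/2$
splits into $\kappa x^2\!/2$ (into $Q$) and $-\kappa x/2$ (into $L$). The
falling-factorial part matters — it is the reason the stochastic drift of
an autocatalytic model changes sign at a different threshold than the
deterministic flux, which the well-jumping example below exploits. If the
cone $\{v \ge 1 : S_b'v = 0\}$ of weights annihilating every bimolecular
stoichiometric vector is nonempty, $Q(v)$ vanishes identically on it and
the unimolecular linear program applies with the extra equalities. A
nonempty cone is equivalent to a conservation relation among the
bimolecular reactions (dimerization, complex formation, contamination all
have one).

**Conserved pools.** Promoter states have no degradation, so no weight can
give them linear decay — yet gene-expression networks are certifiable
because gene copies live in finite conserved pools ($D + D' = 1$).
`pool_bounds()` detects, per species, a nonnegative conservation vector
proving $x_i \le B_i$ for all time given the initial state; the conserved
route then absorbs catalytic propensities driven by pooled species into the
constant $c_2$ (envelope $\kappa B_i \max(\zeta, 0)$) and demands decay
only of the unconfined species, adding $c_1 \sum_{\text{pooled}} v_i B_i$
back into $c_2$. This is what certifies the circadian oscillator — and
makes the certificate structural, i.e. valid for every positive rate
choice.

**Bimolecular networks without conservation.** Two sufficient relaxations:
force every entry of $Q(v)$ nonpositive (a linear program with $O(d^2)$
constraints, sufficient for $x'Q(v)x \le 0$ on the orthant; this is the
route that certifies the p53 model), or ask for $Q(v) \preceq -\epsilon I$.
The definiteness condition is a small convex minimax problem in $v$
(largest eigenvalue of $\sum_i v_i Q_i$ jointly with the linear drift
condition); the package minimizes it by direct multi-start search and
accepts only weights whose $Q(v)$ passes an exact eigenvalue re-check, so
the numerical search can produce false negatives but never false
certificates. The moment conclusions follow conservative bookkeeping:
order 1 for the componentwise route, order 2 for the definiteness route.

**Competition (Lotka–Volterra) template.** For
immigration–reproduction–competition–death systems the quadratic drift is
controlled by the competition matrix $C$: either some diagonal scaling $D$
makes $DC + C'D$ positive definite, or $C + C'$ is strictly copositive.
`copositivity_test()` decides copositivity exactly for dimensions up to
about 10 by enumerating the KKT supports of the quadratic form on the
probability simplex (each support contributes at most one interior
stationary point, recovered by a linear solve); a returned witness always
satisfies $x \ge 0$, $x'Mx < 0$ by direct evaluation.

**Higher-order kinetics.** For a single species the stochastic drift is a
univariate polynomial; a negative leading coefficient gives DD1 for any
$c_1 > 0$ with $c_2 = \max_{s\ge 0}\,(p(s) + c_1 s)$, located through the
real critical points. This certifies the Schlögl model (trimolecular) as
exponentially ergodic; its diffusivity is cubic, so DD2 fails, no
light-tail or higher-moment claim is made, and the moment table honestly
stops at order 1.

### Numerical conventions

* Strict LP inequalities are implemented as
  $(A'v)_i \le -\epsilon\, v_i$ with $\epsilon = 10^{-6}$; combined with
  the normalization $v \ge 1$ (which fixes the scale invariance of every
  certificate and guarantees $\langle v, x\rangle \ge \|x\|_1$, so moment
  bounds transfer to species counts) this is scale-aware.
* The Hurwitz margin is $10^{-9}$; spectral abscissas within it are
  flagged marginal — a zero eigenvalue can still give bounded moments, but
  their limits may depend on the initial condition, so no ergodicity
  verdict is issued there.
* The certificate linear programs are small (variables = species count,
  constraints at most quadratic in it), so the package ships a compact
  dense two-phase simplex with Bland's anticycling rule, validated against
  a vertex-enumeration oracle, plus a monotone least-element iteration for
  the unimolecular inner problem: the feasible set
  $\{v \ge 1 : (A' + c_1 I)v \le 0\}$ is a lattice, its least element
  minimizes every nonnegative objective simultaneously, and the Bellman-type
  iteration that computes it scales to hundreds of species (the test suite
  solves a 200-species attractor in well under a second).
* Grid searches used for *non-existence* observations (e.g. that no DD1
  weight exists for the divergent-pair example) use 20 log-spaced values
  per coordinate and are reported as "no certificate found at grid
  resolution", never as certified non-ergodicity.

## Optimal attractive sets and moment bounds

Under DD1 the first moment obeys $\frac{d}{dt}E[W] \le c_2 - c_1 E[W]$, so
$\{x \ge 0 : \langle v, x\rangle \le \gamma\}$ with $\gamma = c_2/c_1$ is
an attractive compact set. `optimal_attractor()` minimizes $\gamma$: for
fixed $c_1$ the inner problem (minimize $\langle v, b\rangle$ over the
certificate cone) is a linear program, and the outer scalar search runs a
log-spaced grid over $c_1 \in (0, |\text{spectral abscissa}|]$ followed by
golden-section refinement to relative tolerance $10^{-6}$. Two details
matter: the grid must include the spectral boundary, because the optimum
can sit exactly there (for the birth–death process $\gamma^* = k/\gamma_d$
is attained at $c_1 = \gamma_d$, reproducing the Poisson stationary mean to
machine precision) with certificate weights that blow up along the null
direction while $\langle v, b\rangle$ stays finite; and $\gamma(c_1)$ need
not be unimodal, hence the global grid before the local refinement.

For moment orders $n \ge 2$ the package uses a comparison recursion
obtained from Dynkin's formula and a binomial expansion of the jumps,
using $|\Delta W| \le \bar\zeta = \max_k |\langle v, \zeta_k\rangle|$ and
$W^a \le 1 + W^{n-1}$ for $a \le n-1$:

$$\frac{d m_n}{dt} \le -n c_1 m_n + K_n (1 + m_{n-1}), \qquad
K_n = n c_2 + 2 c_3 \sum_{j=2}^{n} \binom{n}{j} \bar\zeta^{\,j-2}.$$

The resulting uniform and asymptotic tables are *valid but conservative*;
their job is soundness, and the validity (never the tightness) is what the
simulation layer checks: ensemble moments of orders 1–3 must stay below the
tables within Monte-Carlo error, which they do with room to spare. The
first order is reported from the pure drift bound, so the asymptotic
first-order entry equals $\gamma$ exactly. When $c_3$ is finite no order
threshold is imposed; when only DD1 holds the table stops at order 1.

## The moment-closure audit

Cumulant-neglect closure of the first-moment equations is, mechanically,
the evaluation of the falling-factorial propensities at the real-valued
means ($E[x(x-1)]/2 \mapsto (m^2 - m)/2$). `closure_audit()` integrates
that closed system (chunked, with an early bail-out if it diverges),
polishes the equilibrium by Newton's method, checks Jacobian stability, and
measures the Euclidean distance from the closed equilibrium to the
certified attractor $\{x \ge 0 : \langle v, x\rangle \le \gamma\}$ — an
exact projection computed by enumerating the active set of zeroed
coordinates, and validated against a quadratic-programming oracle in the
tests. A closed equilibrium outside the set turns the certificate into a
rigorous *lower bound on the closure error*; the distance metric is a
package choice (the attractor is convex, so any norm would do). For the
dimerization model with equal monomer and dimer degradation rates the
closed equilibrium lands exactly on the attractor boundary — the audit
reports a closure-error bound of zero at machine precision, which is also
what simulated first moments do.

## The simulation layer

`ssa()` is the exact direct method. Stochastic propensities use the
falling-factorial convention ($\kappa x(x-1)/2$ for a homodimerization,
$\kappa x(x-1)(x-2)/6$ for the trimolecular Schlögl channel); the
deterministic layer `rre()` integrates the monomial convention
($\kappa x^m$), and the difference between the two is a modeling fact the
package deliberately preserves, since the qualitative-difference examples
live exactly in that gap. Randomness comes from R's generator, so a seed
reproduces a trajectory bit for bit, and ensembles derive one stream per
path from (master seed, path index). Mass-action networks run in compiled
code; networks with bounded propensities need their `eval_hint` (a concrete
functional form used *only* here — no certificate depends on it) and run in
an R loop, which is adequate for the gene-expression fixtures where they
occur.

Two guards mirror how divergent simulations are stopped in practice: an
event-count cap (default $10^7$) and a total-propensity cap (default
$10^6$ per time unit) — a cap on total propensity rather than on a specific
reaction's rate, which generalizes cleanly across networks. Guard-stopped
paths flag ensemble moments as censored.

`truncated_irreducibility_check()` handles the assumption every verdict is
conditional on: it builds the transition graph on a finite box
(conservation-aware: if a positive vector annihilates every stoichiometric
vector, the graph is restricted to the invariant slice through the initial
state), and verifies that the reachable states form one strongly connected
component. A reachable terminal class that is closed under all reactions in
the *full* lattice — not merely cut off by the box — is returned as a
counterexample witness (the pure-death trap at the origin being the
canonical case); anything else that leaks through the box faces is
inconclusive. Full irreducibility decision procedures are out of scope, so
verdicts record whether irreducibility was asserted by the user or verified
on a truncation.

## The example networks and what they emulate

The fixture registry covers the classic certifiable models (birth–death,
dimerization, gene-expression feedback loop, toggle switch, repressilator,
SIR with demography, circadian clock, p53, open Lotka–Volterra, Schlögl)
and three cautionary ones. Package choices worth recording:

* **Circadian clock.** The Vilar–Kueh–Barkai–Leibler oscillator: activator
  and repressor genes with promoter binding, transcription from both
  promoter states, translation, degradation, and activator–repressor
  complex formation, with the standard parameter values of that model. The
  fixture applies the activator degradation rate $\delta_A$ in *every* pool
  the activator occupies — free, complexed ($C \to R$), and promoter-bound
  ($D' \to D$) — which is the same robustness principle the original model
  emphasizes for the complexed form, and gives 9 species and 18 reactions.
  A long-run time average reproduces stationary protein means near
  $A \approx 222$, $R \approx 535$, $C \approx 550$ at the default rates;
  the promoter-bound degradation channels shift these by under 2%.
* **Jumping potential wells** ($\varnothing \to X$, $2X \to 3X$,
  $X \to \varnothing$). Defaults $(600, 30, 300)$ put the stochastic drift
  roots at 2.12 and 18.88 — the largest kept below 50 so the escape region
  is reachable — and the deterministic fixed points at 2.76 (stable) and
  7.24 (unstable). The rate scale is chosen so that nearly every guarded
  run escapes within a 100-time-unit horizon from $x_0 = 5$, which sits in
  the deterministic basin *and* in the stochastic negative-drift region:
  the point of the example is precisely that the stochastic negative-drift
  region is larger than the deterministic basin (falling factorial), yet
  the process still jumps the barrier and explodes.
* **Stable rate equations, divergent moments**
  ($\varnothing \to X_1$, $X_1 + X_2 \to 2X_2$, $X_2 \to \varnothing$, unit
  rates). The rate equations have the globally stable equilibrium
  $(k_3/k_2,\, k_1/k_3)$; stochastically, extinction of $X_2$ is a trap
  after which $X_1$ grows linearly forever, so no stationary distribution
  exists and first moments grow without bound — while every certificate
  rung honestly fails (no positive weight gives $X_1$ any decay).
* **Carcinogenesis.** A two-type branching picture (renewing normal cells
  mutating into a supercritical mutant clone) whose default rates make the
  mutant population non-ergodic — a reminder that ergodicity is a property
  to establish, not to assume.

The synthetic fixtures emulate the *structure* of these systems — finite
promoter pools, bounded regulation, conservation relations, low-order
mass-action kinetics — under exact stochastic simulation. They do not
emulate measurement noise, extrinsic parameter variability across cells, or
non-exponential waiting times; a passing bound check therefore validates
the mathematics of the certificates against the model class, not any
particular laboratory dataset.

## Problem sizes used by the tests

The test suite runs the certificate searches at full size (they are
linear programs) and scales the Monte-Carlo checks to desk size: 100-draw
random-rate sweeps per gene-network fixture, 2000-path ensembles for the
moment-bound checks, $10^5$ occupation samples for the birth–death
total-variation check, 1000 guarded runs for each divergence experiment,
and a 6000-time-unit single trajectory for the circadian stationary means
(the acceptance script uses 20000, giving the means to about 1%; multi-hour
ensembles of 2000 cells would tighten this further but change nothing
qualitatively).

## Limitations

All conditions are sufficient only; a failed search proves nothing about
instability. The higher-moment constants are conservative by design. The
reaction grammar covers mass-action kinetics to order 3 plus
bounded-supremum propensities — rational propensities (Michaelis–Menten
forms with unbounded numerators) must be re-expressed or bounded by hand.
The negative-definiteness route uses a local multi-start search rather than
an interior-point semidefinite solver, so it can miss certificates (never
fabricate them). Robust analysis covers independent rate intervals via the
bound matrix only. Irreducibility is verified only on truncations.
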