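---
title: "Flux tope analysis: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux tope analysis: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtope)
```

## The model

A metabolic network with $m$ internal metabolites and $r$ reactions is
described by its stoichiometric matrix $N \in \mathbb{R}^{m \times r}$ and a
partition of the reactions into irreversible ($I_{\mathrm{irr}}$) and
reversible ($I_{\mathrm{rev}}$) sets. Steady state and irreversibility define
the *flux cone*

$$C = \{v \in \mathbb{R}^r \mid N v = 0,\; v_i \ge 0 \text{ for } i \in I_{\mathrm{irr}}\},$$

the set of all flux modes. Elementary flux modes (EFMs) are the
support-minimal nonzero elements of $C$; they correspond to minimal pathways
and their enumeration grows combinatorially with model size.

This package works with the complementary object: a **flux tope** (FT) is
the subcone obtained by fixing the direction of *every* reversible reaction,
i.e. the set $C_{\le\tau} = \{v \in C \mid \mathrm{sign}(v) \le \tau\}$ for a
maximal sign vector $\tau \in \{-,+\}^r$ of the cone. Where an EFM involves a
minimal set of reactions, a tope contains a maximal "pathway" carrying flux
in all reactions, and the flux cone is the union of its topes. Two facts make
topes computationally attractive:

* whether a full sign vector defines a tope is a single LP feasibility
  question on the sparse matrix $N$ — no polyhedral double description is
  needed to count or list topes; and
* within one tope all directions are fixed, so per-tope EFM enumeration runs
  on a cone of unchanged dimension: no reversible reaction has to be split
  into a forward/backward pair.

In nullspace coordinates $v = Kx$ (with $NK = 0$), the reversible reactions
define central hyperplanes $K_i x = 0$ and topes correspond to cells of the
arrangement that satisfy the irreversibility constraints; this yields the
cell-count bound implemented by `cell_upper_bound()` and the obvious bound
$2^{|I_{\mathrm{rev}}|}$ of `tope_upper_bound()`.

## Consistency, and why it matters

A cone is *consistent* when every reaction can carry flux in each of its
allowed directions. For a consistent cone every tope has full support, so
candidate sign vectors can be restricted to $\{-,+\}^r$ with $+$ forced on
irreversible positions. `make_consistent()` establishes this premise by flux
variability analysis (FVA): reactions whose flux range is within `tol` of
zero (default $10^{-6}$, deliberately the same constant as the feasibility
LP's flux lower bound, so "blocked" and "infeasible tope" are decided on the
same scale) are removed; reversible reactions with a one-sided range are
re-flagged irreversible, and backward-only columns are negated. All column
negations are recorded in the network's `orientation` and inverted in every
user-facing sign vector, so reported topes always refer to the model as
read.

Dependency detection follows: rows of the nullspace basis $K$ that are
scalar multiples describe reactions whose fluxes are proportional in every
flux mode, hence whose directions flip in lockstep. Only *independent*
reversible reactions contribute search dimensions. A dependency class that
mixes a reversible with an irreversible reaction cannot survive
preprocessing — the irreversible member pins the sign of the whole class and
FVA fixes the reversible members — so after `make_consistent()` a class is
counted reversible exactly when any (equivalently, every) member is.

## Tope enumeration

`enumerate_topes()` performs a breadth-first search over full sign vectors.
The root is an initial tope with a full-support witness flux; the all-plus
orientation is tried first (it typically survives preprocessing), otherwise
a witness is assembled by convex combination of per-reaction feasibility
witnesses — the constructive argument that consistency guarantees a
full-support flux. Level $n$ visits the children (one more minus entry among
independent reversible reactions) of all feasible level-$(n-1)$ parents.
Each candidate is checked at most once; outcomes are cached in a table keyed
on the packed pattern of independent reversible signs. The search stops when
a level yields nothing feasible or all independent reversible reactions are
exhausted.

The feasibility LP for a candidate $\tau$ is

$$N v = 0, \qquad \ell \le \tau_i v_i \le u \quad (i = 1,\dots,r),$$

solved in the variables $w_i = \tau_i v_i$ with the network's own bounds
intersected in. Defaults are $\ell = 10^{-6}$ and $u = 10^3$ with a solver
tolerance of $10^{-10}$; $\ell$ separates "zero" from "used" far above
solver noise, while $u$ keeps the basis well-scaled. Both are exposed
(`lb_mag`, `ub_mag`, and `--lp-lb`/`--lp-ub` on the command line) because
model scaling varies.

One caveat is documented rather than hidden: expanding only children of
*feasible* parents presumes that the tope set is connected through adjacent
sign flips, the premise underlying reverse-search cell enumeration in
hyperplane arrangements. We do not prove that a tope all of whose
lower-level neighbours are infeasible cannot exist; instead the test suite
checks BFS output against exhaustive enumeration over all $2^{n}$ candidates
on dozens of randomly generated consistent networks (the acceptance suite
uses 50, with up to $2^{12}$ candidates each).

The level-synchronized queue is also the threading contract: checking the
children of one parent is an independent task, results are merged by a
single writer, and the *set* of topes (not the discovery order) is the
deterministic guarantee. Output files are written in lexicographic sign
order so artifacts are byte-identical for any thread count.

## Optimization

Linear objectives turn the cone into a flux polyhedron
$P = \{v \mid Nv = 0,\ \ell \le v \le u\}$; `fba()` maximizes $c^\top v$
over $P$. The polyhedron of optimal fluxes appends $c^\top v = d_{\mathrm{opt}}$,
implemented as the interval $d_{\mathrm{opt}} - \mathrm{tol} \le c^\top v
\le d_{\mathrm{opt}}$ with $\mathrm{tol} = 10^{-6}\max(1, |d_{\mathrm{opt}}|)$:
a relative tolerance absorbs optimum jitter at solver precision. FVA under
this constraint then restores full support on the optimal set. Reactions
forced to zero flux at the optimum pose a representational choice — they
could be kept as zero entries of (then non-full) sign vectors or dropped
from the alphabet. We drop them and report them separately
(`removed_at_optimum`): full-support candidates keep the enumeration
machinery unchanged and the removed set is informative in itself.
`enumerate_optimal_topes()` carries the optimality interval inside every
feasibility LP, so optimal topes are found directly, without enumerating the
cone's topes first.

## Per-tope EFM enumeration

`enumerate_efms_in_tope()` orients all columns by $\tau$ and enumerates the
extreme rays of $\{v \mid Nv = 0, v \ge 0\}$ by double description in the
nullspace representation. All arithmetic is exact: rational stoichiometries
are scaled row-wise to integers, the nullspace basis comes from fraction-free
elimination, rays are integer vectors reduced by their gcd after every
combination step, and a guard aborts if intermediates approach $2^{52}$
(beyond which doubles no longer represent integers exactly). Exactness over
speed is the right trade at the scale this package targets — single topes of
small-to-medium models — and removes rank and tie ambiguities entirely. The
insertion order of inequalities is "most zeros first"; adjacency of rays is
decided combinatorially.

Canonical EFM normalization divides by the gcd, giving coprime integer
vectors; this is the deduplication key across topes
(`enumerate_efms_via_topes()`). Sign patterns alone would not suffice, as
distinct EFMs can share a support. The per-tope sets are kept alongside the
global set, which makes the structural cross-checks cheap:
`verify_tope_efm_duality()` confirms that each tope's EFM set is exactly the
conforming subset of the global set, that it is maximal conformal, and that
the union over topes recovers every EFM. No global reaction-splitting
enumerator is provided: within this framework it answers no question the
tope decomposition does not answer with less machinery.

## Post-enumeration analytics

`adjacency_histogram()`, `direction_frequencies()` and
`pair_direction_matrix()` summarize the coordination of reaction directions
across a complete tope set. Adjacency is counted over independent reversible
positions only; counting dependent reactions as well would double-count
single degrees of freedom. Pair-direction counts conserve mass (the four
combinations of a pair partition the tope set) and zero cells are flagged
infeasible.

For truncated searches, `fit_incremental_gaussian()` fits
$a\,e^{-(n-\mu)^2/2\sigma^2}$ to the per-level counts by nonlinear least
squares (Levenberg–Marquardt, nonnegative amplitude) and sums the fitted
curve over all levels to extrapolate the total tope count. The fit is on raw
counts, not log counts — the tails would otherwise dominate — and requires
at least four positive levels. Parameter recovery, not any published
parameter table, is the accuracy contract: on synthetic truncated Gaussian
level counts the estimate is within 50% of the truth once roughly the first
half of the curve is observed, and improves with each further level (both
properties are asserted in the test suite).

## The synthetic network generator

`random_network(m, r, n_rev, density, seed)` is first-class, tested code: it
provides the study conditions for every property suite. Each matrix row is a
sum of disjoint two-column "pair vectors" chosen orthogonal to a hidden
strictly positive integer flux, so by construction every generated network
admits a full-support positive flux mode: no reaction can be blocked,
coefficients stay integers in $[-3, 3]$, and `make_consistent()` only ever
fixes directions of reversible reactions that cannot run backward. Defaults
(`density = 0.3`, coefficients from a hidden flux in $\{1,2,3\}$) were
chosen once to give small networks with a realistic mix of exchange-like and
coupled internal reactions; across seeds, networks with $m \in [3,6]$,
$r \in [7,12]$ retain two to five reversible reactions and 4–24 topes.

What the generator does *not* emulate: genome-scale sparsity patterns,
compartments, highly coupled enzyme subsets longer than proportional pairs,
and biomass-style dense objective columns. Passing property tests on these
fixtures therefore certifies algorithmic correctness (BFS equals exhaustive
enumeration; duality between topes and maximal conformal EFM sets), not
performance or numerical behaviour on genome-scale models.

## Problem sizes and tolerances used by the test suite

The suites run at desk scale by choice: the toy network (3 metabolites, 6
reactions, 5 topes, 6 EFMs) anchors every exact expectation; the brute-force
equivalence suite draws 50 networks with at most $2^{12}$ candidate sign
vectors each; the duality suite uses the toy plus six random networks; the
Gaussian recovery suite uses synthetic counts with $a = 10^6$, $\mu = 20$,
$\sigma = 4$ truncated at levels 12–20. Zero tolerance for sign extraction
is $10^{-9}$ — three orders below the LP flux lower bound and above the
$10^{-10}$ solver tolerance — so witness fluxes can never be misread as
zero. Proportionality of nullspace rows uses scale-invariant $2 \times 2$
minors below $10^{-9}$ after row normalization.

## Known limitations

* The LP layer is a dense two-phase tableau simplex; it is exact enough and
  fast enough for desk-scale models but will not carry genome-scale
  matrices. The interfaces (`check_tope_feasible()`, `flux_variability()`)
  are solver-agnostic by design.
* Unboundedness in FVA and FBA is detected with an artificial box at
  $|v| = 10^6$ plus a widened re-solve; fluxes that are genuinely finite but
  above $10^5$ would need a larger `big`.
* Thermodynamic feasibility of topes (ruling out internal-cycle-only
  directions) is out of scope; the toy network's two topes containing the
  internal cycle are reported like any others.
* Floating-point (irrational) stoichiometries fall back to a floating
  nullspace for tope enumeration and are rejected by the exact EFM path.
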