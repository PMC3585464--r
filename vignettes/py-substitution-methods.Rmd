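---
title: "Methods: symbolic steady states by py-substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic steady states by py-substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pysub)
```

## The model class and the steady-state problem

A mass action model is a set of species $X$ and reactions $R$ with
stoichiometric matrix $N$ (entries $s^P_{ij} - s^R_{ij}$) and velocities
$v_j = k_j \prod_i x_i^{c_{ij}}$, where the kinetic order $c_{ij}$ defaults
to the reactant stoichiometry but may be overridden (the reaction format
accepts `order(X) = n` annotations). The mass balance is
$\dot x = N v$; a steady state is any root of $N v = 0$, and it is
*non-trivial* when the individual velocities are nonzero but balance —
the tonic-signalling regime that a living cell at rest occupies. Because
bimolecular velocities make $N v$ quadratic in the concentrations, the
steady states form an algebraic variety with no generic closed form.

## The change of variables

*py*-substitution exploits two facts: $v_j$ is always degree 1 in its rate
constant, and rarely more than degree 2 in the concentrations. Assign every
quantity — concentration or rate constant — to either a *coefficient set* P
or a *linear set* Y, such that every velocity is homogeneous of **degree
exactly 1** in the Y symbols (`validate_partition()` reports the degree per
velocity). Then

$$N\,v = C\,\bar y, \qquad C = N \cdot \partial v/\partial y,$$

with $C$ a matrix over the fraction field $\mathbb{Q}(\mathrm{P})$, and the
steady-state set is the null space of $C$. With a basis $B$ (nullity $q$),
$\bar y = B u$ for free coefficients $u$: the free columns of the reduced row
echelon form correspond to Y quantities that remain independent, the pivot
columns to quantities expressed as rational functions of the independents.
Composing the partition, the null-space solution and the renaming of the
$u$'s back to the quantities that own the free columns yields the
steady-state map $\sigma$, which sends every quantity either to itself or to
an expression in the independent quantities.

Two structural invariants follow from rank-nullity and are enforced in the
test suite: the number of dependent quantities equals $\mathrm{rank}(C) =
\mathrm{rank}(N)$ regardless of the partition, and the number of independent
quantities equals $|X| + |R| - \mathrm{rank}(N)$.

## Pivot policy and the meaning of Y order

Row reduction pivots greedily on the lowest-indexed Y columns, so *the order
of Y is part of the partition*: quantities listed early are favoured to
become dependent, quantities listed late to stay independent. This is
deliberate and reproducible — the same partition always produces the same
pivot set, basis and expressions (term order in printed polynomials is a
fixed lexicographic order on radix-sorted symbol names, so expression dumps
are byte-identical across runs).

Finer control is available through `select_independent()`: a set of $q$ Y
quantities can serve as the independent parameters iff the corresponding
rows of $B$ form an invertible matrix $G$; the function either returns
$u = G^{-1} w$ and the re-expressed solution or a rejection carrying the
zero determinant. `count_admissible_partitions()` counts all invertible
$q$-row subsets; the count is a property of the row matroid of $B$ and is
therefore independent of the basis choice. For the fumarase model with
time-varying substrates this count is 72 of the $\binom{10}{5} = 252$
subsets.

## Pseudospecies and solution branches

Two kinds of velocity cannot be made degree 1 by assignment alone:

* **Sublinear** (degree 0): a zero-order velocity whose rate constant must
  stay in P. The velocity is multiplied by a fresh Y variable $s$ with the
  constraint $\bar s = 1$.
* **Superlinear** (degree 2): a squared Y concentration $x^2$. The square is
  replaced by a fresh Y variable $s$ with the constraint
  $\bar s = \bar x^2$.

Constraints are resolved after the null-space step by substituting
$\bar y = B u$, giving polynomial equations in the $u$'s. The solver
eliminates a $u$ in which the equation is linear whenever one exists
(preferring the $u$ owned by a pseudospecies column, then the
highest-indexed); a constraint quadratic in every available $u$ produces two
branches, one per root. The quadratic is kept exactly as its coefficient
triple $(a, b, c)$ plus a root sign: verification reduces the residual
modulo the relation $a u^2 + b u + c = 0$, and numeric realization solves
the root and flags a branch infeasible when it is negative or complex.
Bistability therefore surfaces naturally as two branches of which a given
parameterization typically admits one. Constraint systems that go beyond a
single terminal quadratic are returned unsolved with an instruction to
reorder Y — the only models that need more are outside the regime this
package targets.

Bilinear violations ($y_a y_b$ with distinct Y quantities) are *not* fixed
with pseudospecies; the validator instructs the user to move one factor to
P, which is always possible and keeps the construction canonical.

## Exact linear algebra

All symbolic computation bottoms out in a sparse multivariate polynomial
kernel with integer coefficients and a rational-function layer on top.
Correctness rests on three choices:

* **No floating point before the numeric layer.** Zero-testing expands the
  numerator polynomial; equality is polynomial identity, so the residual
  verification $N v(\sigma) \equiv 0$ is a proof, not a tolerance check.
* **Fraction-free elimination.** Naive Gauss–Jordan over the fraction field
  swells catastrophically (denominators pile up as uncancelled products).
  The engine instead uses one-step fraction-free Gauss–Jordan
  (Bareiss/Montante): every entry stays a polynomial, every division is
  exact by construction, and the final matrix equals the RREF times a single
  common pivot polynomial. The null-space basis inherits this one-
  denominator form, which downstream operations (determinants, target
  selection) exploit to stay polynomial.
* **Modular screening with exact confirmation.** Counting invertible
  submatrices evaluates the basis at deterministic generic points modulo a
  31-bit prime: a nonzero modular determinant *certifies* symbolic
  invertibility; only the (suspected singular) remainder is confirmed by an
  exact fraction-free determinant. The reported count is exact.

Ranks and pivots are *generic*: P symbols are treated as algebraically
independent. Specific numeric values can drop rank (e.g. exactly balanced
rate constants); realized solutions report a numeric residual so such
degeneracies surface at evaluation time.

## King–Altman for the linear subclass

A model is linear (after freezing designated species, whose concentrations
remain P symbols but whose balance rows are dropped) when every reaction
converts exactly one time-varying species into another and velocities are
degree 1 in the time-varying concentrations. The transition matrix $K$
holds the pseudo-first-order rates $\kappa$ (rate constant times any frozen
concentrations); its columns sum to zero symbolically. King–Altman patterns
for root $i$ are the directed spanning trees into $i$, enumerated by
recursive out-edge assignment with an incremental cycle check and
deduplicated by edge set; the pattern sum equals the principal minor of $K$
up to the matrix-tree sign $(-1)^{n-1}$, and both routes are computed and
compared in the tests (the module's internal oracle pair). Concentrations
are normalized to a total symbol; the equivalence check against a
py-substitution solution imposes the same total and requires every
difference to vanish identically.

## Numeric layer defaults

* Integration: `deSolve::lsoda`, absolute tolerance $10^{-8}$ (state
  units), relative $10^{-6}$; default horizon 48 h (apoptosis-style runs).
* Dose threshold: bisection on log fold-change, default bracket
  $[1, 10^6]$, relative tolerance 1% (the published dose ranges span orders
  of magnitude; the tolerance is our choice, stated here once).
* Sensitivities: backward finite difference with a 1% relative step in each
  quantity's steady value, the dependent quantities recomputed through
  $\sigma$ so each probe starts at steady state; coefficients are
  normalized to the maximum absolute value (so $\max |s| = 1$).
* Steady-state scans: geometric grid over a 100-fold range centered on the
  base value (endpoints base/10 and base×10), with $\sigma$-compensation at
  every point; infeasible points are flagged and skipped, not fatal.
* Switch event: the generic predicate is "the designated output exceeds a
  stated level at any time in the horizon"; the level is a caller choice
  because no universal cleavage fraction fits all models.

## Fixtures and the synthetic generator

The bundled fixtures transcribe printed desk-scale models: four open
Michaelis–Menten strategies (homogeneous, heterogeneous, sublinear,
superlinear) and the Hansen fumarase mechanism in its frozen-substrate
(`fum1`) and time-varying-substrate (`fum2`) treatments. Two fixture-level
choices were genuinely open and are package decisions:

* **fum2 partition.** Degree-1 homogeneity forces the bimolecular
  (association) rate constants into P — their velocities already carry the
  substrate concentration as the Y factor — and the unimolecular
  (dissociation) rate constants into Y. The fixture therefore uses
  Y = {F, H, OH, M, d1…d6}, P = {five enzyme forms, a1…a6}. The nullity
  (5) and the 72-selection count are unaffected by this labelling.
* **omm4 partition.** The squared complex ES and its pseudospecies sit at
  the high end of Y, so both own free columns and the closure constraint
  becomes the product relation $u_s = u_{ES}^2$, which eliminates cleanly
  in either direction. Orderings that force both into pivots lead to surd
  expressions with no printed counterpart, so the fixture avoids them.

`random_linear_model(n_species, n_reactions, seed)` draws distinct directed
first-order conversions uniformly without replacement and rejects weakly
disconnected draws (rejection, not repair). It emulates benchmark-style
first-order networks: six species and 10–20 reactions in the tests. It does
*not* emulate bimolecular structure, conservation pools, or realistic rate
magnitudes — passing the random-model properties (zero symbolic residual,
rank-nullity, King–Altman equivalence) demonstrates correctness of the
algebra on arbitrary first-order topologies, not biological realism.

`toy_switch()` is a two-species positive-feedback module built for the
threshold machinery: signal S drives autocatalytic production of A
(velocity $k_f S A^2$) against basal synthesis, linear decay and a cubic
sink that bounds the induced state. Its reference realization
(S = A = 1, kds = 0.01, kf = 0.2, kda = 1, kc = 0.02) places the resting
state on the low branch with a fold-threshold near 1.85 on S within the
48 h horizon; these values are internal ground truth for oracle comparisons
(binary search vs. grid scan) and are not measurements of any published
system. The slow S turnover (100 h) separates the input timescale from the
response timescale, which keeps the threshold sharp.

The extended apoptosis model is deliberately a loader plus schema validator
(58 species / 115 reactions enforced), not bundled data: the package stays
buildable with no external inputs while a user holding the published
supplementary description can reproduce the full analysis.

## Problem sizes and test design

The suite runs the complete pipeline on all seven fixtures, verifies the
residual and rank-nullity on 50 seeded random first-order models (6 species,
9–20 reactions, homogeneous strategy), checks King–Altman/py equivalence on
the fumarase and on seeded 5-species models, and compares every
pattern-count against the determinant route. These sizes keep the whole
suite under two minutes on one core while exercising every code path;
the symbolic engine itself handles the 9×10 fumarase system in about a
second and scales to the tens-of-species regime via the fraction-free
elimination.

## Known limitations

* Input is the plain-text reaction format only; SBML import is not
  provided in this version.
* Rank decisions are generic in the P symbols (see above).
* Constraint resolution handles chains of linear eliminations plus at most
  one terminal quadratic; deeper polynomial systems are returned unsolved
  rather than attempted by Gröbner-style elimination.
* No claims are made about uniqueness or stability of a steady state; the
  package parameterizes the steady-state variety and verifies membership,
  and the numeric layer reports (in)feasibility of a given realization.
* No optimization over the space of admissible partitions is attempted;
  `count_admissible_partitions()` tells you how large that space is, and
  `select_independent()` lets you pick within it.
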