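# pysub — analytical steady states of mass action models by *py*-substitution

Mass action models of signalling networks are polynomial ODE systems
`dx/dt = N v(x; k)`, where `N` is the stoichiometric matrix and each velocity
is `v_j = k_j ∏ x_i^{c_ij}`. Their non-trivial steady states are roots of a
nonlinear system, so no closed-form expression exists in general — yet an
*analytical* steady-state expression is exactly what one needs to study how a
cell's resting state shapes its response to perturbation, to derive rate
constants from measured concentrations, or to keep a model at steady state
while its parameters are varied systematically.

`pysub` implements ***py*-substitution**, a change of variables that makes
this tractable for arbitrary mass-action structure. Every quantity (species
concentration or rate constant) is assigned to a coefficient set **P** or a
linear set **Y** such that every velocity is homogeneous of degree 1 in the Y
symbols. The steady-state equation then collapses to a linear system

    C ȳ = 0,   C = N · ∂v/∂y,

over the fraction field ℚ(P) of rational functions in the P symbols. A
null-space basis `B` of `C` (special-solution normalization, computed by
exact fraction-free elimination) parameterizes the steady-state manifold:
`ȳ = B u` expresses each pivot (dependent) quantity as a rational function of
the free coefficients `u` and the P symbols. Zero-order velocities
(degree 0 in Y) and squared concentrations (degree 2) are linearized with
*pseudospecies* — auxiliary Y variables whose defining constraints are
resolved afterwards on the `u` coefficients, linearly when possible and
through the two roots of a quadratic otherwise (each real root is a solution
branch). The composed map σ is verified symbolically: `N v(σ) ≡ 0` by exact
polynomial expansion, never floating point.

For the *linear* subclass (every reaction converts one time-varying species
into another), the package also implements the classical **King–Altman**
method — enumeration of the rooted spanning-tree patterns whose rate-product
sums are the principal minors `M_ii` of the transition matrix, with
`x̄_i ∝ M_ii` — and a symbolic equivalence check between the two solutions.
A numeric layer realizes a solution with parameter values, integrates
perturbations (stiff-capable `deSolve::lsoda`), locates dose thresholds by
binary search, and computes max-normalized backward-finite-difference
sensitivity coefficients with steady-state compensation.

## Worked example: the open Michaelis–Menten model

An enzyme system with substrate synthesis and product degradation, so that a
non-trivial steady state exists:

```r
library(pysub)

omm <- parse_model("
  E + S -> ES ; k1    # binding
  ES -> E + S ; k2    # dissociation
  ES -> E + P ; k3    # catalysis
  Ø -> S      ; k4    # zero-order synthesis
  P -> Ø      ; k5    # first-order degradation
")

# homogeneous strategy: all concentrations to P, all rate constants to Y
phi <- partition_map(omm, Y = c("k1", "k2", "k3", "k4", "k5"))
res <- solve_steady_state(omm, phi)
glance(res)
#>   n_species n_reactions  rank nullity n_independent n_dependent ...
#> 1         4           5     3       2             6           3
tidy(res$branches[[1]])
#>   quantity kind    class         expression
#> 1 E        species P             E
#> 2 S        species P             S
#> 3 ES       species P             ES
#> 4 P        species P             P
#> 5 k1       rate    dependent-Y   (ES*k2 + P*k5)/(E*S)
#> 6 k2       rate    independent-Y k2
#> 7 k3       rate    dependent-Y   P*k5/ES
#> 8 k4       rate    dependent-Y   P*k5
#> 9 k5       rate    independent-Y k5
```

Reading the table: of the 9 degrees of freedom (4 concentrations + 5 rate
constants), `rank(C) = 3` are constrained by steady state. The coefficient
matrix row-reduces with free columns 2 and 5, so the dissociation and
degradation rates `k2`, `k5` remain independent alongside all four
concentrations — knowing every steady concentration tells you nothing about
those two rates, and any concentration vector is consistent with infinitely
many rate-constant vectors. The dependent rates are rational functions of
the independents, e.g. `k4 = P*k5` (synthesis must balance degradation flux),
and substituting the map back into `N v` gives an identically zero residual.

The same model solves under a heterogeneous strategy (enzyme kinetic
constants forced independent), a sublinear strategy (the zero-order synthesis
constant kept independent via a pseudospecies) and a superlinear variant
(catalysis ∝ ES², pseudospecies for the square): `fixture("omm1")` …
`fixture("omm4")`. All four yield exactly 3 dependent quantities — the count
depends only on `rank(N)`, not on the strategy.

Other entry points:

```r
f <- fixture("fum1")                            # fumarase, substrates frozen
ts <- transition_system(f$model, f$frozen)      # 5x5 transition matrix
ka <- ka_steady_state(ts, "Etot")               # King-Altman patterns/minors
py <- solve_steady_state(f$model, f$phi)$branches[[1]]
equivalence_check(ka, py)$equivalent            # TRUE, symbolically

f2 <- fixture("fum2")                           # substrates time-varying
sys <- coefficient_matrix(f2$model, f2$phi)     # |Y| = 10, nullity 5
count_admissible_partitions(sys)                # 72 of the 252 row subsets
```

A thin command-line wrapper with `solve`, `ka`, `compare`, `simulate`,
`threshold`, `sensitivity`, `scan`, `gen` and `validate` subcommands is
installed at `system.file("cli", "pysub", package = "pysub")`.

The extended apoptosis model (xEARM, 58 species / 115 reactions) is not
bundled: transcribe the published supplementary `xearm.mpl` into the reaction
format and load it with `load_xearm(path)`, which enforces the schema.

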