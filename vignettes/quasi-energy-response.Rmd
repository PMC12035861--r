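---
title: "Symbolic quasi-energy response functions: models, elimination rules, and exact two-level evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic quasi-energy response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qresponse)
```

## The problem

Frequency-dependent molecular properties — polarizabilities,
hyperpolarizabilities, and their geometric analogues — are derivatives
of the time-averaged quasi-energy Lagrangian of a periodically driven
quantum system with respect to the strengths of the applied
perturbations, evaluated at zero strength.  Deriving these expressions
by hand becomes unmanageable beyond third order: the product rule
scatters derivatives across every constituent of the Lagrangian, the
variational structure permits (but does not require) the elimination of
whole families of response parameters, and each electronic-structure
model (self-consistent field in an atomic-orbital density-matrix
formulation, coupled cluster, ...) contributes its own constraints and
multipliers.

`qresponse` performs this derivation symbolically.  It builds the
quasi-energy Lagrangian of a chosen model as an immutable expression
tree, differentiates it with respect to an ordered collection of
perturbations, applies generalized elimination rules, removes the
terms that vanish at zero perturbation strength, and — for a two-level
atom, where everything is exactly computable — evaluates the result in
exact rational arithmetic.

## Perturbations and multichains

A perturbation carries a strength symbol (the complex Fourier
coefficient of its time-periodic envelope), a frequency, a number of
tensor components (3 for dipole-like fields, 3N for geometric
displacements), and a maximum differentiation order for operators that
depend on it.  Mixed strength derivatives are written as *perturbation
multichains*: totally ordered multisets of perturbations.  The length
of a multichain is its derivative order, equal perturbations must be
consecutive (`abbc` is valid, `abcb` is not), and the member order
fixes the shape of the derivative tensor — `abc` with two dipole and
one geometric perturbation denotes a (3, 3, 3N) tensor, `acb` a
(3, 3N, 3) one.  Internally, derivative bookkeeping stores multichains
in a canonical order (mixed partials commute); the user-facing chain
order is preserved as shape metadata.

The combinatorial backbone of higher-order differentiation is the set
partition of the index chain {1, ..., n}: the n-th derivative of a
product distributes sub-multichains over factors according to these
partitions.  The implementation differentiates order by order, which
reproduces the same expansion; `set_partitions()` exposes the
combinatorics directly and is tested against Stirling/Bell recurrences.

## The two Lagrangians

**Density-matrix formulation.**  For a perturbation $a$ and a
time-independent basis the package builds the variational
time-averaged quasi-energy derivative Lagrangian

$$\tilde L^a \;=\; \operatorname{Tr}_T\!\Big[\tilde E^{0,a}
  \;-\; \tilde S^a \tilde W
  \;-\; \tilde\lambda_a \tilde Y
  \;-\; \tilde\zeta_a \tilde Z\Big],$$

with the TDSCF constraint
$\tilde Y = \tilde F\tilde D\tilde S - \tilde S\tilde D\tilde F
- i\,\tilde S \dot{\tilde D}\tilde S$, the idempotency constraint
$\tilde Z = \tilde D\tilde S\tilde D - \tilde D$, and the generalized
energy-weighted matrix $\tilde W$ kept as an opaque symbol with
declared dependencies (its internal formula is substitutable by the
user).  In an orthonormal basis the overlap never enters.  The
multipliers are opaque perturbed parameters until the elimination
step; the survivors are then expanded through the ansätze

$$\tilde\lambda_a = \tilde D^a \tilde S \tilde D
                  - \tilde D \tilde S \tilde D^a,
\qquad
\tilde\zeta_a = \tilde F^a \tilde D \tilde S
              + \tilde S \tilde D \tilde F^a - \tilde F^a.$$

These forms were derived by imposing stationarity of $\tilde L^a$
under arbitrary density variations for a one-electron Fock operator
(the case the two-level evaluation exercises): using the TDSCF
equation, idempotency and the Jacobi identity one finds
$[\lambda_a, F] + i\dot\lambda_a = [[F^a, D], D]$ for
$\lambda_a = [D^a, D]$, and the remaining condition
$D\zeta_a + \zeta_a D - \zeta_a = F^a - F^aD - DF^a + 2DF^aD$ admits a
one-parameter family of solutions of which
$\zeta_a = F^aD + DF^a - F^a$ is chosen (the $S$-dressed form above is
its general-basis rendering).  The choice is validated operationally:
response values are invariant, to exact rational equality, under the
admissible elimination alternatives that route the computation through
these ansätze.

**Coupled-cluster formulation** (orbital relaxation neglected).  The
quasi-energy Lagrangian is

$$\tilde L = \big\langle e^{\mathrm{ad}_{-T}}(H)\big\rangle
 + \tilde{\boldsymbol\lambda}\cdot\Big(
   \big\langle e^{\mathrm{ad}_{-T}}(H)\big\rangle_\mu
   - i\,\dot{\tilde{\mathbf t}}^{\,T}\Big),$$

with cluster operator $T = \tilde{\mathbf t}\cdot\hat{\boldsymbol\tau}$
and the similarity transform expanded through the
Baker–Campbell–Hausdorff series
$\sum_{j\le J} (1/j!)\,(\mathrm{ad}_{-T})^j(H)$ into explicit nested
commutator products.  The default truncation is $J = 4$, exact for
Hamiltonians with at most two-body interactions; $J$ is configurable,
which also enables the numeric convergence oracle in the tests (the
expansion against the exact $e^{-T} H e^{T}$ for random 2×2 matrices).

## The elimination skeleton

`get_response_functions()` is a template method running six calls in a
fixed order: frequency validation (the frequencies of all
perturbations must sum to zero; for the density-matrix model the
frequency of $a$ must be the negative sum of all others),
extensive/intensive disjointedness validation, Lagrangian retrieval
plus differentiation, elimination of wave-function-parameter
derivatives, elimination of multiplier derivatives, and the
zero-strength cleanup (undifferentiated field operators vanish;
time-differentiated quantities that are unperturbed or have zero
frequency sum are removed).  Concrete models override individual hooks
without changing the skeleton.

With $k$ extensive perturbations, the minimum elimination order
$k_{\mathrm{wfn}}$ ($k_t$ or $k_D$) is admissible when
$k_{\mathrm{wfn}} \ge \lfloor k/2\rfloor + 1$; values above $k$ mean
nothing is eliminated and all multipliers can be removed.  The
automatic choice (`min_wfn_exten = 0`) is the lower bound.  The
multiplier minimum order is
$k_\lambda = \max(k - k_{\mathrm{wfn}} + 1,\, 0)$, eliminating
differentiated multipliers to the greatest compatible extent.  With
all perturbations extensive and the automatic choice this reproduces
the familiar 2n+1 rule for wave-function parameters and 2n+2 rule for
multipliers, which the test suite asserts for orders 2 through 5.

`eliminate()` itself is a purely structural order filter: it removes
every additive term containing a derivative of the parameter whose
order over the extensive set lies in the banned range.  Its
*correctness* as an elimination rule rests on the admissibility
conditions enforced by the driver, not on the filter — which is why
the package also tests value invariance, not just structure.

## Exact evaluation on the two-level atom

The evaluation model realizes every operator as a 2×2 matrix: the
unperturbed Hamiltonian is $\mathrm{diag}(E_0, E_1)$, the system
starts in the ground state, and each perturbation carries one
Hermitian field operator differentiable only to first order.  From the
Liouville equation in the frequency domain, the order-n density
derivative follows recursively from order n−1:

$$\rho^{b_1\cdots b_n}_{jk}
 = \frac{\sum_{i}\big[V^{b_i},\,
     \rho^{b_1\cdots\widehat{b_i}\cdots b_n}\big]_{jk}}
        {\omega_{b_1\cdots b_n} - (E_j - E_k)},$$

so no linear response equation needs solving; derivatives are cached
per model.  The switch-on infinitesimal that regularizes resonances is
taken to zero from the outset: frequencies here are generic symbols or
rationals drawn off resonance (the fixture generator redraws until no
sub-multichain frequency sum hits $0$ or $\pm\Delta E$), so every
denominator is structurally nonzero and the limit is trivial.

All arithmetic is exact: complex rationals for coefficients and matrix
entries, and linear forms with rational coefficients over frequency
symbols and the level splitting $\Delta E$ for denominators.  Exactness
is what makes term counting and equality testing decisive rather than
tolerance-dependent.

**Canonical terms.**  An evaluated scalar is decomposed by its
transition-moment numerators: terms are keyed by the sorted product of
matrix-element factors $V_x[i,j]$, merged by summing their rational
frequency coefficients, and a key survives only if the merged
coefficient is not identically zero.  Zero testing evaluates the
coefficient exactly at two deterministic generic points (the m-th
symbol receives $p^{-m}$ for $p = 2$ and $3$); because every
denominator factor is an integer combination of distinct symbols with
unit coefficients, such points can never annihilate a denominator, and
a nonzero rational function cannot vanish at both assignments.
Denominator factors are sign-normalized (leading $\Delta E$
coefficient positive).  This canonicalization is the package's
operational definition of "unique term"; under it the third-, fourth-
and fifth-order response functions of the two-level atom decompose
into exactly 12, 54 and 220 unique terms, the model's headline
numbers.  Because a term survives precisely when its $V$-monomial has
a nonzero rational-function coefficient — a property of the function,
not of any particular representation — the counts are independent of
which admissible elimination produced the expression.

## Response-equation right-hand sides

Solving the response equations numerically is deliberately out of
scope; the package emits their symbolic ingredients.  For the
density-matrix model, `dao_response_rhs()` differentiates the TDSCF
constraint to order n and substitutes the full order-n density
derivative by a particular-solution symbol (the time derivative
becomes an explicit $-i\omega$ frequency factor, which vanishes in the
static limit), and `dao_particular_density()` truncates the
differentiated idempotency constraint after order n−1.  For coupled
cluster, `cc_response_rhs()` removes the top-order terms from the
differentiated stationarity conditions and attaches the left-hand-side
structure — $(A - \omega I)$ on amplitudes, $(A^T + \omega I)$ on
multipliers, with $A$ the coupled-cluster Jacobian kept opaque — as
metadata.  The multiplier stationarity condition is represented as a
formal, unexpanded parameter gradient: expanding it would require
component-level amplitude algebra that the symbolic layer deliberately
avoids.  Sign conventions of the emitted right-hand sides are the
package's own and are documented on the functions.

## What the synthetic models do and do not emulate

The fixture generator produces seeded, byte-reproducible two-level
models: random Hermitian operators with small integer entries, random
rational frequencies with zero total sum, and an integer level
splitting, redrawn deterministically to stay off resonance.  These
models exercise every algebraic path of the pipeline — noncommuting
operators, complex entries, frequency cancellation, elimination and
ansatz substitution — under exact arithmetic.  They do not emulate
real electronic structure: there is no basis set, no two-electron or
exchange-correlation contribution (those enter the density-matrix
Lagrangian only as opaque symbols), no resonant response, and no
N-level structure.  Passing tests therefore certify the symbolic
machinery and the two-level evaluation exactly, but say nothing about
integral evaluation or numerical conditioning in a real calculation,
which are user-side concerns by design.

## Numerical and design choices

* Scalars are exact complex rationals stored as integer pairs in
  doubles, with overflow guarded at $2^{52}$; frequencies are exact
  linear forms.  Floating-point frequencies are rejected at the API
  boundary.
* Expressions are kept expanded (products distribute over sums at
  construction) because additive terms are the granularity of
  elimination and zero-strength filtering; sums collect like terms
  under canonical keys computed once per node.
* Matrix products are never reordered (noncommutative); only scalar
  coefficients are canonicalized.
* Derivative nodes are atomic occurrences: a derivative of a field
  operator does not count as an occurrence of the bare operator.
* Problem sizes in the shipped tests: two-level term counting through
  order 5 (about 15–20 s); coupled-cluster elimination properties at
  orders 2–5 with BCH truncation 4, 2, 1, 1 respectively — the
  elimination bounds are independent of the truncation, and these
  sizes keep the symbolic expansion (which grows roughly as
  $(2J+2)^n$ terms) proportionate to what the assertions need.
* Serialization is a versioned JSON tree with a `kind` tag per node;
  LaTeX export is deterministic.

## Limitations

Multiconfigurational and orbital-relaxed coupled-cluster Lagrangians,
excited-state residues, relativistic Hamiltonians, and
perturbation-dependent basis-set integrals are out of scope.  The
density-matrix Lagrangian is implemented for time-independent basis
sets (a perturbation-dependent overlap is supported symbolically, but
the extra half-time-differentiated overlap terms of a time-dependent
basis are not constructed).  Equality of differently-eliminated
coupled-cluster expressions is checked numerically on the two-level
realization of the density-matrix model; no symbolic equivalence
prover is attempted.  The search for *optimal* elimination parameters
is left to the user; the run log's per-step term counts are the
intended starting point for it.
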