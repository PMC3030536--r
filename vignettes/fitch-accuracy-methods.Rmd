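---
title: "Exact reconstruction accuracy of Fitch parsimony: model, recurrence, and numerics"
output: html_document
vignette: >
  %\VignetteIndexEntry{Exact reconstruction accuracy of Fitch parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitchacc)
```

## The model and the two accuracies

A character with state set `{1, …, N}` evolves down a rooted binary tree under
the symmetric (Jukes–Cantor type) Markov model: along the branch into node
`v`, the state is conserved with probability `q = 1 − (N−1)p` and changes to
each specific other state with probability `p`. On a branch of length `l`
with substitution rate `λ`, `p = (1/N)(1 − e^{−Nλl})`, so `p` never exceeds
the stationary value `1/N`.

Fitch parsimony reconstructs the root state in two passes. Leaf-to-root, each
node gets a state set: a leaf its own state, an internal node the
intersection of its children's sets if nonempty, else the union (each union
event is one unavoidable substitution; their count is the parsimony score).
Root-to-leaf, one state is resolved per node, uniformly at random from the
root set and copied downward whenever compatible.

Two success probabilities are of interest, conditional on the (symmetric,
hence irrelevant) true root state:

* **UA** — the root set is exactly the true state's singleton;
* **AA** — a uniform draw from the root set hits the true state,
  `AA = Σ_{B ∋ s_true} Pr[S_r = B]/|B|` (so `UA ≤ AA` always).

## The class recurrence

The naive computation sums over `N^L` leaf configurations; a set-valued
dynamic program needs `2^N − 1` states per node. Both collapse under
symmetry. Conditional on the node's true state, every permutation of the
other `N − 1` states leaves the process invariant, so the reconstructed set
is uniformly distributed *within* the class `(i, c)` — size `i`, flag `c` for
containing the true state. There are `2N − 1` such classes (`(N, 0)` cannot
occur), indexed `(i,1) ↔ 2i−1`, `(i,0) ↔ 2i`. The package propagates, per
node, the vector of total class probabilities, which always sums to 1 — a
running invariant asserted (to 1e−9) at every node, deliberately *not*
repaired by renormalization inside a single tree traversal, so that a kernel
or mixing defect cannot hide.

Two operations drive the recurrence:

* **Branch mixing** re-conditions a child-state-conditioned vector onto the
  parent's true state. With probability `q` the child's true state is the
  parent's; with probability `p` each, it is another state `j`, and by
  within-class uniformity a size-`i` set containing `j` contains the parent
  state with probability `(i−1)/(N−1)`, one avoiding `j` with probability
  `i/(N−1)`. This yields
  `m(i,1) = q·a(i,1) + p[(i−1)a(i,1) + i·a(i,0)]`,
  `m(i,0) = q·a(i,0) + p[(N−i)a(i,1) + (N−1−i)a(i,0)]`,
  which preserves the size marginal — a tested invariant.
* **The combination kernel** applies intersect-else-union to two independent
  class-uniform sets. Writing `i' = i − c`, `j' = j − c'` for the non-true
  parts, their overlap `m` is hypergeometric over the `N − 1` non-true
  states, landing in class `(m + cc', cc')` when nonempty and in the union
  class `(i + j, max(c, c'))` otherwise.

UA and AA read off the root vector as `UA = A[(1,1)]`,
`AA = Σ_k A[(k,1)]/k`. Cost: `O(nodes × N³)`.

The within-class-uniformity argument is the one step that does not verify
itself, which is why the package carries an independent oracle:
`exact_enumeration_accuracy()` enumerates every leaf configuration, computes
its probability by matrix peeling, runs the actual Fitch rule, and
accumulates the definitions literally. The test suite proves recurrence =
enumeration to 1e−10 over every rooted binary shape with ≤ 5 leaves,
N ∈ {2, 3, 4}, 20 random branch assignments each, and backs the enumeration
itself with a cruder sum over all internal labelings on tiny trees. A
vectorized Monte-Carlo estimator (`estimate_accuracy_mc()`) closes the loop
at 3σ on larger random trees.

## Class-vector convention

Class-total probabilities (summing to 1) are used rather than
per-representative-set probabilities; the two differ by the class
cardinalities `C(N−1, i−1)` and `C(N−1, i)`. Totals were chosen because
normalization then is a strong running invariant; the AA formula above
absorbs the conversion. The kernel's hypergeometric terms are built from
binomial coefficients, which are exact integers in double precision up to
`C(49, 24) ≈ 6×10¹³ < 2⁵³`, so every kernel entry is correct to one rounding
(rows sum to 1 within 1e−12); N is capped at 50 accordingly.

## Extremal shapes and asymptotics

**Equal-branch complete binary trees.** Both root subtrees of the `2^n`-leaf
tree are the `2^{n−1}`-leaf tree, so one *level map* (mix, then self-combine)
iterated `n` times from the leaf vector gives the exact root vector. There is
an equilibrium interval `[a, b]` of `q` in which the limiting AA is `1/N` —
Fitch does no better than guessing. `estimate_threshold_b()` locates `b` by
bisecting `q` in `(1/N, 1)` (default width 1e−4), iterating the level map to
two-step stationarity (tolerance 1e−13, cap 10⁴ iterations) and classifying
a candidate as equilibrium when both iteration subsequences end within 1e−5
of `1/N`. The defaults balance critical slowing near `b` against runtime;
they reproduce the reference three-decimal values of `b` to ±0.0005 for
N = 2…25. For N = 2 the map settles into a period-2 cycle below `a = 1/8`
(states alternate level by level), so stationarity is judged on the even and
odd subsequences separately and `a` is located as the boundary where their
limits separate; for N ≥ 3 that regime vanishes and `a = 0`. Note the N = 2
analysis below `q = 1/2` needs `p > 1/N`: mixing and the kernel accept the
full valid transition range `p ≤ 1/(N−1)`, while *tree input* is capped at
the Jukes–Cantor-reachable `p ≤ 1/N` unless explicitly overridden — the cap
exists to catch branch-length-vs-probability confusion, not as a law of the
recurrence.

**Numerical note (the one deliberate renormalization).** The level map is
quadratic in the class vector, so a sum drift of order ε *squares* every
iteration: starting from machine epsilon it reaches order 1 within ~60
iterations and overflows shortly after. Inside fixed-point iteration drivers
(`complete_binary_limit()`, and the long Hennigian path recurrence) the
vector is therefore divided by its computed sum each step. The exact sum is
identically 1, so this removes roundoff only; single tree traversals, where
drift stays additive (~nodes × ε), keep the strict assert-don't-repair
policy.

**Caterpillars.** The equal-branch comb satisfies
`A_n = combine(mix(leaf, p), mix(A_{n−1}, p))` — one kernel application per
added leaf. Its limiting accuracies never beat the nearest root-to-leaf path
(accuracy `q` at one branch) once `q ≥ 1/N`; the path baseline is the
closed form `1/N + ((N−1)/N)(1−Np)^k`. The Hennigian (ultrametric) comb
fixes interior edges at length `l` and stretches the pendant of the `k`-th
interior node to `(n−k)l`, putting all leaves at depth `(n−1)l`; the
bottom-up pass along the interior path costs O(n). Its AA always degenerates
to `1/N`, while UA converges to
`N^{N−2} / Σ_{i=1}^{N} N^{N−i} (N−1)!/(N−i)!`, independent of `λl`. The
package evaluates this through the algebraically identical product
recurrence `t_1 = N`, `t_i = t_{i−1}(N−i+1)/N`, `UA = 1/Σt_i`, which neither
overflows nor cancels at N = 50. The tests confirm the finite-`n` recurrence
approaches this limit to better than 0.002 by n = 2000 for every
`λl ∈ {0.05, 0.1, 0.3}` tried — and already to 0.002 by n = 400.

## The synthetic-data machinery

Experiments need no external data. `generate_yule()` grows a topology by
splitting a uniformly chosen current leaf until the target leaf count — the
pure-birth topology distribution. Following the published experimental
design, branch *probabilities* are then assigned as one common conservation
probability per sweep point rather than from birth-process waiting times
(`set_branch_probabilities()`); exponential waiting times plus a clock rate
would be the alternative, out of scope here. The character simulator draws
substitutions as a uniform offset among the `N − 1` alternatives — exactly
the symmetric model the recurrence assumes. What passing Yule tests show is
therefore internal consistency and the qualitative equilibrium behavior on
random balanced-ish topologies; they say nothing about rate heterogeneity,
asymmetric substitution, or model misspecification on real data, none of
which the model covers.

Default experiment sizes were chosen to exhibit the asymptotics cleanly at
interactive runtimes: combs and Hennigian paths at n = 2000 leaves (their
accuracies move by < 1e−4 on doubling n), level maps to stationarity with
the 10⁴-iteration cap, the Yule sweep at 50 trees × 1024 leaves — the
published leaf count, with the tree count scaled down — where the median AA
inside the equilibrium range sits within 0.01 of `1/N`. At 256 leaves that
margin would be ~0.03: the offset is a finite-size property of the tree
ensemble, not of the recurrence, which is why the leaf count is not scaled
down.

## Design choices on open points

* **Degree-2 root after subset restriction**: suppressed internal degree-2
  nodes compose their incident branches (`1 − Np` multiplies); a root left
  with one child keeps that single composed branch, and accuracy through it
  is plain branch mixing. Accuracy of a one-leaf "tree" is the conservation
  probability of its branch.
* **Stage-two uniformity at children**: the uniform draw is specified at the
  root; at non-root nodes "any state" is implemented as uniform too. Root
  accuracies never depend on this, but it makes the RNG contract testable.
* **Randomness**: functions use R's global RNG (`set.seed()` upstream), and
  stochastic entry points take an explicit `seed` argument; no global state
  beyond the RNG is touched.
* **Typo-level reconstructions**: the class partition requires the even
  classes to be the sets *not* containing the true state (otherwise it is
  not a partition), and the limiting-UA closed form above is the unique
  variant consistent with both the recurrence limit and the small-N exact
  values `1/3`, `16/142`, `125/1569`.

## Known limitations

Strictly binary rooted trees only; one character at a time (no alignment
batching); symmetric single-parameter model only — no Sankoff weights, no
rate heterogeneity, no asymmetric exchange; enumeration oracle capped at
`N^L ≤ 10⁷`; kernel capped at N ≤ 50 (exactness of double-precision
binomials), Monte-Carlo bitmasks at N ≤ 30. The threshold `b` is an
estimate with the stated bisection/detection tolerances, not an algebraic
number; near `b` convergence of the level map slows critically, and the
10⁴-iteration cap bounds, but does not eliminate, classification error
within ~1e−3 of the boundary.
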