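---
title: "Random-walk influence scoring: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk influence scoring: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkrank)
```

## The model and its assumptions

`walkrank` treats a set of proteins regulating a hub interaction (the
motivating system is the p53–MDM2 axis) as a directed graph and asks how
much of each protein's individual effect on the hub survives once the
network's internal interactions are accounted for. The device is a random
walk with restart. Two artificial nodes are added to the protein network:
an initial node S with edges to and from every protein (the restart,
standing in for influence arriving from proteins outside the modelled
network) and a transition node T that receives an edge from every protein
and sends a single edge back to S (the walk leaving the network). S is
deliberately *not* linked to T: a restart always lands on a real protein.
That choice is forced by the walk's semantics — a walker stepping S → T
would model external influence that bypasses the network entirely — and it
is what makes the worked three-node example come out at
`P = (1, 1/3, 1/3, 4/9, 1/2)`.

The walker moves along out-edges with equal probabilities, so the chain's
transition matrix is `M[i, j] = 1/outdeg(i)` on the support of the
augmented graph, over the fixed ordering `[S, proteins in input order, T]`.
Augmentation guarantees the two convergence conditions of a Markov chain:

* **irreducibility** — any protein reaches any other through S, so the
  augmented graph is strongly connected;
* **aperiodicity** — every node A sits on the cycle A → T → S → A of
  length 3, and every protein edge A → B closes A → B → T → S → A of
  length 4; gcd(3, 4) = 1.

The stationary distribution P solves `P M = P`. Dropping the S and T
entries and dividing by their sum N yields the influence vector X, whose
entries sum to 1 and are reported as percentages against the uniform
baseline 1/n. Two consequences worth knowing: X is invariant to the
scaling of P (the normalization divides it out), and proteins with no
incoming protein edges all receive identical scores, since their only
inflow is the uniform restart from S.

The model's assumptions are blunt and should be kept in mind: edges are
unweighted and untyped (activation and inhibition count the same), the
walk is uniform over out-edges, and edge direction is taken exactly as
given in the input.

## Solvers and numerical choices

The default solver (`stationary_direct()`) computes the eigenvector of
`t(M)` at eigenvalue 1 with base R's `eigen()`. The eigenvalue is accepted
within `1e-6` of 1 and must be simple; a multiple eigenvalue signals a
non-ergodic or numerically degenerate chain and is an error rather than a
silent pick. Eigenvectors are sign-ambiguous, so the vector is flipped to
the nonnegative orientation (possible by Perron–Frobenius for an ergodic
chain) and entries below zero by rounding noise are clamped. Each returned
distribution records the residual `max |P M − P|` of its sum-one form;
every path through the package keeps this below `1e-8`, and in practice it
sits at machine precision.

`stationary_power()` is the independent cross-check: it iterates
`P_{t+1} = P_t M` from the uniform distribution until the max-norm change
drops below `tol` (default `1e-12`, capped at `1e6` iterations). The limit
of an ergodic chain does not depend on the start, which the tests assert
by running several starting distributions. One subtlety: on a periodic
chain the uniform distribution can *be* the oscillation's fixed point — on
a pure 2-cycle the iteration from uniform converges immediately even
though the chain has no limit. Periodicity detection by non-convergence
therefore needs an asymmetric start; the ergodicity check, not the solver,
is the authoritative guard.

Ergodicity is verified explicitly (`check_ergodicity()`): strong
connectivity via igraph's strongly-connected components, and the period by
the BFS-level method — label nodes with breadth-first levels from any
root and take the gcd over edges u → v of `level(u) + 1 − level(v)`. A
brute-force enumerator of cycle lengths through matrix powers serves as
the small-instance oracle in the test suite; the two agree on every
strongly connected random graph tried.

Three scaling conventions are exposed because published stationary vectors
come in different normalizations: `sum-one` (canonical probabilities, the
internal form), `unit-euclidean` (unit 2-norm), and `initial-node-one`
(S entry equal to 1). All are rescalings of the same solution.

Matrices transcribed from print carry rounding: at 4 decimals per entry a
row of nine entries can miss a sum of 1 by several times `1e-4`.
`load_transition()` therefore renormalizes rows whose sums lie within
`1e-3` of 1 and refuses anything worse — a zero row, a negative entry, or
a genuinely non-stochastic row is not repairable rounding. Comparisons
against vectors printed to 4 decimals use an absolute tolerance of `5e-4`
per entry for the same reason.

Ranking ties are broken stably by input order. Because eigen-solvers
return exactly-tied entries with ~`1e-16` noise, ranking compares scores
at 12 significant digits; below that resolution two proteins are treated
as tied and keep their input order.

## The packaged nine-protein matrix

The 11 × 11 transition matrix of the nine-protein p53–MDM2 regulator
network ships as `inst/extdata/p53_regulators_matrix.csv`. Its published
rendering is laid out column-major — the columns, not the rows, of the
printed array sum to 1, and the first printed line holds the inflow
probabilities into S (the proteins' reciprocal out-degrees plus 1.0 from
T) — so the fixture stores the transpose, with rows as from-nodes. The
transcription was validated before freezing by reproducing the published
unit-Euclidean stationary vector and normalized influence vector to within
`5e-5` per entry, an order of magnitude inside the rounding band. Only the
fifth protein position is identified (HDAC1, pinned by its published
15.25% score); the remaining positions carry placeholder labels P1–P4 and
P6–P9 because the published text never states the row order of the other
eight proteins. The nine protein names are shipped alongside in their
published table order, which is not asserted to be the matrix order.

## The synthetic network generator

`random_network(n, edge_prob, seed)` draws a directed Erdős–Rényi graph:
every ordered pair of distinct nodes becomes an edge independently with
probability `edge_prob`. It is the input generator for the property-style
tests, which run it at `n ≤ 20` and edge probabilities spread over
0.1–0.85 — the regime of the method's intended use (small curated
regulator networks) and the scale at which the brute-force oracles stay
exact. Property tests assert, across 200 such networks, that augmentation
always yields an ergodic chain, that the direct and power solvers agree to
`1e-8`, and that S carries exactly twice the stationary mass of T (S and T
receive identical inflow from the proteins, and S additionally receives
all of T's mass).

Erdős–Rényi graphs do not emulate the degree heterogeneity, hubbiness, or
motif structure of real interaction networks, nor edge signs or
confidence weights. Passing these tests therefore demonstrates the
*mathematical* correctness of the pipeline on arbitrary topologies, not
that the model captures the biology of any particular network; biological
validity rests on the curated input network itself.

## The Monte Carlo simulator

`simulate_walk()` runs the walker literally — seeded, starting at S,
uniform over out-neighbors — and is the implementation-independent oracle
for the analytic solvers. The start at S is counted as a visit, so counts
sum to `steps + 1` (the standard occupancy estimator); no burn-in is
discarded by default because these chains mix in a handful of steps, but a
`burn_in` option exists. Empirical frequencies are compared to the
analytic distribution with a per-node tolerance of
`4 * sqrt(p (1 − p) / steps)`: binomial-CLT scale, with the factor 4
absorbing the inflation from the walk's serial dependence. At 10^6 steps
the toy network's total-variation distance from the analytic solution is
below 0.01, and across the toy plus ten random networks at least 95% of
node-level deviations fall within the bound. The validation suite runs
the million-step walks in about five seconds total.

## The two-stage group-then-rescore procedure

For networks too large to score whole, `hierarchical_score()` implements
the group-then-rescore idea: proteins are grouped by functional
similarity (the grouping is user input — the package deliberately ships
none for the nine-protein network, as no published grouping exists), each
group's induced subnetwork is scored independently with its own S and T,
the top `k` proteins per group are pooled, and their joint subnetwork —
with edges induced from the *original* network, the only defensible
source since stage 1 discards cross-group edges — is scored again. `k`
has no default: how many proteins to carry per group is a modelling
decision, not a numeric one. Degenerate groupings reduce exactly to plain
scoring (one group containing everything, or singleton groups with
`k = 1`), which the tests use as oracles alongside a fully manual
composition of the two stages.

## Known limitations

* Unweighted, untyped edges; no activation/inhibition semantics.
* The hub proteins themselves (p53, MDM2) are not nodes; the method
  scores regulators' shares, not the hub's state.
* Stationary probabilities measure topological exposure of the walk, not
  causal effect sizes.
* A monotonicity intuition — adding an incoming edge should not lower the
  target's score — holds empirically on the randomized suite but is not a
  theorem and is probed, not asserted.
* For protein networks literally containing proteins named "S" or "T",
  the artificial labels must be renamed via the `reserved` argument.
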