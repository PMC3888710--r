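# walkrank

Random-walk influence scoring for protein regulatory networks.

## The problem

Hub interactions such as p53–MDM2 are regulated by many proteins at once.
Each regulator's effect has usually been measured as an isolated molecular
event, but the regulators also interact with *each other*, so the effective
contribution of any one protein depends on the whole network. `walkrank`
quantifies that compound effect: given a directed graph whose nodes are
proteins and whose edges are protein–protein interactions, it assigns each
protein the long-run fraction of a random walker's visits — a stationary
probability — and reads it as the percentage of that protein's individual
interaction with the hub that is effective within the network. It is aimed
at systems biologists who have a small-to-moderate interaction network and
want a principled, fully deterministic ranking of its members.

## The model

The input network G is augmented with two artificial nodes:

* an **initial node S** with a directed edge *to* every protein and *from*
  every protein — the walk's restart, modelling influence entering the
  network from external proteins (S has no edge to T);
* a **transition node T** with a directed edge *from* every protein and a
  single edge *to* S — the walk exiting to external proteins.

A walker starts at S and at each step moves to a uniformly chosen
out-neighbor, giving the row-stochastic transition matrix
`M[i, j] = 1/outdeg(i)` over the ordering `[S, proteins, T]`. Augmentation
makes the chain ergodic: the graph is strongly connected via S, and the
cycles `A → T → S → A` (length 3) and `A → B → T → S → A` (length 4)
force the gcd of cycle lengths to 1. The stationary distribution *P* is
the unique solution of `P M = P`, computed directly as the eigenvector of
`t(M)` at eigenvalue 1 (power iteration is available as an independent
cross-check). Dropping the S and T entries and renormalizing,

    X = (p_2, ..., p_{n-1}) / N,   N = sum of the protein entries,

gives the influence scores, which sum to 1 and are compared against the
uniform baseline 1/n. A useful structural identity — tested on hundreds of
random networks — is that S always carries exactly twice the stationary
mass of T.

## Worked example

The packaged toy network has three proteins A, B, C and a single
interaction B → C:

```r
library(walkrank)
cmd_score(run_config(
  input = system.file("extdata", "toy_network.tsv", package = "walkrank"),
  nodes = system.file("extdata", "toy_network_nodes.txt", package = "walkrank")))
```

```
ergodicity check: strongly connected: yes; period: 1; ergodic: yes
stationary solve: direct, residual 1.67e-16
influence scores for 3 protein(s) (baseline 33.33%)
  A           30.00%  (0.3000)
  B           30.00%  (0.3000)
  C           40.00%  (0.4000)
```

30% of the individual hub interactions of A and of B are effective within
the network, and 40% of C's: C is the only protein receiving a
protein-level edge, so the network amplifies it above the 1/3 baseline,
while A and B — which have no interaction with each other — land on
identical scores. The stationary vector behind these numbers, scaled so
the S entry is 1, is `(1, 1/3, 1/3, 4/9, 1/2)`.

The packaged 11 × 11 matrix of the nine-protein p53–MDM2 regulator
network scores the same way (only the fifth protein position is
identified, as HDAC1; see `inst/extdata/p53_regulators_matrix_PROVENANCE.txt`):

```r
cmd_score(run_config(
  input = system.file("extdata", "p53_regulators_matrix.csv", package = "walkrank"),
  input_type = "matrix"))
```

```
influence scores for 9 protein(s) (baseline 11.11%)
  P1          11.63%  (0.1163)
  P2           7.84%  (0.0784)
  P3           8.20%  (0.0820)
  P4          16.19%  (0.1619)
  HDAC1       15.25%  (0.1525)
  P6           8.04%  (0.0804)
  P7           6.50%  (0.0650)
  P8          13.03%  (0.1303)
  P9          13.33%  (0.1333)
```

HDAC1's 15.25% against the uniform 11.1% baseline singles it out as a
disproportionately influential regulator of p53 stability.

A shell front end wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "walkrank.R", package = "walkrank"))') \
    score --edges inst/extdata/toy_network.tsv --nodes inst/extdata/toy_network_nodes.txt
```

with subcommands `score`, `check`, `simulate`, `random`, and
`hierarchical` (the two-stage group-then-rescore procedure for large
networks).

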