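---
title: "Structure predictability from lossless network compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure predictability from lossless network compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpred)
```

## The problem

Link prediction asks: given an observed network, which unobserved pairs of
nodes are most likely to be (missing) links?  Decades of algorithm
development notwithstanding, there has been little guidance on the
*absolute* ceiling — how predictable a given network's structure actually
is, independent of any particular algorithm.  `netpred` implements a
framework in which that ceiling is read off the network's **shortest
lossless compression length**: a structure that compresses well is simple,
hence predictable; one that resists compression is close to random, hence
unpredictable.

Two quantities carry the framework:

* **L\***, the normalized compression length.  A two-stage label-free
  compressor encodes the graph up to isomorphism and the bit length
  \(L\) is divided by the ceiling
  \(\mathcal{R} = \binom{N}{2} h(q) - N \log_2 N\)
  (the structural entropy of an Erdős–Rényi graph with the same \(N\) and
  \(E\); \(h\) is the binary entropy, \(q = E/\binom{N}{2}\)).
* **H\***, the normalized rank entropy of link prediction.  For every
  edge in turn, remove it, score all unlinked pairs, and record the
  descending-score rank \(r_i\) of the removed edge among the
  \(M = \binom{N}{2} - E + 1\) candidates (leave-one-out).  The ranks are
  binned with width \(N\) (about \(N/2\) bins), and
  \(H = -\sum_j p_j \log_2 p_j\) is normalized by \(\log_2 N - 1\), the
  rank entropy of an ER graph.  Minimizing \(H\) over a suite of
  algorithms gives the best-performing-algorithm estimate (BPAA) of the
  theoretical optimum (TBPA).

Across empirical networks the two obey a linear law
\(H^* \approx 1.63\,L^* - 0.63\) (through the ER point \((1,1)\)), and for
edge-independent random graphs the analogous line can be derived exactly
(`theory_line()`, three nested approximations).  The law converts a
compressed file size into an entropy budget, and entropy-constrained
optimization converts that budget into hard bounds on top-\(C\) prediction
precision (`upper_pc()`, `lower_pc()`) and into a conservative dataset
value \(V = \Theta\,2^{-(1.63 L/\mathcal{R} - 0.63)(\log_2 N - 1)}\).

## The compressor

`encode_structure()` follows the partition-refinement scheme for
label-free graph compression.  Vertices are processed one at a time while
the unprocessed vertices are kept in an ordered partition of cells; all
members of a cell have identical adjacency to the processed set, so the
encoder only needs to transmit, per cell, *how many* members are
neighbours of the current vertex (one bit for singleton cells, stream B1;
a count for larger cells, stream B2).  Cells then split into
neighbour/non-neighbour sub-cells.  Because members of a cell are
interchangeable, the decoder may pick any subset of the stated size and
still reconstruct a graph isomorphic to the original — this is where the
\(N \log_2 N\) label savings come from.

The second stage is an adaptive arithmetic coder.  Counts are coded with
an exchangeable Pólya (adaptive binomial) model whose link-rate estimate
is *contexted* on the number of processed vertices adjacent to both the
current vertex and the cell — a common-neighbour context.  On an ER graph
the context carries no information and the coder converges to the optimal
\(\binom{N}{2} h(q) - \Sigma \log_2 \binom{s}{c}\) rate; on graphs with
transitivity or degree structure (ring lattices, Chung–Lu graphs) the
context concentrates the predictive distribution and the length drops well
below \(\mathcal{R}\).  A ring lattice compresses to
\(L^* \approx 0.08\); an ER graph sits at \(L^* \approx 1.05\).

Why 1.05 and not 1.00?  The ceiling uses the paper-convention label term
\(N \log_2 N\), but the most any label-free code can save is
\(\log_2 N! = N\log_2 N - N\log_2 e + O(\log N)\).  The difference,
\(N \log_2 e\) bits (~721 bits at \(N = 500\), ~4.5% of \(\mathcal{R}\)),
is a once-per-file offset that every real coder pays.  It sits well inside
the \([0.9, 1.1]\) calibration band used by the tests and shrinks with
density and size.

Tunable knobs: `runs` (default 50) controls how many seeded traversal
orders are averaged — the spread across runs is reported and is small
(well under 1%); `order_policy` (`random`, `high_degree_first`,
`low_degree_first`) changes the traversal start order and moves \(L\) by
under 2%.

### Why additivity misses 5% at N = 300

For two independent edge-disjoint graphs A and B on the same nodes the
framework expects \(L_{A+B} \approx L_A + L_B\).  The identity is
asymptotic.  Two finite-size terms spoil it at desk scale: the
\(\log_2 N!\) label savings enters once per compressed file (twice in
\(L_A + L_B\), once in \(L_{A+B}\)), ~3% of \(L_{A+B}\) at \(N = 300\),
and the binary-entropy subadditivity
\(\sum h(q_A) + \sum h(q_B) - \sum h(q_{A\cup B})\) contributes ~4.4% at
\(\langle k\rangle = 10\).  An *ideal* coder would therefore show a ~7.6%
discrepancy; ours measures ~6%.  The 5% acceptance tolerance is kept as
stated and that test is expected to fail at this size — the numbers above
are the analysis of why, and the discrepancy shrinks steadily with
network size (the regime of the original experiments, which used networks
one to two orders of magnitude larger).

## Tie handling in leave-one-out ranks

Neighbourhood scores are massively tied on sparse graphs (most candidate
pairs share no neighbour and score 0).  A deterministic mid-rank
convention would place every member of a tie block in the same width-\(N\)
bin, collapsing the rank distribution of an ER graph to near-zero entropy
— contradicting the ER baseline \(\log_2 N - 1\) that anchors all the
normalizations.  The package therefore resolves ties by a *seeded
uniform-random order within the tie block* by default, which makes the ER
rank distribution uniform as required; `ties = "midrank"` implements the
deterministic convention \(r = \#\{\text{higher}\} + (\#\{\text{tied}\}+1)/2\)
for reproducible single-rank arithmetic.  The same convention applies when
ranking Q-matrix probabilities in `h_tbpa_numeric()`.

## The synthetic world

All tests run on networks generated in-package:

* `er_graph(n, e, seed)` — fixed-edge-count G(N, M), matching the "same
  number of nodes and links" normalization.
* `chung_lu_graph(degrees, seed)` / `chung_lu_q_matrix(degrees)` — the
  edge-independent model \(q_{ij} = \min(1, k_i k_j / \Sigma k)\).
  `powerlaw_degrees(n, k, gamma = 2.5)` builds a deterministic
  power-law-ish sequence (quantile construction, capped at
  \(\sqrt{2E}\), even sum); \(\gamma = 2.5\) is a conventional
  heavy-tailed exponent and was fixed before any calibration.
* `circle_model(n, k_c)` — the ring lattice that injects regular,
  trivially compressible structure.
* `shuffle_links()`, `perturb_links()`, `combine_graphs()` — the
  perturbations under which the law is invariant (and with which it is
  stress-tested).

What a green test does establish: calibration on ER, monotone degradation
of both axes under shuffling, the exact theoretical line for Q-ensembles,
oracle-verified precision bounds.  What it does not: the 1.63 slope
itself, which is an empirical fit across twelve real networks and is not
reproducible from synthetic data; synthetic Q-ensembles follow the flatter
finite-size theory line (slope ~0.6–0.7), as the original analysis itself
points out.  For that reason the entropy-constrained bounds are validated
on synthetic graphs through each ensemble's *own* (re-fitted) line — the
law constants are exposed via `options(netpred.law = )` precisely to
support re-fitted laws — and additionally through the distribution-free
form at the measured BPAA entropy.

## Numerical choices

* Bin count is \(\lceil M/N \rceil\) with the final partial bin kept, so
  the binned distribution always sums to one; entropies use observed
  proportions, no smoothing.
* `h_tbpa_numeric()` averages the binned rank distribution across sampled
  graphs and then takes the entropy (the per-draw entropy average is
  biased low by about \((B-1)/(2E\ln 2)\) bits and is reported alongside).
* Bound solvers bisect on brackets where the constraint is monotone
  (tolerance 1e-10, max 200 iterations, diagnostics returned).  The
  lower \(P_C\) bound is a direct constrained search: a candidate \(P\)
  is feasible iff the minimum entropy attainable with top-\(C\) mass
  \(P\) (top block plus tail capped at \(p_C\), optimized over the cap)
  does not exceed the target; the smallest feasible \(P\) is bisected,
  and the result is cross-checked against an independent optimizer in the
  tests.  At \(C = 1\) and dyadic targets it reduces to \(2^{-H}\)
  exactly.
* `target_entropy()` clamps negative values (very compressible networks,
  outside the law's fitted range) to zero with a warning; consequently
  the dataset value never exceeds \(\Theta\).
* Degenerate eigenvalues in the structural perturbation method are
  handled as blocks (relative gap < 1e-10) by re-diagonalizing the
  perturbation inside the degenerate eigenspace.

## Worked example

```{r example}
set.seed(1)
g <- chung_lu_graph(powerlaw_degrees(300, 10), seed = 7)
g

cr <- compression_length(g, runs = 20, seed = 1)
cr

est <- bpaa(g, algorithms = c("cn", "ra", "jaccard"), seed = 1)
est

line_gap(cr$L_star, est$H_star)
```

The gap of the BPAA point from the empirical law line quantifies how much
room is left for better algorithms on this network; the same machinery
turns `cr$L` into precision bounds and a dataset value:

```{r bounds}
h <- min(target_entropy(cr$L_star, g$n), log2(g$n / 2))
upper_p1(h, g$n)
lower_p1(h)
commercial_value(cr$L, g$n, edge_count(g), theta = 1000)
```

## Known limitations

* The validity band \(\ln N \ll \langle k \rangle \ll N - \ln N\) is
  enforced only as a warning (`check_validity_band()`); outside it the
  ceiling degenerates and normalization fails by design.
* The spectral indices (katz, act, lrw, spm) recompute dense
  decompositions per removed edge, an \(O(N^3 E)\) leave-one-out; they
  are meant for networks up to a few hundred nodes.  The six
  neighbourhood indices share a bitset C++ sweep and handle thousands of
  nodes.
* Exact isomorphism of decode–encode round-trips is verified at small
  \(N\); at larger sizes the tests check the invariants (N, E, degree
  multiset) that the partition argument guarantees.
* Directed, weighted, bipartite and temporal graphs are out of scope.
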