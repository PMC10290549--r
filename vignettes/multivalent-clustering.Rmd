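---
title: "Simulating and characterizing multivalent molecular clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and characterizing multivalent molecular clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfcluster)
```

## The modeling problem

Multivalent biomolecules bind each other through specific site–site
interactions. When each molecule carries several sites, a handful of
binding rules generates a combinatorial explosion of possible complexes:
a pre-enumerated reaction network is infeasible, but an *agent-based*
(network-free) simulation that tracks individual molecules and individual
bonds is not. `nfcluster` implements that simulation for a deliberately
restricted rule language, and the statistical machinery needed to
characterize what many stochastic trials produce: distributions of cluster
size, composition, bonding, and saturation.

The restricted dialect covers exactly what this analysis needs and no
more: molecule types are bags of named sites without internal states or
compartments; rules are reversible bimolecular site–site bindings; seeds
are fully unbound monomers. Synthesis, degradation, state flips, and
functional rate laws are rejected at parse time rather than silently
ignored, so a model file means what it says.

## The stochastic process

The simulator is an exact stochastic simulation algorithm (Gillespie
direct method) over two event channels per rule.

**Binding.** A rule `A(a) + B(b)` with stochastic on-rate `kon` (per
site-pair per time unit) fires with propensity `kon * P`, where `P` counts
the free (a, b) site pairs lying in *distinct* clusters:

$$P \;=\; T_a T_b \;-\; \sum_{c} a_c b_c,$$

with $T_a, T_b$ the total free-site counts and $a_c, b_c$ the free-site
counts inside cluster $c$. For a symmetric rule (both endpoints the same
site of the same type) unordered pairs are counted instead:
$P = \binom{T}{2} - \sum_c \binom{t_c}{2}$. The executed event picks a
uniformly random eligible pair and merges the two clusters with a new
bond.

**Dissociation.** Each rule's off-rate `koff` (per bond per time unit)
multiplies its current bond count; the event removes a uniformly chosen
bond of that rule.

Two modeling assumptions follow the default semantics of network-free
simulation of bimolecular rules:

* **No ring closure.** Binding acts only *between* clusters, never within
  one. Every cluster is therefore a tree (`bonds = size - 1`), and a
  dissociation always splits its cluster in two. Cyclic complexes are
  still accepted on the *read* side (`parse_complex`), since externally
  produced species files may contain them; their summaries are flagged
  `is_tree = FALSE`.
* **Context-free rates.** All site pairs matching one rule share the same
  `kon`/`koff`, regardless of what else is bound to either molecule
  (no cooperativity or allostery).

Rates are stochastic, copy-number based constants; no molar/volume
conversion is performed. Users coming from concentration units should
convert once when writing the model file.

### Bookkeeping and complexity

Per-cluster free-site tallies and the per-rule sums $\sum_c a_c b_c$ are
maintained incrementally, so propensities cost O(#rules) per event rather
than a scan over clusters. Pair selection uses two-stage rejection
sampling (draw a free site per endpoint, reject intra-cluster draws),
which is uniform over eligible pairs; after 100 rejections — possible only
near complete gelation, when one cluster holds most free sites — the
sampler falls back to an exact weighted draw. Dissociations locate the
smaller fragment by breadth-first search and rebuild only its tally row.

### Sampling and seeding conventions

* Observables are recorded at the `n_steps + 1` evenly spaced times of
  `[0, t_end]` as the state *as of* that time (left-continuous sampling of
  the jump process), with `t = 0` always included.
* A trial with zero total propensity (no rules, zero copies, all sites
  bound with `koff = 0`) fast-forwards to `t_end` with flat observables
  rather than erroring.
* Trial `i` of an ensemble uses `trial_seed(master, i)` — the master seed
  XORed with a multiplicative hash of `i`, kept below 2^31 — so ensembles
  are bit-reproducible, order-independent, and trials share no state.

The test suite verifies the incremental bookkeeping against full-state
rescans (`run_trial(audit = TRUE)`), and verifies distributional
exactness on the smallest nontrivial system: 2 A + 2 B dimerization at
`kon = koff`, whose bond count is a three-state birth–death chain with
up-rate `kon (2-b)^2` and down-rate `koff b`, hence stationary law
$\pi \propto (1, 4, 2)$. A chi-square test at $\alpha = 0.01$ on $10^4$
sampled states (spaced 2 time units apart, far beyond the chain's O(1)
relaxation time) checks the simulator against this closed form.

## The statistics

Final clusters from all trials are **pooled** into one combined dataset —
the primary analysis mode; per-trial statistics can be had by pooling a
single trial. Clusters read from species files are weighted by their
counts (entries are expanded at pooling time).

* `occupancy_distribution`: fraction of all molecules in clusters of size
  *s* is $s\,n_s / N$; its mean is the average cluster occupancy (ACO).
  Pooled ACO equals the molecule-weighted mean of per-trial ACOs (an
  algebraic identity that is tested, not assumed).
* `bin_distribution`: sums occupancy fractions over integer size ranges.
  Default breaks are monomer-resolved to size 10, then 1–2–5
  logarithmic steps, with a final open bin.
* `bond_histogram`: node-degree distribution over all molecules or one
  type; for a tree cluster of size *n* the mean degree is exactly
  `2(n-1)/n`.
* `bf_matrix`: per-cluster bound fraction (`2 * bonds / total sites`)
  histogrammed against size. Normalization is *within each size column* —
  the conditional distribution of saturation given size — because raw
  joint frequencies would make the sparse large-size columns unreadable.
  The bound fraction exists in two forms: per cluster (used here) and per
  molecule (`molecule_bound_fraction`, occupied sites over valence).
* `composition_table`: per size (or size bin), the fraction of member
  molecules of each type; columns sum to 1.
* `timecourse_stats`: pointwise mean and *sample* (n − 1) standard
  deviation across trials; the divisor is a convention choice, and a
  single trial reports zero standard deviation by the same convention.

All statistics are cross-checked in the tests against naive brute-force
enumeration on fixtures of ≤ 20 clusters.

### Canonical complex strings

Species files identify complexes by BNGL strings, and duplicate
aggregation relies on string equality. Exact graph-isomorphism
deduplication is NP-hard in general, but the simulator only produces
trees, and trees admit a true canonical form: `emit_complex` roots each
tree at its center (ties between the two centers broken by comparing an
AHU-style subtree encoding extended with each edge's site pair), orders
children by their encodings, and renumbers bond labels in depth-first
preorder. Isomorphic trees therefore emit identical strings — verified in
the tests by exhausting node permutations on small clusters. Cyclic
read-side clusters are emitted deterministically from stored node order
and deduplicate only up to exact string equality.

## The synthetic-cluster generator

`generate_synthetic_clusters` grows random rule-respecting trees of
prescribed sizes, for testing the statistics without a simulation. It
emulates the *structural* properties of simulated clusters — tree
topology, declared valences, rule-compatible edges — but **not** their
statistical law: real final clusters have size- and composition-dependent
frequencies determined by the kinetics, while the generator draws
attachment points uniformly. Tests built on it therefore validate
bookkeeping and statistical arithmetic, not kinetic realism; the
simulator-level tests (stationary law, absorbing states, conservation)
carry that burden.

## The packaged example and its parameters

The example system is a mixed-valence scaffold network: Nephrin (sites
`y1`–`y3`), Nck (`sh2`, `sh3a`–`sh3c`), NWASP (`p1`–`p6`), with every
pY–SH2 and SH3–PRM site combination a separate rule sharing class-wise
rates (21 rules). The copy numbers 180/540/270 (≈ 990 molecules) were
chosen once to be site-stoichiometric — 540 phosphotyrosines against 540
SH2 domains, 1620 SH3 domains against 1620 PRMs — so neither interaction
class is starved. The affinity presets are placed far on either side of
the clustering threshold:

| preset | kon | koff | regime |
|---|---|---|---|
| `"low"` | 1e-5 | 1 | dispersed: expected bonds per site-pair class ≪ 1, monomer-dominated unimodal occupancy |
| `"high"` | 0.1 | 0.01 | clustered: near-saturated bonding, one supply-limited giant cluster per trial |

Defaults `t_end = 10`, `n_steps = 20`, `n_runs = 10` let both regimes
equilibrate their qualitative structure: at high affinity the initial
binding propensity (~10^5 events per time unit) collapses the pool within
the first time unit, and at low affinity binding and unbinding balance at
a few dozen bonds well before `t_end`. Ten trials of 990 molecules run in
well under a minute and are the problem size used throughout the examples
and acceptance checks.

## Degenerate inputs and numerical choices

* Models with no rules or zero copies simulate to `t_end` with flat
  observables.
* Sum-to-one invariants (occupancy, composition columns, BF columns) are
  exact rational arithmetic on counts; tests use a 1e-9 tolerance only to
  absorb floating-point division.
* `findInterval` on bin lower bounds makes size bins right-open integer
  ranges; the bound-fraction bin for BF = 1 is folded into the top bin.
* All tally arithmetic stays in integer-valued doubles (exact below
  2^53), so incremental propensities never drift; the audit mode asserts
  this.

## Known limitations

* No spatial resolution: steric, crowding, and geometric effects that
  spatial simulators address are out of scope, as are rates conditioned
  on the binding status of other sites.
* No ring closure means no intra-cluster saturation: per-cluster bound
  fraction of a tree of size *n* is bounded by `2(n-1)/total sites`, so
  fully saturated large clusters are unreachable by construction.
* Symmetric self-binding rules use the unordered-pair convention above;
  parity with other engines' statistical factors for such rules is not
  claimed.
* The canonicalizer guarantees deduplication only for trees (plus exact
  string matches otherwise).
* Performance targets desk-scale studies (10^3–10^4 molecules, 10^5–10^6
  events); it is pure R and makes no claim at 10^5+ molecules.
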