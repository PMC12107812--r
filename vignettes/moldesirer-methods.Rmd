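---
title: "Methods: desirability-driven evolutionary molecular design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desirability-driven evolutionary molecular design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `moldesirer`, its
assumptions, the tunable parameters, and the numerical and design
choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The optimization model

A candidate molecule (an `Individual`) is identified by its canonical
SMILES; two individuals are the same molecule exactly when those
strings are equal. Its fitness is a scalar cost, lower is better,
`Inf` meaning unevaluated or failed.

The built-in `cost` fitness maps three property axes through
Derringer–Suich desirability transforms and aggregates them with a
weighted geometric mean `D`; the cost is `1 - D`:

* binding score (kcal/mol-like axis, served by a scoring backend):
  smaller-the-best with target `t = -10` and upper limit `u = -2` —
  scores weaker than −2 kcal/mol are worthless (d = 0), −10 or better
  fully satisfactory (d = 1), linear in between (`r = 1`);
* drug-likeness `qed`: larger-the-best with `l = 0.1`, `t = 0.75`;
* synthetic accessibility `sa_score`: smaller-the-best with `t = 3`,
  `u = 7`.

All weights default to 1. The geometric mean is *annihilating*: one
fully unacceptable property (d = 0 with positive weight) zeroes `D`
regardless of the others, which is the main reason to prefer it over an
arithmetic mean for multi-constraint design. A zero-weight factor is
ignored entirely, even at d = 0 (the weighted-mean semantics of "this
property does not participate"). Knot points evaluate on the
closed-interval branch, so `d(l) = 0` and `d(t) = 1` exactly.

`cost_only_score` uses the raw backend score as the cost;
`cost_multi_receptor` adds one score desirability per receptor, with
anti-targets ("maximize") mapped through the mirrored larger-the-best
ramp built from the same knots (`l = t_score`, `t = u_score`). The
selectivity literature motivates the goal without fixing a formula, so
this mirror construction is this package's choice and the per-receptor
weights are exposed (`vina_score_1`, `vina_score_2`, ...). Note that
*duplicating* a receptor is not a no-op for a weighted geometric mean
unless the duplicated receptor's weight is split — the exact
equivalences (single-receptor reduction; split-weight duplication) are
asserted in the test suite.

## Selection, offspring and elitism

Parents are drawn with replacement from the Boltzmann distribution
`P_i = exp(-beta * cost_i) / sum_j exp(-beta * cost_j)`. `beta = 0` is
uniform (pure exploration); large `beta` is greedy. The implementation
subtracts the minimum cost before exponentiation — mathematically
identical (the distribution is shift-invariant) and numerically safe
for large `beta`. Members with infinite cost get probability zero; if
every member is infinite, selection raises an error rather than
guessing.

Each generation requests `max(1, round(pc * popsize))` children
(`pc = 0.5`, `popsize` 20–100 are typical operating points; the count
formula itself is this package's choice since only `pc` is named by the
method description). Each drawn parent contributes one child sampled
uniformly from its mutation set. A campaign-wide `seenSmiles` registry
records every child ever sampled, accepted or not, and children already
seen (or already in the population) are discarded with bounded retries
(4× the requested count). This makes "molecules generated and
evaluated" well-defined and guarantees no structure is ever evaluated
twice; the acceptance rate of a generation is accepted/generated.

The merged parent+offspring pool is sorted by cost — ties broken toward
the older individual (lower identifier), for stability — and truncated
to `popsize`. Elitism follows: the sorted cost vector of generation
g+1 is pointwise ≤ that of generation g, and the best-so-far cost never
increases across any number of `runGA()` calls.

Reproducibility: one master seed lives in the state; the RNG is
re-seeded deterministically from (master seed, generation number) at
the top of every generation. Evaluation is the only parallel section
and consumes no randomness, so results are independent of `njobs`, and
a checkpointed 5+5-generation run reproduces a straight 10-generation
run exactly (asserted in the suite).

## The mutation operator

The built-in mutator is a fragment-table generator. A *site* is either
a hydrogen position (size 0) or a connected heavy-atom fragment of size
`minSize..maxSize` that attaches to the rest of the molecule through
exactly one bond — the single-attachment restriction makes replacement
by a single-attachment-point fragment well-defined and keeps the
remainder connected. A replacement is feasible when the heavy-atom
increment (fragment size − site size) lies in `[minInc, maxInc]`. New
bonds are single bonds; children must pass a valence check (allowed
valences per element, charge-adjusted) and canonicalization, and are
deduplicated by canonical SMILES. Protected atoms are never part of a
removed site; growing at a protected atom's hydrogens *is* allowed —
otherwise a fully protected seed could never grow, which is precisely
the constrained-campaign use case.

The `radius` parameter (context sphere of external interchangeable-
fragment databases) is accepted and forwarded verbatim by the external
generator adapter but is a no-op in the built-in mutator: context
tables require the external database, and emulating them without it
would misrepresent the operator. This is a documented limitation, not
an approximation. Fragment tables are TSV
(`fragment_smiles<TAB>heavy_atoms`) with one terminal `*` attachment
dummy per fragment; heavy sites with more than ~200 candidates are
enumerated in deterministic order and capped to bound cost.

The staged schedule exposed by `stagedCampaignConfig()` mirrors the
canonical lead-generation→lead-optimization progression with parameter
tuples (minSize, maxSize, minInc, maxInc) = (0,0,1,6), (0,2,−2,4),
(1,8,−5,3), (0,1,−1,1) at radius 3, with generation counts scaled
proportionally to the published 20/25/40/15 split.

## Scoring backends and the surrogate

Scoring is a registry of backends with the contract
`function(individual, receptorSpec) -> list(score, pose)`; failures
poison only the affected individual (`cost = Inf`) and never abort a
run. The deterministic surrogate `-0.35·H + 0.005·H²` (heavy-atom
count `H`) stands in for a docking engine in desk-scale runs: it
decreases strictly up to its minimum −6.125 at H = 35 and rises
afterwards, giving the engine a growth gradient that saturates inside
drug-like size, with magnitudes on the docking-score scale the default
desirability window (−10, −2) expects. Its coefficients are a test
device, chosen once and documented as such; it carries no chemistry
beyond size. Consequences worth keeping in mind: under the surrogate,
score ties are common (isomers share H), the score axis is
conformation-independent, and campaign dynamics are driven mostly by
qed/sa differences between isomers — toy campaigns exercise the
engine's guarantees (elitism, uniqueness, determinism, acceptance
accounting), not docking realism.

Drug-likeness and synthetic accessibility delegate to the established
descriptor implementations (QED with default weights; the
fragment-contribution + complexity-penalty accessibility score) through
a bundled Python/RDKit helper, batched once per evaluation round and
cached by canonical SMILES, rather than re-deriving published constant
tables. One behavior of the established accessibility score worth
noting: single-atom molecules (e.g. methane) receive the rare-fragment
penalty and score ~7.3, not at the easy end — range tests use ethane.

## Constrained conformers

`constraintconf` holds a reference core rigid in 3D while the rest of
the candidate is embedded. The core is located by element-matched
subgraph monomorphism (LAD); among multiple matches the one minimizing
the mapped-index sum is chosen, a deterministic tie-break. When no
full match exists, an approximate maximum-common-substructure fallback
iteratively strips terminal reference atoms and retries — approximate
because an exact MCS search is not provided by any dependency and the
shrink-and-match loop is deterministic and bounded.

Embedding generates up to `nConf` (default 20) conformers (Open Babel
3D build + conformer search), rigidly superposes each onto the
reference over the mapped atoms (Kabsch), then places the mapped atoms
at the reference coordinates; embedded conformers therefore satisfy
the core tolerance (default 0.1 Å RMSD) by construction, at the price
of small boundary-bond distortions — acceptable for clash screening
and for backends that re-optimize locally, and irrelevant to the
conformation-independent surrogate. If constrained placement fails,
the rigid alignment alone is kept and flagged as a fallback. The
conformer search itself is not seedable through Open Babel, so
conformer geometries are not bit-reproducible; nothing in the GA's
determinism contract depends on them, and clash-filter unit tests use
synthetically constructed conformers where exact geometry matters.

Clash detection is a fixed-distance criterion: a conformer is removed
when any ligand heavy atom lies within `cutoff` (default 1.5 Å) of any
protein heavy atom; hydrogens are ignored on both sides. The filter is
monotone in the cutoff. `score_only` scores the best surviving
conformer (lowest core RMSD, ties by index) as-is; `local_only` needs
an engine capable of local pose relaxation and degrades to
`score_only` with a warning under the surrogate.

## Analytics

Similarity analytics use Morgan-style circular fingerprints (radius 2,
2048 bits) implemented in-package by iterative neighborhood hashing
over (atomic number, degree, hydrogen count, charge, ring membership)
invariants; the construction is invariant under atom reordering. Bit
positions are not interchangeable with any other toolkit's Morgan
bits — all similarity statements are internally consistent Tanimoto
values, which is what intra/inter-campaign comparisons need. Two
all-zero fingerprints compare as identical (similarity 1): both are
featureless.

Chemical-space projection keeps the top 50 principal components
(`prcomp`; the cumulative explained-variance fraction is reported) and
embeds the scores in 2D with an exact O(n²) t-SNE implemented
in-package (perplexity 30 capped at (n−1)/3, fixed seed, 350
iterations with early exaggeration). The embedding is qualitative by
nature and excluded from numeric acceptance; the PCA stage is verified
against an independent eigendecomposition.

The relative→absolute binding free energy conversion is pure
arithmetic, `dG_i = ddG_i + dG_r − ddG_r`, with errors in quadrature;
the molecular-dynamics machinery that produces its inputs is out of
scope, and the representative molecule is an input, not a choice this
package makes.

## What the toy fixtures do and do not show

The fixture generators produce fragment tables from a fixed pool of
simple substituents, pseudo-receptors (a spherical-shell cavity and a
plane wall of carbon pseudo-atoms), and staged run plans — all pure
functions of their seed. Together with the surrogate they let the
whole pipeline run in minutes on one CPU: the suite runs campaigns of
population 10–20 for 4–15 generations, 10⁵-draw selection checks, and
1000-case desirability property sweeps; the acceptance script runs a
15-generation, population-20 campaign. What passing shows: the
engine's invariants (elitism, uniqueness, shift-invariant Boltzmann
selection, resume determinism), the exactness of the desirability and
free-energy arithmetic, the mutation contract (increments, protection,
valence validity), and agreement of the two reference molecules'
descriptor values with their published property table. What it cannot
show: docking realism, the chemistry of real interchangeable-fragment
databases (context radius, synthetic-accessibility-filtered corpora),
or wall-clock/acceptance figures of engine-backed campaigns, which
require an external docking engine and receptor structures.

## Known limitations

* The built-in mutator treats molecules as neutral-organic connection
  tables; exotic valences fall back to conservative no-hydrogen
  assumptions and such children are rejected rather than guessed.
* Stereochemistry is preserved through canonical SMILES and thus
  participates in molecule identity; mutation does not create or
  enumerate stereocenters.
* `pdbqt` pose payloads are opaque text passed through from backends;
  the package never parses them.
* Only the three printed desirability shapes are provided; weights are
  user-set, never tuned automatically.
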