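---
title: "Threshold-free topology of metabolic brain covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free topology of metabolic brain covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metabolic connectivity treats the correlation of regional FDG uptake
across subjects as a network: if two brain regions' metabolic activity
covaries over the animals of a group, they are considered connected. This
is a *group-level* construct — with n subjects per group there is exactly
one network per (group, age) cell, not one per animal — which shapes the
entire statistical design (see *Inference* below).

`metanet` implements the full analysis chain for a paired two-group,
two-timepoint design modeled on a developmental comparison of an
ADHD-model rat strain (SHR) against its control (WKY) at 4 and 6 weeks of
age: network construction, threshold-free topology via graph filtration,
spanning-tree modularization, an information-flow model (volume entropy
and capacities), and permutation inference with FDR control. Because no
imaging data are distributed with the package, a synthetic cohort
generator reproduces the *statistical shape* of such a study so that every
stage is testable end to end.

## Network construction

Per group, the Pearson correlation $r_{ij}$ between ROI columns is
computed across subjects and restricted to positive values; the distance

$$d_{ij} = \sqrt{1 - r_{ij}}$$

maps $r = 1$ to distance 0 and $r \le 0$ to the maximal distance 1.
Negative correlations are **clipped to zero** by default. The alternative
(`negative = "drop"`) marks the pair as never directly merging (an
infinite internal distance, reported as 1 in files); both are provided
because the choice between them is a genuine free parameter of
positive-correlation network analysis, and clipping is the default because
it keeps the distance matrix complete so the filtration is always
well-defined.

## Graph filtration

Rather than fixing an arbitrary edge threshold, the analysis sweeps all of
them. As the threshold grows, connected components merge; the component
count $\beta_0(t)$ is a nonincreasing step function from $p$ (here 32
ROIs) down to 1. The threshold at which a single component first contains
every node is the birth of the giant connected component (GCC). Three
representations are derived from the merge sequence:

* the **β0-curve**, evaluated exactly at the merge thresholds
  (piecewise-constant, right-continuous) — no evaluation grid is needed,
  and any sampled curve can be reconstructed from it;
* the **single-linkage matrix (SLM)**, whose $(x,y)$ entry is the merge
  distance that first joins $x$ and $y$. It is an ultrametric, bounded
  above elementwise by $d$, and equals the minimax path distance of the
  weighted graph — facts the test suite verifies against brute-force
  oracles;
* the **dendrogram**, exported as Newick with midpoint branch lengths so
  cophenetic distances equal SLDs exactly.

Equal distances are processed in lexicographic node order. Ties can change
the *narration order* of merges but never the SLM or the β0-curve; they
can change the MST, so the spanning-tree code records whether ties exist
and the modularization scorer warns.

## MST and modularization

The minimum spanning tree (Kruskal, same deterministic tie rule) is the
minimal edge set carrying the SLM. The *modularization score* of a named
region set — e.g. the memory system (bilateral anterodorsal/posteroventral
hippocampus, retrosplenial cortex, thalamus, insula) or the
reward-motivation system (caudoputamen, medial prefrontal and anterior
cingulate cortices) — is the count of tree edges with both endpoints in
the set: a direct, assumption-free measure of how much of the network
backbone stays inside the system. It is bounded by $|S|-1$, attained
exactly when the set induces a connected subtree; trend tests therefore
operate below this saturation plateau.

## Volume entropy and capacities

Information flow is modeled by a generalized Markov system on *directed
edges*: each undirected edge of the GCC-supporting graph becomes two
ordered states, and the transition structure is

$$L(h)_{ef} = a_{ef}\, e^{-h\, l(f)},$$

where $l(f)$ is the (normalized) length of edge $f$ and $a_{ef}=1$ when
$f$ can follow $e$ (head of $e$ = tail of $f$). Design choices, each
exposed as an argument:

* **Adjacency.** The default forbids immediate backtracking
  ($f \ne \bar e$), matching the geodesic-flow definition of volume
  entropy on metric graphs; with backtracking allowed even trees acquire
  spurious closed walks and hence spurious entropy. A consequence the
  package enforces explicitly: under non-backtracking adjacency a tree has
  *no* closed paths at all, so `mode = "mst"` input is rejected with an
  explanatory error, and the default GMS substrate is the **filtration
  graph** — every edge at or below the GCC threshold.
* **Volume normalization.** Lengths are rescaled so the directed
  edge-weight total is exactly 2 (each undirected length counted twice).
  This makes the entropy invariant to any uniform rescaling of the raw
  distances. The alternative reading (undirected total 2) is available as
  `convention = "undirected2"`.
* **Entropy.** The spectral radius of $L(h)$ is strictly decreasing in
  $h$; volume entropy is the unique $h \ge 0$ with radius 1, found by
  bracketed bisection with secant refinement to $|\lambda - 1| \le
  10^{-12}$ (hard failure above $10^{-9}$). The radius is computed by
  power iteration on $L + I$ — the unit shift makes every recurrent class
  primitive, so the iteration converges even on periodic edge graphs; the
  suite cross-checks it against a dense eigensolver and against the closed
  form $h = \ln(p-2)/l$ for equal-length complete graphs.
* **Stationary state.** At the root, the Perron eigenvector $z \ge 0$
  (normalized to $\sum z = 1$; the model fixes no scale, so capacities are
  comparable only as proportions) is reshaped to the edge-capacity matrix
  $Z$, giving afferent (column-sum), efferent (row-sum) and net node
  capacities; net capacities sum to zero identically. Simplicity of the
  leading eigenvalue is certified via the strongly connected components of
  the edge digraph: an irreducible nonnegative matrix has a simple Perron
  root, so if two recurrent components attain the radius (e.g. the two
  orientations of a pure cycle) the stationary state is not unique and the
  solver refuses; dangling degree-1 vertices only generate a warning —
  their transient edges carry zero stationary capacity, which is the
  mathematically consistent answer.

Global efficiency is the standard Latora–Marchiori mean inverse weighted
shortest-path length, computed on the full distance graph by default
(restriction to the GCC graph is available) — it is a complementary global
feature, not part of the GMS.

## Inference

Because networks are group-level objects, group comparisons permute
*subjects* and rebuild the entire pipeline per pseudo-group:

* **Unpaired** (strain vs strain within an age): sampled label shuffles
  (default 10,000 in the statistical layer; the bundled analysis scripts
  use 2,000), two-tailed p with the add-one correction
  $(1 + \#\{|t^\ast| \ge |t|\})/(1+B)$ — conservative and never zero.
* **Paired** (age vs age within a strain): all $2^n$ within-pair swaps are
  enumerated — 4,096 for 12 pairs — and the p-value is exact counting; the
  identity pattern is one of the enumerated relabelings.
* **Bootstrap**: subjects resampled with replacement (default 100
  resamples) for distributional displays of global features.
* **FDR**: Benjamini–Hochberg step-up at $q = 0.05$ over each declared
  family (the analysis scripts correct over the contrast family; edge- or
  node-level families are corrected within all tested pairs/nodes).

## The synthetic cohort

Activity is multivariate Gaussian per (group, age) with a target
correlation matrix assembled as *baseline + block overwrites + effect
deltas*, clamped to $[0, 0.95]$ off-diagonal and repaired to positive
semi-definiteness by eigenvalue clipping (failing loudly if the repair
moves any entry by more than `repair_tol`). Ages are linked by a shared
latent factor with across-age correlation 0.5, so paired tests have true
pairing to exploit. The default design uses 12 subjects per group, 32
bilateral ROIs, baseline correlation 0.10, memory and reward-motivation
blocks at 0.35, and developmental deltas: a whole-brain strengthening with
age that is larger in controls (+0.05 → +0.17) than in the ADHD-model
group (0 → +0.08), a memory-system gain that is full-sized in controls
(+0.20) but partial in the ADHD-model group (+0.08), and a
left-lateralized cortical gain (+0.20) specific to the older ADHD-model
group. These values were chosen once as a realistic rendering of the
qualitative findings the design emulates — earlier GCC formation with age
and in controls, growing memory-system modularization in controls,
left-hemisphere strengthening in the ADHD-model group — and the trend
tests run across 20 seeds rather than relying on any single realization.

Behavioral scores are truncated normals calibrated to the reported group
summaries (marble burying 12.5 ± 2.6 vs 2.8 ± 2.1 of 15 marbles;
open-field distance 5.0 ± 1.5 vs 3.6 ± 1.3 m; delay discounting
12.8 ± 8.2 vs 35.8 ± 33.3 % choice of the larger delayed reward). The
latent location of each distribution is moment-matched by root-finding so
that the *post-truncation* (and, for the marble count, post-rounding)
expectation equals the configured mean — without this, clipping the
marble count at 15 would drag a nominal mean of 12.5 down to about 11.7.
Phenotype selection excludes SHR rats strictly below the 25th percentile
(linear-interpolation quantile, ties retained) of any of the three
ADHD-direction scores; the delay-discounting score is reversed
($100 - x$) so that higher always means more impulsive. Whether the
original exclusion used the union or the intersection of the per-test
quartiles is not determinable from the text; union is the default,
intersection a flag.

What the generator does *not* emulate: spatial autocorrelation of
parcellated PET, global-normalization artifacts, non-Gaussian uptake
distributions, or any voxel-level structure. Passing tests therefore
demonstrate correctness of the algorithms and the statistical machinery
under a clean covariance model, not robustness to imaging confounds.

## Numerical choices and degenerate inputs

* Zero-variance ROI columns are rejected by name; a zero distance (r = 1)
  is rejected at graph construction because a zero-length edge makes the
  GMS volume normalization meaningless.
* Disconnected inputs (possible under `negative = "drop"`) fail the
  filtration and MST with explicit messages.
* Sparse graphs whose non-backtracking radius is below 1 at $h = 0$ are
  rejected (entropy would be negative); a radius of exactly 1 at $h = 0$
  solves to $h \approx 0$.
* All sampled randomness (generator, unpaired permutations, bootstrap)
  is seeded explicitly; identical configuration and seed reproduce every
  output byte for byte, and the pipeline manifest records the
  configuration hash.

## Problem sizes

The bundled analysis runs four 12-subject × 32-ROI cells; exhaustive
paired contrasts enumerate 4,096 relabelings each, unpaired contrasts use
2,000 shuffles, and bootstrap displays use 100 resamples per cell. The
test suite exercises the same operations on 3–12-node fixtures with
exhaustive oracles (all spanning trees, minimax path distances, full
permutation enumerations) and on 500-replicate null calibrations of the
unpaired test. These sizes were chosen so the complete chain — including
every property test — re-runs from scratch in a few minutes on a laptop.

## Known limitations

* Capacities are proportions (Σz = 1); absolute comparisons across
  networks with different edge counts conflate density with flow.
* The GCC-threshold statistic is a maximum and is noisy at n = 12; single
  realizations can move against the population trend, which is why the
  scripts report permutation p-values rather than point contrasts.
* Modularization scores saturate at $|S| - 1$; near saturation they lose
  sensitivity.
* With tied distances the MST is non-unique; the deterministic tie rule
  makes results reproducible but not canonical, and a warning flags the
  condition.
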