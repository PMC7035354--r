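# metanet

Threshold-free topological analysis of **metabolic brain covariance
networks** — for researchers who estimate group-level networks from
subject-by-ROI tables of normalized FDG-PET uptake (or any comparable
regional activity measure) and want to compare their topology across
groups and developmental timepoints without committing to an arbitrary
edge threshold.

## What it computes

Per group, the positive Pearson correlation r\_ij between ROI columns is
turned into a distance

> d\_ij = sqrt(1 − r\_ij)

and analysed four ways:

1. **Graph filtration** — sweep the threshold over all values; track the
   number of connected components β0(t), the single-linkage matrix (SLM;
   the ultrametric of merge distances, equal to the minimax path
   distance), the dendrogram, and the birth threshold of the giant
   connected component (GCC).
2. **Minimum spanning tree** — the minimal edge set carrying the same
   SLM; the *modularization score* of a region set (memory,
   reward-motivation, …) counts tree edges internal to the set.
3. **Volume entropy** — a generalized Markov system on directed edges
   with transition matrix L(h) = [a\_ef e^(−h l(f))] (non-backtracking
   adjacency by default, edge lengths normalized to directed total 2);
   volume entropy is the h at which the spectral radius of L(h) equals 1,
   and the stationary Perron state yields edge capacities and
   afferent/efferent/net node capacities mapping directed information
   flow. Global efficiency (mean inverse shortest-path length) is
   computed alongside.
4. **Permutation inference** — sampled unpaired subject shuffles,
   exhaustive paired sign-flip enumeration (2^12 = 4096 for 12 pairs),
   subject bootstrap, and Benjamini–Hochberg FDR; every statistic rebuilds
   the whole network pipeline per pseudo-group.

A synthetic cohort generator (paired two-group, two-age Gaussian design
with block-modular correlation targets, plus calibrated behavioral scores
and ADHD-phenotype quartile selection) makes the entire chain testable
without imaging data. See the methods vignette
(`vignettes/metabolic-network-topology.Rmd`) for the model, parameter
defaults and their rationale.

## Worked example

```r
library(metanet)
cfg  <- default_cohort_config(seed = 42)     # 12/group x 32 ROIs x 2 ages
mats <- generate_roi_activity(cfg)
d    <- distance_matrix(mats[["control.wk6"]])

single_linkage_merges(d)
#> single-linkage dendrogram: 32 nodes, 31 merges, GCC threshold 0.6996

t <- minimum_spanning_tree(d)
modularization_score(t, "memory", default_roi_schema(), warn_ties = FALSE)
#> [1] 5

gms_analysis(d)          # GMS on the filtration graph at the GCC threshold
#> GMS result: h = 166.24 on 32 nodes / 152 directed edges ( nonbacktracking , directed2 )
#> largest |net| capacities: THA_R=+0.0540 PVH_R=+0.0494 THA_L=+0.0442 RSC_R=+0.0362 INS_R=-0.0336

global_efficiency(d)
#> [1] 1.219224

sf <- network_stat("global_efficiency")      # paired age contrast, exhaustive
paired_permutation_test(sf, unclass(mats[["control.wk6"]]),
                            unclass(mats[["control.wk4"]]))
#> permutation test: observed = 0.0799705, p = 0.1987 (exhaustive, 4096 perms)
```

Reading the numbers: the control-group week-6 network becomes fully
connected at distance 0.70; five MST edges run inside the memory system;
the stationary flow concentrates net influx on thalamic/hippocampal nodes
(positive net capacity = more afferent than efferent flow); and the
week-6 vs week-4 efficiency gain of 0.08 sits at p = 0.199 over all 4096
paired relabelings of this single synthetic realization.

## The analysis workflow

Numbered drivers under `analysis/` replay the full study design on the
default synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # behavior + phenotype selection + activity tables
Rscript analysis/02_network_topology.R     # filtration, SLMs, dendrograms, MSTs, scores
Rscript analysis/03_information_flow.R     # volume entropy, capacities, efficiency, bootstraps
Rscript analysis/04_group_statistics.R     # permutation contrasts + BH-FDR, full bundle
```

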