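# dominet

Minimum dominating set analysis of protein interaction networks.

## The problem

In an undirected binary protein interaction network *G = (V, E)* — the kind
produced by yeast-two-hybrid screens — a **minimum dominating set** (MDSet)
is a smallest set of proteins *S* such that every protein is either in *S*
or interacts with a member of *S*. MDSet proteins are a minimal "control
backbone": every other protein is one interaction away. The classic
centrality–lethality question asks whether topologically central proteins
tend to be essential; `dominet` sharpens it by stratifying proteins into
**essential**, **MDSet**, and **e-MDSet** (essential *and* MDSet) sets and
quantifying how each stratum behaves topologically and functionally.

The MDSet is computed exactly from the binary integer program

```
min Σ_v x_v    s.t.    x_v + Σ_{w ∈ Γ(v)} x_w ≥ 1   for every v ∈ V,  x_v ∈ {0,1}
```

by a deterministic branch-and-bound solver (greedy incumbent, set-cover
branching, packing lower bound, neighborhood-subsumption reduction)
implemented in C++. Around it, the package provides the full analysis
battery for the strata:

* degree-threshold enrichment curves `E_{i,≥k} = N_{i,≥k} / N^r_{i,≥k}`
  under seeded label-resampling nulls, and fractions over logarithmic
  degree bins;
* betweenness centrality `c_B(v) = Σ_{s≠t≠v} σ_st(v)/σ_st`, top-20%
  bottleneck sets, and their overlap enrichment (plus one-sided Fisher's
  exact tests);
* degree-ordered deletion trajectories (components and removed
  interactions per step) comparing the e-MDSet against equally many
  top-degree essential proteins;
* complex participation coefficients `P_i = Σ_s (n_{i,s}/Σ_s n_{i,s})²`
  with Wilcoxon stratum comparisons, and intra/inter-complex interaction
  enrichment under a complex-size-preserving reassignment null;
* COG-style functional class enrichment under a per-protein
  code-count-preserving permutation null;
* a seeded synthetic-study generator (scale-free network, planted
  degree-coupled essentiality, overlapping complexes with boosted internal
  wiring, biased class labels) so the whole pipeline is testable without
  any external database;
* `run_full_analysis()`, one call that produces a machine-readable report
  of everything above (thin CLI wrapper in `inst/scripts/run_analysis.R`).

All resampling tests report plus-one empirical p-values
`(1 + #extreme) / (1 + R)` and are bit-reproducible under a fixed seed.

## Worked example

```r
library(dominet)

study <- generate_study(study_config(n_nodes = 600, seed = 42))
mdset <- solve_mdset(study$network, time_limit = 30)
strata <- stratify(study$network, mdset, study$essential)
strata
#> Protein strata:
#>   MDSet:                110
#>   essential in network: 154
#>   e-MDSet (overlap):    45

fisher_overlap(600, 110, 154, 45)
#> [1] 7.29e-05
```

110 of 600 proteins (18%) dominate the network; 45 of them are also
essential, far more than the ~28 expected for an essentiality-blind set of
that size (one-sided Fisher p = 7.3e-5) — the planted degree coupling makes
high-degree proteins both more dominant and more essential. The e-MDSet's
degree-enrichment curve rises with the threshold *k*:

```r
head(degree_enrichment_curve(study$network, strata$e_mdset, reps = 1000, seed = 7), 4)
#>   k n_geq_k n_marked_geq_k null_mean null_sd enrichment        p_ge p_le
#> 1 1     600             45    45.000 0.00000   1.000000 1.000000000    1
#> 2 2     600             45    45.000 0.00000   1.000000 1.000000000    1
#> 3 3     409             45    30.725 3.13292   1.464605 0.000999001    1
#> 4 4     302             44    22.742 3.32844   1.934746 0.000999001    1
```

(at k = 3 the 45 e-MDSet proteins all sit in a bin where a random set of 45
would contribute ~31 — enrichment 1.46, p below 1/1001 — and the ratio keeps
growing with k). Interactions among essential proteins concentrate inside
the planted complexes:

```r
complex_null_enrichment(study$network, study$catalog,
                        strata$essential_in_network, reps = 1000, seed = 8)$intra
#> Enrichment: observed 109, null 11.84 +/- 3.86 (R = 1000)
#>   ratio 9.208, p_ge = 0.000999, p_le = 1
```

`run_full_analysis(study, reps = 10000, seed = 1)` chains every stage and
`write_report()` exports `report.json` plus per-stage TSVs.

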