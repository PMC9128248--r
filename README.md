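# pminet

Direct gene co-expression networks with **part mutual information (PMI)**,
matched Pearson-correlation baselines, multi-omics gene-pair relationship
encoding, and a copy-number/methylation gene-pair survival score — with a
synthetic-data module that generates every pipeline input from known
ground truth.

## Why

Ordinary co-expression networks wire up everything that correlates: a
cascade X → Y → Z produces a strong X–Z edge that is pure redundancy.
PMI scores the *direct* part of a dependence,

    PMI(X;Y|Z) = D( p(x,y,z) || p*(x|z) p*(y|z) p(z) ),
    p*(x|z) = Σ_y p(x|z,y) p(y),   D(p,q) = Σ p log(p/q)  (extended KL),

and the network builder starts fully connected, then removes every edge
whose PMI — maximized over conditioning sets drawn from the edge's common
network neighbors — falls below a threshold chosen by a stability scan.
Around that core the package provides:

* three **comparable PCC networks** per PMI network (edge-count-matched,
  node-coverage-matched, per-edge dominance) and the **PCC-only** edges;
* **correlation change networks** across a 4-stage disease progression
  (per-edge existence patterns such as `0-1-1-1`, per-node mean stage
  values);
* weighted **gene-pair relationship tables** from transcription
  regulation (CoTR), PPI, genomic distance (SCGD), joint copy number
  (CoCNV: GG/LL/GL/LG/NC with level-product weights) and joint CpG-island
  methylation (CoDM: LL/HH/LH/HL cross products);
* permutation **recall Z-scores** of networks against those tables, plus
  rank-sum weight comparisons;
* **survival factors** on gene pairs (log-rank on CoCNV groups > 20
  samples; median splits of NMAD-filtered CoDM values), the per-pair
  contribution `I_gp ∈ {-1, 0, +1}`, the patient `Score = Σ I_gp`,
  tertile stratification, Cox multivariate fits and 80%-subsample
  stability summaries.

## Worked example

Plant a 10-edge directed cascade over 20 genes, fit the PMI network with a
threshold scan, and check it against the ground truth:

```r
library(pminet)

g    <- random_dag(20, 10, seed = 3)                 # 10 direct edges
sim  <- simulate_expression(g, 1000, seed = 4)       # genes x samples
scan <- optimal_network_scan(sim$expr, seq(0.02, 0.26, by = 0.04))
scan
#> <PMI threshold scan>
#>  threshold edges jaccard_next
#>       0.02    12        0.833
#>       0.06    10        1.000
#>       0.10    10        1.000
#>       0.14    10        0.800
#>       0.18     8        0.875
#>       0.22     7        1.000
#>       0.26     7           NA
#> chosen: threshold 0.06 (index 2)
```

The scan settles at the first threshold whose edge set agrees with the
next one (Jaccard ≥ 0.95). The chosen network contains exactly the ten
planted direct edges — the spurious and indirect pairs were eliminated by
the order-0 threshold and the conditioned order-1 pass:

```r
rel <- relationship_table(sim$truth$true_direct_edges, kind = "planted")
recall_zscore(scan$chosen, rel, n_perm = 1000, seed = 5)
#> <recall: PMI network vs planted> 10 of 10 edges recalled
#>  variant observed null_mean   null_sd        z
#>    count       10     0.517 0.6664497 14.22913
```

All ten edges are records of the planted relationship table; random
10-edge draws from the 190 possible pairs recall ~0.5 on average, so the
enrichment Z-score is about 14 — the network captured real structure, not
correlation volume.

Survival scoring works the same way end to end: `cocnv_table()` /
`codm_table()` encode pair statuses, `find_cocnv_factors()` /
`find_codm_factors()` discover oriented factors such as `GG > NC` or
`HH-high > HH-low`, and `score_patients()` sums `I_gp` per patient (a GG
patient under a single `GG > NC` factor contributes +1; NC is always
neutral) before `cox_multivariate()` tests the score against clinical
covariates.

A thin command-line surface over the same functions lives at
`inst/cli/pminet.R` (subcommands `simulate`, `pmi-net`, `pcc-net`,
`change-net`, `relations`, `recall`, `survival`, `report`), each writing
TSV/SIF outputs plus a JSON manifest of parameters and seeds.

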