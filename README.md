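# fbdstrata

Stratigraphic evaluation of fossilized birth–death (FBD) posterior tree
distributions.

## The problem

Tip-dated phylogenies of entirely extinct clades are usually inferred from
the subset of taxa that have a morphological character matrix. That subset
is not a random sample of the fossil record — morphology gets scored for the
most abundantly sampled species — which violates the FBD model's assumption
of uniform fossil recovery and throws away the stratigraphic ages of every
other occurrence. The alternative is a *semi-resolved* analysis: add the
occurrence-only taxa with their ages and constrain their placement with
genus-level monophyly, then compare against the morphology-only *resolved*
analysis on the shared leafset.

`fbdstrata` is for palaeobiologists and phylogeneticists who want to make
that comparison quantitative on posterior tree samples. It provides:

* a forward **FBD simulator** (speciation λ, extinction μ, fossil recovery
  ψ, extant sampling ρ) with sampled ancestors, genus assignment by a
  stem-crossing rule, symmetric-Mk character matrices, abundance-biased
  morphology-taxon selection, stage-binned occurrence ages, and a
  congruence-weighted pseudo-posterior generator — so every downstream stage
  is testable without any download;
* **occurrence cleaning** (rank / imprecision / exclusion rules with
  deterministic audits) and one-interval-per-species age tables;
* **stratigraphic congruence** metrics under minimal node dating: the
  minimum implied gap `MIG = Σ ghost ranges`, its exact extremes
  `g_min = max(FAD) − min(FAD)` and `g_max = Σ (max(FAD) − FAD_i)`, the gap
  excess ratio `GER = 1 − (MIG − g_min)/(g_max − g_min)` and the
  stratigraphic consistency index (proportion of nodes not older than their
  sister), all backed by exhaustive topology-enumeration oracles;
* **treespace**: Robinson–Foulds and clustering-information tree distances
  (exact Hungarian split matching), classical PCoA with the full eigenvalue
  spectrum, congruence landscapes, per-group density maps and spread
  statistics;
* **consensus analytics**: majority-rule consensus, MCC trees, splitwise
  phylogenetic information content `h(s) = −log₂[(2a−3)!!(2b−3)!!/(2n−5)!!]`
  and greedy rogue-taxon detection;
* **HPD machinery**: shortest-window highest-posterior-density intervals,
  per-clade node-age HPD widths, and percent narrowing between arms.

`run_comparison()` orchestrates the full two-arm pipeline and returns a
classed report with `print()`, `summary()` and `plot()` methods. A thin CLI
wrapper lives at `inst/scripts/fbdstrata`.

## Worked example

Simulate one extinct clade, build two posterior-like arms over the same
truth — one unweighted (the morphology-only analogue) and one weighted by
stratigraphic congruence (the semi-resolved analogue) — and compare them:

```r
library(fbdstrata)

sc  <- synthetic_comparison(n_taxa_min = 18, n_taxa_max = 25,
                            n_trees = 50, seed = 7)
rep <- run_comparison(sc$config, seed = 7)
summary(rep)
```

```
Resolved vs semi-resolved comparison: 50 trees per arm on 25 taxa
  MIG: resolved 109 vs semi 99.3 (U = 2222, p = 1.44e-13)
  GER: resolved 0.924 vs semi 0.937 (U = 278.5, p = 1.44e-13)
  SCI: resolved 0.882 vs semi 0.923 (U = 631.5, p = 9.62e-06)
  origin-age 95% HPD width: resolved 8.91, semi 8.5 (4.6% narrower)

Consensus analytics:
  resolved  N nodes 23, N rogues 0, information 257.20 bits, mean improvement 0.00, sum posteriors (MCC) 21.12
  semi      N nodes 23, N rogues 0, information 267.84 bits, mean improvement 0.00, sum posteriors (MCC) 21.90

Treespace spread:
    group  n sum_variance sum_range mean_centroid_dist
 resolved 50     9.378509  88.59122           2.810340
     semi 50     6.172769  76.59040           2.204207
```

Reading it: the congruence-weighted arm implies ~10 myr less ghost range
per tree (lower MIG, higher GER/SCI; the Mann–Whitney p-values test the
between-arm shift), clusters more tightly in treespace (lower sum of
variances and centroid distance), conveys slightly more information about
the posterior's clades in bits, and dates the origin with a narrower 95%
HPD. `plot(rep)` draws the metric boxplots, the congruence landscape, the
per-arm density contours and the node-age HPD widths;
`report_json(rep, "report.json")` serializes the report reproducibly.

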